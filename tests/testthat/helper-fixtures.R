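# shared fixtures, built in code

# short template for fast alignment tests
small_template <- function(dt = 0.25) {
  make_template(dt = dt, n_pre = 8L, n_move = 10L, n_post = 6L,
                depth = 100, f_total = 500)
}

# circular cell contour of radius r centred at (cx, cy)
circle_contour <- function(r = 2500, cx = 0, cy = 0, n = 1440L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  membrane_contour(cx + r * cos(a), cy + r * sin(a))
}

# axisymmetric tube + hemispherical cap profile (base at z = 0)
tube_profile <- function(tube_len = 80, r_tube = 15, ds = 0.5,
                         time = NA_real_, id = "tube") {
  z_tube <- seq(0, tube_len, by = ds)
  a <- seq(0, pi / 2, length.out = 60L)[-1L]
  membrane_profile(c(z_tube, tube_len + r_tube * sin(a)),
                   c(rep(r_tube, length(z_tube)), r_tube * cos(a)),
                   time = time, id = id)
}

# cylinder profile (open tube, no cap)
cylinder_profile <- function(len = 200, r = 15, ds = 0.5, time = NA_real_,
                             id = "cylinder") {
  z <- seq(0, len, by = ds)
  membrane_profile(z, rep(r, length(z)), time = time, id = id)
}

# cohort of isometry-scattered noisy copies of a template
scatter_cohort <- function(template, n, sigma, lags = 0L, f_noise = 0) {
  nt <- nrow(template)
  lapply(seq_len(n), function(j) {
    beta <- stats::runif(1, 0, 2 * pi)
    tv <- stats::runif(2, -500, 500)
    lag <- if (length(lags) == 1L) lags else sample(lags, 1L)
    idx <- seq.int(max(1L, 1L + lag), min(nt, nt + lag))
    g <- iso_transform(beta, tv[1L], tv[2L])
    xy <- apply_transform(g, cbind(template$x[idx], template$y[idx]))
    m <- length(idx)
    f <- template$f[idx]
    if (f_noise > 0) f <- pmax(f * (1 + stats::rnorm(m, 0, f_noise)), 0)
    trajectory((seq_len(m) - 1) * attr(template, "dt"),
               xy[, 1L] + stats::rnorm(m, 0, sigma),
               xy[, 2L] + stats::rnorm(m, 0, sigma),
               f, id = sprintf("fix%02d", j), complete = TRUE)
  })
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(abs(a$theta - b$theta), tol)
  expect_lt(abs(a$tx - b$tx), tol)
  expect_lt(abs(a$ty - b$ty), tol)
}
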