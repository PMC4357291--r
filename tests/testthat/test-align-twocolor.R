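test_that("affine warp recovers a pure translation exactly", {
  set.seed(31)
  a <- matrix(runif(24, 0, 5e4), ncol = 2L)
  b <- sweep(a, 2L, c(10, -5))     # channel B shifted by (-10, +5)... A = B + (10, -5)
  w <- build_warp(a, b, "affine")
  pred <- predict_warp(w, b)
  expect_lt(max(abs(pred - a)), 1e-8)
  expect_lt(w$loo_rms, 1e-6)
  # identity control points -> identity warp
  wi <- build_warp(a, a, "affine")
  expect_lt(max(abs(predict_warp(wi, a) - a)), 1e-8)
  # collinear control points are degenerate
  x <- seq(0, 100, length.out = 5L)
  expect_error(build_warp(cbind(x, 2 * x), cbind(x, 2 * x + 1), "affine"),
               "degenerate|collinear")
})

test_that("local weighted mean beats affine on a quadratic distortion", {
  set.seed(32)
  g <- expand.grid(x = seq(0, 4e4, length.out = 6L),
                   y = seq(0, 4e4, length.out = 6L))
  a <- as.matrix(g)
  # smooth quadratic distortion field between the channels
  b <- a + cbind(3e-8 * a[, 1L]^2 + 1e-8 * a[, 1L] * a[, 2L] + 20,
                 -2e-8 * a[, 2L]^2 + 1e-8 * a[, 1L]^2 - 10)
  wa <- build_warp(a, b, "affine")
  wl <- build_warp(a, b, "lwm", n_neighbors = 12L)
  expect_lt(wl$loo_rms, wa$loo_rms)
  # and the lwm interpolates the field well away from control points
  mid <- matrix(c(1.7e4, 2.3e4), 1L)
  mid_b <- mid + cbind(3e-8 * mid[1L]^2 + 1e-8 * mid[1L] * mid[2L] + 20,
                       -2e-8 * mid[2L]^2 + 1e-8 * mid[1L]^2 - 10)
  expect_lt(sqrt(sum((predict_warp(wl, mid_b) - mid)^2)), 5)
})

test_that("pair lag and fit recover identity and constructed shifts", {
  tmpl <- make_template()
  P <- orient_to_axis(avg_trajectory(tmpl$t, tmpl$x, tmpl$y, tmpl$f),
                      center = FALSE)
  pair <- trajectory_pair(tmpl, tmpl)
  pt <- pair_lag_and_fit(pair, P, P, ma_window = 1L)
  expect_identical(pt$tau_p, 0L)
  expect_identical(pt$tau_r, 0L)
  expect_transform_equal(pt$T_p, iso_transform(), tol = 1e-6)
  # fluorescence curve shifted k frames is found by the cross-correlation
  k <- 4L
  n <- nrow(tmpl)
  idx <- (k + 1L):n
  shifted <- trajectory((seq_along(idx) - 1) * 0.25, tmpl$x[idx],
                        tmpl$y[idx], tmpl$f[idx], id = "shift")
  pt <- pair_lag_and_fit(trajectory_pair(shifted, tmpl), P, P,
                         ma_window = 1L)
  expect_identical(pt$tau_p, -k)
  expect_identical(pt$tau_r, 0L)
})

test_that("weighted pair fit matches a dense theta-grid oracle", {
  set.seed(33)
  tmpl <- make_template()
  n <- nrow(tmpl)
  P <- orient_to_axis(avg_trajectory(tmpl$t, tmpl$x, tmpl$y, tmpl$f,
                                     dx = runif(n, 0.5, 2),
                                     dy = runif(n, 0.5, 2)),
                      center = FALSE)
  p <- trajectory(tmpl$t, tmpl$x + rnorm(n, 0, 12),
                  tmpl$y + rnorm(n, 0, 12), tmpl$f)
  pt <- pair_lag_and_fit(trajectory_pair(p, p), P, P, ma_window = 1L)
  # oracle: same weights, dense theta grid with optimal translation
  w <- P$f * p$f / (P$dx * P$dy)
  wn <- w / sum(w)
  cost_at <- function(theta) {
    ct <- cos(theta); st <- sin(theta)
    rx <- ct * p$x - st * p$y
    ry <- st * p$x + ct * p$y
    tx <- sum(wn * (P$x - rx)); ty <- sum(wn * (P$y - ry))
    sum(wn * ((P$x - rx - tx)^2 + (P$y - ry - ty)^2))
  }
  oracle <- min(vapply(seq(-pi, pi, by = 1e-4), cost_at, numeric(1)))
  got <- cost_at(pt$T_p$theta)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("median/MAD aggregation reproduces hand arithmetic", {
  mk <- function(tau_r, tau_p = 0L)
    structure(list(tau_p = tau_p, tau_r = tau_r,
                   T_p = iso_transform(), T_r = iso_transform()),
              class = "pair_transforms")
  # lags (frames) {-1, 0, 0, 1, 2} at dt = 1 s
  est <- aggregate_transforms(lapply(c(-1L, 0L, 0L, 1L, 2L), mk), dt = 1)
  expect_equal(est$tau, 0)
  expect_equal(est$dtau, 1.4826 * 1 / sqrt(5), tolerance = 1e-12)
  # identical transforms -> zero uncertainties, medians equal the transform
  same <- lapply(1:4, function(i)
    structure(list(tau_p = 1L, tau_r = 3L,
                   T_p = iso_transform(0.01, 2, -1),
                   T_r = iso_transform(0.02, 5, 4)),
              class = "pair_transforms"))
  est <- aggregate_transforms(same, dt = 0.25)
  expect_equal(est$tau, 0.5)
  expect_equal(est$dtau, 0)
  expect_equal(est$dTx, 0)
  # T = T_r (T_p)^{-1} componentwise
  tref <- compose_transforms(iso_transform(0.02, 5, 4),
                             invert_transform(iso_transform(0.01, 2, -1)))
  expect_equal(est$Ttheta, tref$theta, tolerance = 1e-12)
  expect_equal(est$Tx, tref$tx, tolerance = 1e-9)
  expect_equal(est$Ty, tref$ty, tolerance = 1e-9)
})

test_that("alignment error propagation matches Monte-Carlo sampling", {
  # first-order zeta formula vs direct simulation of the transform noise
  set.seed(34)
  tmpl <- make_template()
  P <- avg_trajectory(tmpl$t, tmpl$x, tmpl$y, tmpl$f, dx = 1.5, dy = 1.2)
  est <- structure(list(tau = 0, Ttheta = 0, Tx = 0, Ty = 0,
                        dtau = 0, dTtheta = 0.02, dTx = 2, dTy = 1.5,
                        M = 100L),
                   class = "transform_estimate")
  al <- apply_alignment(P, est)
  nmc <- 1e5
  th <- rnorm(nmc, 0, est$dTtheta)
  tx <- rnorm(nmc, 0, est$dTx)
  ty <- rnorm(nmc, 0, est$dTy)
  for (i in c(5L, 20L, 40L)) {
    xs <- cos(th) * rnorm(nmc, P$x[i], P$dx[i]) -
      sin(th) * rnorm(nmc, P$y[i], P$dy[i]) + tx
    ys_ <- sin(th) * rnorm(nmc, P$x[i], P$dx[i]) +
      cos(th) * rnorm(nmc, P$y[i], P$dy[i]) + ty
    expect_equal(sd(xs), al$zx[i], tolerance = 0.05)
    expect_equal(sd(ys_), al$zy[i], tolerance = 0.05)
  }
  # identity estimate with zero uncertainty returns the input untouched
  est0 <- structure(list(tau = 0, Ttheta = 0, Tx = 0, Ty = 0, dtau = 0,
                         dTtheta = 0, dTx = 0, dTy = 0, M = 1L),
                    class = "transform_estimate")
  al0 <- apply_alignment(P, est0)
  expect_equal(al0$x, P$x)
  expect_equal(al0$zx, P$dx)
})

test_that("non-motile averaging places targets by their reference tracks", {
  set.seed(35)
  tmpl <- make_template()
  R <- orient_to_axis(avg_trajectory(tmpl$t, tmpl$x, tmpl$y, tmpl$f),
                      center = FALSE)
  n <- nrow(tmpl)
  pairs <- lapply(1:12, function(j) {
    beta <- runif(1, 0, 2 * pi)
    tv <- runif(2, -500, 500)
    g <- iso_transform(beta, tv[1L], tv[2L])
    rxy <- apply_transform(g, cbind(tmpl$x, tmpl$y))
    # target: static spot 30 nm from the reference along the axis
    txy <- apply_transform(g, cbind(tmpl$x + 30, tmpl$y))
    trajectory_pair(
      trajectory(tmpl$t, txy[, 1L], txy[, 2L], tmpl$f, id = "t"),
      trajectory(tmpl$t, rxy[, 1L], rxy[, 2L], tmpl$f, id = "r"),
      id = paste0("pair", j))
  })
  avg <- average_nonmotile(pairs, R, ma_window = 1L)
  expect_equal(nrow(avg), n)
  expect_lt(max(abs(avg$x - (R$x + 30))), 1e-6)
  expect_lt(max(abs(avg$y - R$y)), 1e-6)
  # a single pair returns that pair's transformed target
  one <- average_nonmotile(pairs[1], R, ma_window = 1L)
  expect_true(all(is.na(one$dx)))
  expect_lt(max(abs(one$x - (R$x + 30))), 1e-6)
})
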