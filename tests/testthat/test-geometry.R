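test_that("projection foreshortening follows the spherical closed form", {
  geom <- cell_geometry(radius = 2500, depth_of_field = 500)
  expect_equal(projection_underestimate(250, geom), 0.005,
               tolerance = 0.01)  # the printed figure is rounded to 0.5%
  expect_identical(projection_underestimate(0, geom), 0)
  expect_equal(projection_underestimate(1500, geom), 1 - sqrt(1 - 0.36))
  expect_equal(projection_underestimate(1500, geom), 0.2, tolerance = 1e-12)
  # monotone in |z|
  z <- seq(0, 2000, by = 50)
  expect_true(all(diff(projection_underestimate(z, geom)) > 0))
  expect_error(projection_underestimate(3000, geom), "radius")
})

test_that("membrane angles fold into [0, 90] with the right extremes", {
  contour <- circle_contour(r = 2500)
  # inward radial track near the contour point (2500, 0)
  tt <- (0:19) * 0.25
  radial <- trajectory(tt, 2480 - 5 * (0:19), rep(0, 20), rep(1, 20))
  expect_equal(membrane_angle(radial, contour), 90, tolerance = 0.5)
  # symmetric about y = 0 so the closest tangent is exactly vertical
  tangential <- trajectory(tt, rep(2480, 20),
                           seq(-25, 25, length.out = 20L), rep(1, 20))
  expect_equal(membrane_angle(tangential, contour), 0, tolerance = 0.5)
  # degenerate: no net displacement
  expect_warning(a <- membrane_angle(
    trajectory(tt, rep(2480, 20), rep(0, 20), rep(1, 20)), contour),
    "degenerate")
  expect_true(is.na(a))
})

test_that("uniformly oriented tracks average to 45 degrees", {
  set.seed(51)
  contour <- circle_contour(r = 2500)
  tt <- (0:9) * 0.25
  angles <- vapply(seq_len(2000), function(k) {
    a <- runif(1, 0, 2 * pi)
    membrane_angle(trajectory(tt, 2450 + 40 * cos(a) * (0:9) / 9,
                              40 * sin(a) * (0:9) / 9, rep(1, 10)),
                   contour)
  }, numeric(1))
  expect_equal(mean(angles), 45, tolerance = 0.05)
})

test_that("membrane angle is invariant under a joint rigid motion", {
  set.seed(52)
  tt <- (0:9) * 0.25
  contour <- circle_contour(r = 2500)
  traj <- trajectory(tt, 2460 - 3 * (0:9), 20 + 2 * (0:9), rep(1, 10))
  a0 <- membrane_angle(traj, contour)
  S <- iso_transform(1.1, 300, -150)
  cxy <- apply_transform(S, cbind(contour$x, contour$y))
  txy <- apply_transform(S, cbind(traj$x, traj$y))
  a1 <- membrane_angle(trajectory(tt, txy[, 1L], txy[, 2L], traj$f),
                       membrane_contour(cxy[, 1L], cxy[, 2L]))
  expect_equal(a0, a1, tolerance = 1e-6)
})

test_that("photobleach alignment recovers constructed jumps", {
  tmpl <- make_template()
  P <- orient_to_axis(avg_trajectory(tmpl$t, tmpl$x, tmpl$y, tmpl$f),
                      center = FALSE)
  contour <- circle_contour(r = 2500, cx = -2500 + min(P$x), cy = 0)
  # identical continuation: zero offsets, zero jump
  btraj <- trajectory(P$t, P$x, P$y, P$f, id = "bleach")
  bl <- align_photobleach(btraj, bleach_time = P$t[20L], contour, P)
  expect_equal(bl$jump, 0, tolerance = 0.5)
  expect_identical(bl$tau, 0L)
  # imposed -20 nm displacement after the bleach
  set.seed(53)
  jumps <- vapply(1:25, function(k) {
    x <- P$x + rnorm(nrow(P), 0, 2)
    post <- P$t >= P$t[20L]
    x[post] <- x[post] - 20
    b <- trajectory(P$t, x, P$y, P$f, id = "bleach")
    align_photobleach(b, bleach_time = P$t[20L], contour, P)$jump
  }, numeric(1))
  expect_equal(mean(jumps), -20, tolerance = 0.15)
  # post-bleach-only trajectory violates the precondition
  expect_error(align_photobleach(btraj, bleach_time = P$t[1L] - 1,
                                 contour, P),
               "pre-bleach")
})

test_that("profile registration is self-consistent and ordered", {
  # profiles of increasing depth; a coat trajectory constructed to pass
  # exactly through their tip centres of mass must be recovered exactly
  depths <- c(0, 40, 80, 120)
  profiles <- c(list(membrane_profile(c(0, 0), c(60, 0), id = "flat")),
                lapply(seq_along(depths[-1L]), function(k)
                  tube_profile(tube_len = depths[k + 1L] - 15, r_tube = 15,
                               id = paste0("pr", k))))
  coms <- vapply(profiles[-1L], function(pr) {
    s <- endotrack:::profile_arclength(pr)
    endotrack:::band_centroid_z(pr, max(0, s[length(s)] - 35), s[length(s)])
  }, numeric(1))
  tt <- seq(0, 12, by = 0.25)
  xx <- approx(c(0, 4, 8, 12), c(0, coms), xout = tt)$y
  sla2 <- data.frame(t = tt, x = xx)
  rvs <- structure(data.frame(t = tt, n = dnorm(tt, 9, 1.5)),
                   class = c("molecule_curve", "data.frame"))
  reg <- register_membrane_profiles(profiles, sla2, rvs)
  expect_equal(reg$times$time, c(0, 4, 8, 12), tolerance = 1e-6)
  expect_equal(reg$scission_time, 9)
  expect_equal(reg$times$time_rel_scission, c(0, 4, 8, 12) - 9,
               tolerance = 1e-6)
  # ordering preserved: deeper profiles never get earlier times
  expect_true(all(diff(reg$times$time) >= 0))
  # flat profile is pinned to the trajectory start (the position origin)
  expect_equal(reg$times$time[1L], tt[1L])
})

test_that("tip-band centre of mass matches direct numerical integration", {
  pr <- tube_profile(tube_len = 80, r_tube = 20, ds = 0.25)
  s <- endotrack:::profile_arclength(pr)
  total <- s[length(s)]
  for (L in c(30, 40)) {
    com <- endotrack:::band_centroid_z(pr, total - L, total)
    # quadrature oracle on a fine independent grid
    sg <- seq(total - L, total, length.out = 20001L)
    zg <- approx(s, pr$z, xout = sg)$y
    rg <- approx(s, pr$rho, xout = sg)$y
    num <- sum(2 * pi * rg * zg) / sum(2 * pi * rg)
    expect_equal(com, num, tolerance = 0.5 / num)
  }
})
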