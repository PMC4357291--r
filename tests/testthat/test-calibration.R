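test_that("copy number reduces to the reference when the ratio is one", {
  x <- rep(c(100, 110, 90, 105, 95), 4L)
  cal <- copy_number(x, x, n_r = 280.6, dn_r = 16.1)
  expect_equal(cal$n_p, 280.6)
  # identical samples: the ratio is exactly 1 and the only surviving error
  # should be dominated by the n_r term; with zero spread terms removed
  cal0 <- copy_number(rep(100, 5L), rep(100, 5L), n_r = 280.6, dn_r = 16.1)
  expect_equal(cal0$dn_p, 16.1)
  # scale invariance: multiplying both channels by a constant changes nothing
  cal2 <- copy_number(7 * x, 7 * x, n_r = 280.6, dn_r = 16.1)
  expect_equal(cal2$n_p, cal$n_p)
  expect_equal(cal2$dn_p, cal$dn_p, tolerance = 1e-12)
  expect_error(copy_number(c(-1, 2, 3), x, 100, 0), "positive")
  expect_error(copy_number(x[1:2], x, 100, 0), "at least 3")
})

test_that("the tag-corrected formula reduces to the plain one at c = 1", {
  set.seed(41)
  f <- rlnorm(50, 5, 0.4)
  g <- rlnorm(60, 5.5, 0.3)
  plain <- copy_number(f, g, n_r = 280.6, dn_r = 16.1)
  ext <- copy_number(f, g, n_r = 280.6, dn_r = 16.1, c_tag = 1, dc_tag = 0)
  expect_identical(ext$n_p, plain$n_p)
  expect_identical(ext$dn_p, plain$dn_p)
  # with the myEGFP-style correction the estimate scales by c and the
  # uncertainty gains the dc term
  corr <- copy_number(f, g, n_r = 280.6, dn_r = 16.1, c_tag = 0.68,
                      dc_tag = 0.14)
  expect_equal(corr$n_p, 0.68 * plain$n_p)
  expect_gt(corr$dn_p / 0.68, plain$dn_p)
})

test_that("copy-number uncertainty agrees with a bootstrap oracle", {
  set.seed(42)
  nsamp <- 500L
  f <- rlnorm(nsamp, log(200), 0.5)
  g <- rlnorm(nsamp, log(100), 0.25)
  cal <- copy_number(f, g, n_r = 100, dn_r = 0)
  expect_equal(cal$n_p, 100 * median(f) / median(g), tolerance = 1e-12)
  boot <- replicate(2000, {
    fb <- sample(f, replace = TRUE)
    gb <- sample(g, replace = TRUE)
    100 * median(fb) / median(gb)
  })
  expect_equal(cal$dn_p, sd(boot), tolerance = 0.2)
  # consistency: the estimate approaches the true median ratio
  expect_equal(cal$n_p, 200, tolerance = 0.12)
})

test_that("curve calibration matches hand arithmetic and is scale invariant", {
  P <- avg_trajectory(t = 0:2, x = numeric(3), y = numeric(3),
                      f = c(0, 1, 2), dx = 0, dy = 0, df = 0)
  cal <- structure(list(n_p = 2, dn_p = 0), class = "molecule_calibration")
  mc <- calibrate_curve(P, cal)
  expect_equal(mc$n, c(0, 2, 4))
  expect_equal(mc$dn, c(0, 0, 0))
  expect_equal(attr(mc, "F_bar"), 1)
  # scaling the fluorescence curve leaves the molecule curve unchanged
  P7 <- P; P7$f <- 7 * P$f
  expect_equal(calibrate_curve(P7, cal)$n, mc$n)
  # time-average identity: mean(P^n) = n_p by construction
  set.seed(43)
  Pr <- avg_trajectory(t = 0:19, x = numeric(20), y = numeric(20),
                       f = runif(20, 1, 5))
  mcr <- calibrate_curve(Pr, structure(list(n_p = 137.5, dn_p = 3),
                                       class = "molecule_calibration"))
  expect_equal(mean(mcr$n), 137.5, tolerance = 1e-12)
  expect_error(calibrate_curve(
    avg_trajectory(0:2, numeric(3), numeric(3), rep(2, 3)), cal),
    "constant")
})

test_that("molecule-curve errors agree with Monte-Carlo propagation", {
  set.seed(44)
  N <- 25L
  fcurve <- 50 + 40 * sin(seq(0, pi, length.out = N))^2
  dfv <- rep(1.2, N)
  P <- avg_trajectory(t = seq_len(N), x = numeric(N), y = numeric(N),
                      f = fcurve, df = dfv)
  np <- 200; dnp <- 8
  mc <- calibrate_curve(P, structure(list(n_p = np, dn_p = dnp),
                                     class = "molecule_calibration"))
  l <- attr(mc, "min_index")
  nmc <- 1e5
  draws <- matrix(0, nmc, N)
  np_s <- rnorm(nmc, np, dnp)
  eps <- matrix(rnorm(nmc * N, 0, 1.2), nmc)
  f_s <- sweep(eps, 2L, fcurve, "+")
  m_s <- f_s[, l]
  Fb_s <- rowMeans(f_s - m_s)
  for (i in seq_len(N)) draws[, i] <- np_s * (f_s[, i] - m_s) / Fb_s
  sds <- apply(draws, 2L, sd)
  away <- setdiff(seq_len(N), c(l - 1L, l, l + 1L))
  expect_lt(max(abs(sds[away] - mc$dn[away]) / sds[away]), 0.10)
})

test_that("tagged fraction follows the ratio algebra", {
  tf <- tagged_fraction(c(1, 1, 1))
  expect_equal(tf$r_tilde, 0.5)
  expect_equal(tf$sr_tilde, 0)
  tf0 <- tagged_fraction(c(0, 0))
  expect_equal(tf0$r_tilde, 0)
  expect_equal(tf0$sr_tilde, tf0$sr)
  # replicates constructed with mean ratio 0.0989 give the ~9% fraction
  reps <- 0.0989 + c(-0.003, -0.001, 0, 0, 0.001, 0.003, -0.002, 0.002)
  tf9 <- tagged_fraction(reps)
  expect_equal(tf9$r_tilde, 0.0989 / 1.0989, tolerance = 1e-6)
  expect_equal(round(100 * tf9$r_tilde), 9)
  expect_error(tagged_fraction(c(-0.1, 0.2)), "non-negative")
  expect_error(tagged_fraction(0.5), "2 replicates")
})

test_that("filament length arithmetic", {
  fl <- filament_length_estimate(3000, 200, rise_nm = 2.7)
  expect_equal(fl$subunits_per_filament, 15)
  expect_equal(fl$mean_length_nm, 40.5)
})
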