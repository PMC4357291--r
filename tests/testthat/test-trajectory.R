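test_that("trajectory construction enforces the invariants", {
  tr <- trajectory(c(0, 0.25), c(0, 1), c(0, 0), c(1, 1), id = "a",
                   complete = TRUE)
  expect_s3_class(tr, "trajectory")
  expect_equal(attr(tr, "dt"), 0.25)
  expect_error(trajectory(0, 0, 0, 1), "at least 2")
  expect_error(trajectory(c(0, 0, 0.25), c(0, 1, 2), c(0, 0, 0),
                          c(1, 1, 1), id = "dup"),
               "strictly increasing")
  expect_error(trajectory(c(0, 0.25, 0.6), 1:3, 1:3, c(1, 1, 1)),
               "not uniform")
  expect_error(trajectory(c(0, 0.25), c(0, 1), c(0, 0), c(-1, 1)),
               "fluorescence")
})

test_that("table io validates, converts units and round-trips bitwise", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tt\tx\ty\tf",
               "a\t0\t0\t0\t1",
               "a\t1\t1.5\t-2\t2"), path)
  # frame/pixel dialect: 1 frame = 0.25 s, 1 px = 100 nm
  trs <- read_trajectories(path, trajectory_dialect(
    xy_unit = "px", t_unit = "frame", px_nm = 100, dt = 0.25))
  expect_length(trs, 1L)
  expect_equal(trs[["a"]]$x, c(0, 150))
  expect_equal(trs[["a"]]$t, c(0, 0.25))

  writeLines(c("id\tt\tx\ty\tf", "b\t0\t0\t0\t1", "b\t0\t1\t0\t1"), path)
  expect_error(read_trajectories(path), "strictly increasing")
  writeLines(c("id\tt\tx\tf", "b\t0\t0\t1"), path)
  expect_error(read_trajectories(path), "misses column")

  # round trip of a synthetic cohort preserves every coordinate bitwise
  set.seed(3)
  cohort <- scatter_cohort(small_template(), 65L, sigma = 12)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(cohort, out)
  back <- read_trajectories(out)
  expect_length(back, 65L)
  for (j in seq_along(cohort)) {
    id <- attr(cohort[[j]], "id")
    expect_identical(back[[id]]$x, cohort[[j]]$x)
    expect_identical(back[[id]]$y, cohort[[j]]$y)
    expect_identical(back[[id]]$f, cohort[[j]]$f)
    expect_identical(back[[id]]$t, cohort[[j]]$t)
  }
})

test_that("smoothing preserves constants, SG is exact on polynomials, and the moving average obeys the variance law", {
  n <- 31L
  tt <- (seq_len(n) - 1) * 0.25
  const <- trajectory(tt, rep(5, n), rep(-2, n), rep(3, n))
  for (mode in c("savitzky_golay", "moving_average")) {
    sm <- smooth_trajectory(const, cohort_config(mode, window = 11L))
    expect_equal(sm$x, const$x, tolerance = 1e-12)
    expect_equal(sm$t, const$t)          # time stamps untouched
    expect_identical(nrow(sm), nrow(const))
  }
  # linear ramp: SG window 11 order 3 reproduces interior points exactly
  ramp <- trajectory(tt, seq_len(n) * 2, rep(0, n), rep(1, n))
  sm <- smooth_trajectory(ramp, cohort_config("savitzky_golay",
                                              window = 11L, order = 3L))
  interior <- 6:(n - 5)
  expect_equal(sm$x[interior], ramp$x[interior], tolerance = 1e-9)
  # white noise variance reduced ~5x by a length-5 moving average
  set.seed(9)
  m <- 10000L
  noise <- trajectory((seq_len(m) - 1) * 0.25, rnorm(m), rnorm(m),
                      rep(1, m))
  sm <- smooth_trajectory(noise, cohort_config("moving_average",
                                               window = 5L))
  ratio <- var(noise$x[3:(m - 2)]) / var(sm$x[3:(m - 2)])
  expect_equal(ratio, 5, tolerance = 0.15)
  expect_error(smooth_trajectory(trajectory(c(0, .25, .5), 1:3, 1:3,
                                            c(1, 1, 1)),
                                 cohort_config(window = 11L)),
               "shorter")
})

test_that("patch lifetimes apply the completeness and start-window rules", {
  dt <- 0.25
  mk <- function(first, last, complete = TRUE) {
    fr <- first:last
    trajectory(fr * dt, numeric(length(fr)), numeric(length(fr)),
               rep(1, length(fr)), complete = complete)
  }
  # frames 10..50 at dt = 0.25 s span 10 s
  tr <- mk(10L, 50L)
  expect_equal(patch_lifetimes(list(tr), known_lifetime = 10,
                               movie_length = 400L), 10)
  # starting beyond 3x lifetime -> excluded
  late <- mk(200L, 240L)
  expect_length(patch_lifetimes(list(late), known_lifetime = 10,
                                movie_length = 400L), 0L)
  # incomplete -> excluded
  inc <- mk(10L, 50L, complete = FALSE)
  expect_length(patch_lifetimes(list(inc), known_lifetime = 10,
                                movie_length = 400L), 0L)
  expect_error(patch_lifetimes(list(tr), known_lifetime = 0,
                               movie_length = 400L), "> 0")
})

test_that("movie truncation biases the estimated mean lifetime downward", {
  # exponential true lifetimes observed in a finite movie: events that are
  # cut off are incomplete, surviving complete events under-represent the
  # long tail
  set.seed(21)
  dt <- 1
  movie <- 120
  true_mean <- 15
  cohort <- lapply(1:400, function(j) {
    start <- runif(1, 0, movie * 0.9)
    life <- rexp(1, 1 / true_mean)
    end <- min(start + life, movie)
    n <- max(2L, ceiling((end - start) / dt))
    trajectory(start + (seq_len(n) - 1) * dt, numeric(n), numeric(n),
               rep(1, n), complete = start + life < movie && start > 0)
  })
  est <- patch_lifetimes(cohort, known_lifetime = true_mean,
                         movie_length = movie)
  expect_gt(length(est), 20L)
  expect_lte(mean(est), true_mean)
})
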