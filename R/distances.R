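#' Density of measured 2D separations between two fluorophores
#'
#' Two fluorophores a true distance `d` apart, each localised with
#' isotropic error of standard deviation `sigma` per coordinate, yield
#' measured centroid separations `s` distributed as the length of a 2D
#' Gaussian displacement (a Rice distribution):
#' \deqn{p(s \mid d, \sigma) = \frac{s}{\sigma^2}
#'   \exp\!\Big(-\frac{s^2 + d^2}{2\sigma^2}\Big)
#'   I_0\!\Big(\frac{s d}{\sigma^2}\Big),}
#' with \eqn{I_0} the modified Bessel function of order zero. At `d = 0`
#' this reduces to the Rayleigh density. The second moment is
#' \eqn{E[s^2] = d^2 + 2\sigma^2}.
#'
#' @param s separations (nm, >= 0).
#' @param d true separation (nm, >= 0).
#' @param sigma localisation spread (nm, > 0).
#' @param log logical; return the log density.
#' @return Density (or log density) values.
#' @export
dseparation <- function(s, d, sigma, log = FALSE) {
  z <- s * d / sigma^2
  # scaled Bessel avoids overflow: log I0(z) = log besselI(z,0,scaled) + z
  logI0 <- log(besselI(z, 0, expon.scaled = TRUE)) + z
  ld <- log(s) - 2 * log(sigma) - (s^2 + d^2) / (2 * sigma^2) + logI0
  ld[s < 0] <- -Inf
  if (log) ld else exp(ld)
}

#' Maximum-likelihood separation between two fluorophore populations
#'
#' Fits the non-Gaussian 2D displacement density (see [dseparation()]) to
#' per-spot centroid separations by maximum likelihood, with standard
#' errors from the inverse observed Fisher information (the Hessian of the
#' negative log-likelihood at the optimum). Optimisation starts from
#' moment estimates (\eqn{E[s^2] = d^2 + 2\sigma^2}) and falls back to a
#' coarse grid restart if the first attempt fails or hits the boundary.
#'
#' @param samples separations (nm, >= 0).
#' @param min_samples smallest accepted sample size.
#' @param fix_sigma optional known localisation spread (nm); when given
#'   only `d` is fitted.
#' @return A list of class `separation_fit` with `d`, `sigma`, `se_d`,
#'   `se_sigma`, `loglik`, `n`, `convergence`.
#' @export
fit_separation <- function(samples, min_samples = 20L, fix_sigma = NULL) {
  s <- as.numeric(samples)
  if (any(s < 0)) stop("negative separations are not valid")
  if (length(s) < min_samples)
    stop("need at least ", min_samples, " samples (got ", length(s), ")")
  m2 <- mean(s^2)
  sigma0 <- stats::sd(s)
  if (!is.null(fix_sigma)) sigma0 <- fix_sigma
  d0 <- sqrt(max(m2 - 2 * sigma0^2, (0.1 * sqrt(m2))^2))
  nll <- if (is.null(fix_sigma)) {
    function(par) -sum(dseparation(s, par[1L], par[2L], log = TRUE))
  } else {
    function(par) -sum(dseparation(s, par[1L], fix_sigma, log = TRUE))
  }
  run <- function(start) {
    lower <- if (is.null(fix_sigma)) c(0, 1e-6) else 0
    tryCatch(stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                          hessian = TRUE),
             error = function(e) NULL)
  }
  start <- if (is.null(fix_sigma)) c(d0, sigma0) else d0
  opt <- run(start)
  if (is.null(opt) || opt$convergence != 0) {
    # coarse grid restart
    dg <- seq(0, 3 * sqrt(m2), length.out = 15L)
    sg <- if (is.null(fix_sigma))
      seq(0.1 * sigma0 + 1e-3, 3 * sigma0 + 1, length.out = 15L) else
      fix_sigma
    grid <- expand.grid(d = dg, sigma = sg)
    vals <- apply(grid, 1L, function(g)
      nll(if (is.null(fix_sigma)) c(g[["d"]], g[["sigma"]]) else g[["d"]]))
    g <- grid[which.min(vals), ]
    opt <- run(if (is.null(fix_sigma)) c(g$d, g$sigma) else g$d)
    if (is.null(opt))
      stop("separation fit did not converge (n = ", length(s),
           ", mean s = ", signif(mean(s), 4), ")")
  }
  par <- opt$par
  d_hat <- par[1L]
  sigma_hat <- if (is.null(fix_sigma)) par[2L] else fix_sigma
  se <- rep(NA_real_, length(par))
  hi <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (!is.null(hi)) {
    v <- diag(as.matrix(hi))
    se <- ifelse(v > 0, sqrt(v), NA_real_)
  }
  structure(list(d = d_hat, sigma = sigma_hat,
                 se_d = se[1L],
                 se_sigma = if (is.null(fix_sigma)) se[2L] else 0,
                 loglik = -opt$value, n = length(s),
                 convergence = opt$convergence),
            class = "separation_fit")
}

#' @export
print.separation_fit <- function(x, ...) {
  cat(sprintf("separation fit (n = %d): d = %.2f +/- %.2f nm, sigma = %.2f +/- %.2f nm\n",
              x$n, x$d, x$se_d, x$sigma, x$se_sigma))
  invisible(x)
}

#' Orientation of fluorophore pairs relative to the membrane
#'
#' For matched two-colour centroid pairs near the cell surface, the angle
#' between the inter-centroid vector and the nearest membrane tangent,
#' folded into [0, 90] degrees. Pairs with a vanishing inter-centroid
#' vector are excluded.
#'
#' @param pairs_a,pairs_b two-column matrices of matched centroid
#'   positions (nm) of the two fluorophores.
#' @param contour a [membrane_contour()].
#' @param min_length smallest inter-centroid distance considered (nm).
#' @return A list with `angles` (degrees, `NA` for excluded pairs),
#'   `mean`, `sem`.
#' @export
termini_angle <- function(pairs_a, pairs_b, contour, min_length = 1e-6) {
  pairs_a <- as.matrix(pairs_a); pairs_b <- as.matrix(pairs_b)
  stopifnot(ncol(pairs_a) == 2L, ncol(pairs_b) == 2L,
            nrow(pairs_a) == nrow(pairs_b))
  angles <- rep(NA_real_, nrow(pairs_a))
  for (i in seq_len(nrow(pairs_a))) {
    v <- pairs_b[i, ] - pairs_a[i, ]
    len <- sqrt(sum(v^2))
    if (len < min_length) next
    mid <- (pairs_a[i, ] + pairs_b[i, ]) / 2
    seg <- closest_contour_segment(contour, mid)
    ca <- abs(sum(v / len * seg$tangent))
    angles[i] <- acos(min(max(ca, 0), 1)) * 180 / pi
  }
  ok <- !is.na(angles)
  if (any(!ok))
    warning(sum(!ok), " pair(s) excluded (vanishing inter-centroid vector)",
            call. = FALSE)
  list(angles = angles, mean = mean(angles[ok]),
       sem = stats::sd(angles[ok]) / sqrt(sum(ok)))
}
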