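#' Pair a target and a reference trajectory acquired simultaneously
#'
#' @param target the target-protein trajectory (GFP channel).
#' @param reference the reference-protein trajectory (Abp1 channel),
#'   acquired simultaneously with the target (shared time base).
#' @param id acquisition identifier.
#' @return A list of class `trajectory_pair`.
#' @export
trajectory_pair <- function(target, reference, id = "pair") {
  stopifnot(inherits(target, "trajectory"), inherits(reference, "trajectory"))
  if (abs(attr(target, "dt") - attr(reference, "dt")) > 1e-6)
    stop("pair '", id, "': channels do not share the sampling interval")
  structure(list(target = target, reference = reference, id = id),
            class = "trajectory_pair")
}

#' Rotate an average trajectory onto its symmetry axis
#'
#' The invagination axis is estimated as the principal direction of the
#' fluorescence-weighted spread of the average trajectory (weighted PCA of
#' the coordinates), signed so that the net motion of the centroid points
#' toward +X. Optionally the trajectory is also centred at its
#' fluorescence-weighted centre of mass.
#'
#' @param avg an `avg_trajectory`.
#' @param center logical; centre at the weighted centre of mass.
#' @return The oriented (and possibly centred) `avg_trajectory`, with the
#'   applied [iso_transform()] stored in attribute `orientation`.
#' @export
orient_to_axis <- function(avg, center = FALSE) {
  w <- avg$f / sum(avg$f)
  mx <- sum(w * avg$x); my <- sum(w * avg$y)
  cx <- avg$x - mx; cy <- avg$y - my
  cov <- matrix(c(sum(w * cx * cx), sum(w * cx * cy),
                  sum(w * cx * cy), sum(w * cy * cy)), 2L)
  ax <- eigen(cov, symmetric = TRUE)$vectors[, 1L]
  # sign: net motion (late minus early mean position) points toward +X
  k <- max(2L, round(nrow(avg) / 5))
  net <- c(mean(utils::tail(avg$x, k)) - mean(utils::head(avg$x, k)),
           mean(utils::tail(avg$y, k)) - mean(utils::head(avg$y, k)))
  if (sum(net * ax) < 0) ax <- -ax
  theta <- -atan2(ax[2L], ax[1L])
  tr <- iso_transform(theta, 0, 0)
  xy <- apply_transform(tr, cbind(avg$x, avg$y))
  out <- avg
  out$x <- xy[, 1L]; out$y <- xy[, 2L]
  if (center) {
    ofs <- c(sum(w * out$x), sum(w * out$y))
    out$x <- out$x - ofs[1L]; out$y <- out$y - ofs[2L]
    tr <- compose_transforms(iso_transform(0, -ofs[1L], -ofs[2L]), tr)
  }
  attr(out, "orientation") <- tr
  out
}

resample_onto <- function(traj, dt) {
  # cubic-spline interpolation onto a grid with the average's interval
  if (abs(attr(traj, "dt") - dt) <= 1e-9) return(traj)
  tt <- seq(traj$t[1L], traj$t[nrow(traj)], by = dt)
  if (length(tt) < 2L) stop("trajectory too short to resample")
  trajectory(tt,
             stats::spline(traj$t, traj$x, xout = tt)$y,
             stats::spline(traj$t, traj$y, xout = tt)$y,
             pmax(stats::spline(traj$t, traj$f, xout = tt)$y, 0),
             id = attr(traj, "id"), channel = attr(traj, "channel"),
             complete = attr(traj, "complete"))
}

xcorr_lag <- function(pf, Pf, min_overlap = 5L) {
  # tau maximising sum_i p_{i+tau} P_i: track index = average index + tau
  np <- length(pf); nP <- length(Pf)
  lags <- (1L - nP):(np - 1L)
  lags <- lags[order(abs(lags), lags)]
  best_tau <- NA_integer_; best_cc <- -Inf
  for (tau in lags) {
    i0 <- max(1L, 1L - tau); i1 <- min(nP, np - tau)
    if (i1 - i0 + 1L < min_overlap) next
    cc <- sum(Pf[i0:i1] * pf[(i0:i1) + tau])
    if (cc > best_cc) { best_cc <- cc; best_tau <- tau }
  }
  if (is.na(best_tau)) stop("no lag with sufficient fluorescence overlap")
  best_tau
}

xcorr_lag_norm <- function(pf, Pf, min_overlap = 5L) {
  # cosine-normalised variant for short segments
  np <- length(pf); nP <- length(Pf)
  lags <- (1L - nP):(np - 1L)
  lags <- lags[order(abs(lags), lags)]
  best_tau <- NA_integer_; best_cc <- -Inf
  for (tau in lags) {
    i0 <- max(1L, 1L - tau); i1 <- min(nP, np - tau)
    if (i1 - i0 + 1L < min_overlap) next
    a <- Pf[i0:i1]; b <- pf[(i0:i1) + tau]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den <= 0) next
    cc <- sum(a * b) / den
    if (cc > best_cc) { best_cc <- cc; best_tau <- tau }
  }
  if (is.na(best_tau)) stop("no lag with sufficient fluorescence overlap")
  best_tau
}

weight_floor <- function(w) {
  bad <- !is.finite(w)
  if (any(bad)) {
    if (all(bad)) {
      w[] <- 1
    } else {
      cap <- stats::quantile(w[!bad], 0.99, names = FALSE)
      w[bad] <- cap
      warning("non-finite weights capped at the 99th percentile",
              call. = FALSE)
    }
  }
  w
}

fit_track_to_average <- function(traj, avg, cfg) {
  sm <- smooth_trajectory(traj, cohort_config("moving_average",
                                              window = cfg$ma_window))
  sm <- resample_onto(sm, attr(avg, "dt"))
  tau <- xcorr_lag(sm$f, avg$f, cfg$min_overlap)
  # average index i matches track index i + tau
  i0 <- max(1L, 1L - tau); i1 <- min(nrow(avg), nrow(sm) - tau)
  iP <- i0:i1
  ip <- iP + tau
  keep <- rep(TRUE, length(iP))
  if (isTRUE(cfg$invagination_only))
    keep <- iP <= which.max(avg$f)
  if (sum(keep) < 2L) keep <- rep(TRUE, length(iP))
  iP <- iP[keep]; ip <- ip[keep]
  w <- avg$f[iP] * sm$f[ip] / (avg$dx[iP] * avg$dy[iP])
  w <- weight_floor(w)
  tr <- fit_rigid_weighted(cbind(sm$x[ip], sm$y[ip]),
                           cbind(avg$x[iP], avg$y[iP]), w)
  list(tau = tau, transform = tr)
}

#' Temporal and spatial alignment of one trajectory pair
#'
#' The target track `p` is aligned in time to the target average `P` by the
#' lag maximising the fluorescence cross-correlation
#' \eqn{\tau_p = \arg\max_\tau \sum_i p^f_{i+\tau} P^f_i}, and in space by
#' the weighted rigid fit with weights
#' \eqn{w_i = P^f_i p^f_{i+\tau_p} / (\delta^x_i \delta^y_i)}. The same is
#' done for the reference track `r` against the reference average `R`.
#' Tracks are smoothed with a short moving average and cubic-spline
#' interpolated onto the averages' sampling grid first.
#'
#' @param pair a [trajectory_pair()].
#' @param P,R `avg_trajectory` objects for the target and reference
#'   proteins, already oriented to their symmetry axis (see
#'   [orient_to_axis()]); `P` centred at its weighted centre of mass.
#' @param ma_window moving-average window for pair smoothing (frames).
#' @param min_overlap minimum overlap for the lag search (frames).
#' @param ref_invagination_only logical; restrict the reference spatial fit
#'   to points up to the reference average's fluorescence peak.
#' @return A list of class `pair_transforms` with `tau_p`, `tau_r`
#'   (frames), `T_p`, `T_r` ([iso_transform()]).
#' @export
pair_lag_and_fit <- function(pair, P, R, ma_window = 3L, min_overlap = 5L,
                             ref_invagination_only = FALSE) {
  cfg_p <- list(ma_window = ma_window, min_overlap = min_overlap,
                invagination_only = FALSE)
  cfg_r <- list(ma_window = ma_window, min_overlap = min_overlap,
                invagination_only = ref_invagination_only)
  fp <- fit_track_to_average(pair$target, P, cfg_p)
  fr <- fit_track_to_average(pair$reference, R, cfg_r)
  structure(list(tau_p = fp$tau, tau_r = fr$tau,
                 T_p = fp$transform, T_r = fr$transform, id = pair$id),
            class = "pair_transforms")
}

#' Aggregate per-pair transforms into a robust average transform
#'
#' Each pair yields an estimate \eqn{T = T_r (T_p)^{-1}} of the transform
#' aligning the target average to the reference average. Components are
#' combined by medians:
#' \deqn{\tau = \mathrm{median}(\tau_r - \tau_p)\,dt,\quad
#'   T^\theta = \mathrm{median}(T_r^\theta - T_p^\theta),}
#' \deqn{T^x = \mathrm{median}(T_r^x - \cos\Delta\theta\,T_p^x +
#'   \sin\Delta\theta\,T_p^y),\quad
#'   T^y = \mathrm{median}(T_r^y - \sin\Delta\theta\,T_p^x -
#'   \cos\Delta\theta\,T_p^y),}
#' with \eqn{\Delta\theta = T_r^\theta - T_p^\theta} per pair. Each
#' uncertainty is the standard error of a median,
#' \eqn{1.4826 \times \mathrm{MAD} / \sqrt{M}}. The composition of the
#' rotation is a small-angle approximation, valid because both averages are
#' pre-rotated onto their symmetry axis; a warning is issued when the
#' median rotation exceeds `small_angle_warn`.
#'
#' @param per_pair list of `pair_transforms` (from [pair_lag_and_fit()]).
#' @param dt sampling interval (s) used to convert frame lags to seconds.
#' @param small_angle_warn threshold (rad) for the small-angle warning.
#' @return A list of class `transform_estimate` with `tau` (s), `Tx`, `Ty`
#'   (nm), `Ttheta` (rad), the MAD-based standard errors `dtau`, `dTx`,
#'   `dTy`, `dTtheta`, and `M` (number of pairs used).
#' @export
aggregate_transforms <- function(per_pair, dt, small_angle_warn = 0.1) {
  M <- length(per_pair)
  if (M == 0L) stop("no pair transforms to aggregate")
  tau_d <- vapply(per_pair, function(p) (p$tau_r - p$tau_p) * dt, numeric(1))
  th_r <- vapply(per_pair, function(p) p$T_r$theta, numeric(1))
  th_p <- vapply(per_pair, function(p) p$T_p$theta, numeric(1))
  dth <- th_r - th_p
  tx <- vapply(per_pair, function(p) p$T_r$tx, numeric(1)) -
    cos(dth) * vapply(per_pair, function(p) p$T_p$tx, numeric(1)) +
    sin(dth) * vapply(per_pair, function(p) p$T_p$ty, numeric(1))
  ty <- vapply(per_pair, function(p) p$T_r$ty, numeric(1)) -
    sin(dth) * vapply(per_pair, function(p) p$T_p$tx, numeric(1)) -
    cos(dth) * vapply(per_pair, function(p) p$T_p$ty, numeric(1))
  med_se <- function(v) 1.4826 * stats::mad(v, constant = 1) / sqrt(M)
  ttheta <- stats::median(dth)
  if (abs(ttheta) > small_angle_warn)
    warning("median rotation ", signif(ttheta, 3),
            " rad exceeds the small-angle threshold (",
            small_angle_warn, " rad); the composed translation medians ",
            "assume T_r^theta ~ T_p^theta", call. = FALSE)
  structure(list(tau = stats::median(tau_d), Ttheta = ttheta,
                 Tx = stats::median(tx), Ty = stats::median(ty),
                 dtau = med_se(tau_d), dTtheta = med_se(dth),
                 dTx = med_se(tx), dTy = med_se(ty), M = M),
            class = "transform_estimate")
}

#' @export
print.transform_estimate <- function(x, ...) {
  cat(sprintf(paste0("transform estimate (M = %d pairs):\n",
                     "  tau    = %8.3f +/- %.3f s\n",
                     "  Ttheta = %8.4f +/- %.4f rad\n",
                     "  Tx     = %8.2f +/- %.2f nm\n",
                     "  Ty     = %8.2f +/- %.2f nm\n"),
              x$M, x$tau, x$dtau, x$Ttheta, x$dTtheta,
              x$Tx, x$dTx, x$Ty, x$dTy))
  invisible(x)
}

#' Apply an aggregated transform estimate to an average trajectory
#'
#' Coordinates are transformed by `(Ttheta, Tx, Ty)`; positional standard
#' errors are propagated to first order,
#' \deqn{\zeta^x_i = \sqrt{(\delta^x_i)^2 + (P^y_i\,\delta T^\theta)^2 +
#'   (\delta T^x)^2},\qquad
#'   \zeta^y_i = \sqrt{(\delta^y_i)^2 + (P^x_i\,\delta T^\theta)^2 +
#'   (\delta T^y)^2},}
#' so that the alignment uncertainty only ever adds variance. The aligned
#' time base is `t - tau` (the reference clock); 95% confidence bands are
#' `1.96 * zeta` and `1.96 * dtau`.
#'
#' @param P the (oriented, centred) target `avg_trajectory`.
#' @param est a `transform_estimate` from [aggregate_transforms()].
#' @return A data frame of class `aligned_trajectory` with columns `i`,
#'   `t` (reference time base, s), `x`, `y`, `f`, `zx`, `zy`, `zf`; the
#'   estimate is kept in attribute `estimate`.
#' @export
apply_alignment <- function(P, est) {
  stopifnot(inherits(est, "transform_estimate"))
  tr <- iso_transform(est$Ttheta, est$Tx, est$Ty)
  xy <- apply_transform(tr, cbind(P$x, P$y))
  zx <- sqrt(P$dx^2 + (P$y * est$dTtheta)^2 + est$dTx^2)
  zy <- sqrt(P$dy^2 + (P$x * est$dTtheta)^2 + est$dTy^2)
  structure(data.frame(i = P$i, t = P$t - est$tau,
                       x = xy[, 1L], y = xy[, 2L], f = P$f,
                       zx = zx, zy = zy, zf = P$df),
            estimate = est, dt = attr(P, "dt"),
            class = c("aligned_trajectory", "data.frame"))
}

#' Two-colour averaging for non-motile proteins
#'
#' Proteins without clear inward movement cannot be aligned by their own
#' trajectories. Instead, for each simultaneously acquired pair the
#' reference track is aligned to the reference average, and the resulting
#' lag and transform are applied to the target track; the transformed
#' target tracks are then averaged per time index.
#'
#' @param pairs list of [trajectory_pair()] objects.
#' @param R the reference `avg_trajectory` (oriented to its axis).
#' @param ma_window,min_overlap,ref_invagination_only see
#'   [pair_lag_and_fit()].
#' @return An `avg_trajectory` of the target protein in the reference
#'   frame.
#' @export
average_nonmotile <- function(pairs, R, ma_window = 3L, min_overlap = 5L,
                              ref_invagination_only = FALSE) {
  dt <- attr(R, "dt")
  cfg_r <- list(ma_window = ma_window, min_overlap = min_overlap,
                invagination_only = ref_invagination_only)
  pieces <- list()
  for (pair in pairs) {
    fr <- tryCatch(fit_track_to_average(pair$reference, R, cfg_r),
                   error = function(e) {
                     warning("pair '", pair$id, "' excluded: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(fr)) next
    tgt <- resample_onto(pair$target, dt)
    xy <- apply_transform(fr$transform, cbind(tgt$x, tgt$y))
    # track index j corresponds to reference-average index j - tau_r
    pieces[[length(pieces) + 1L]] <-
      data.frame(i = seq_len(nrow(tgt)) - fr$tau,
                 x = xy[, 1L], y = xy[, 2L], f = tgt$f)
  }
  if (!length(pieces)) stop("no pair could be aligned to the reference")
  all <- do.call(rbind, pieces)
  idx <- sort(unique(all$i))
  stat <- function(v, fun) vapply(idx, function(i)
    fun(all[[v]][all$i == i]), numeric(1))
  sem <- function(v) vapply(idx, function(i) {
    vals <- all[[v]][all$i == i]
    if (length(vals) < 2L) NA_real_ else stats::sd(vals) / sqrt(length(vals))
  }, numeric(1))
  structure(data.frame(i = idx, t = (idx - 1L) * dt + R$t[1L],
                       x = stat("x", mean), y = stat("y", mean),
                       f = stat("f", mean),
                       dx = sem("x"), dy = sem("y"), df = sem("f"),
                       n = vapply(idx, function(i) sum(all$i == i),
                                  numeric(1))),
            dt = dt, class = c("avg_trajectory", "data.frame"))
}
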