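#' Best pairwise alignment of two trajectories (rigid + lag)
#'
#' For every admissible integer lag `tau`, points `p_i` are matched with
#' `q_{i+tau}` and the weighted rigid transform mapping `p` toward `q` is
#' fitted with weights \eqn{w_i = q^f_{i+\tau} p^f_i} (the product of the
#' spot fluorescence intensities, which concentrates the fit on the bright,
#' well-localised part of the event and acts as a fluorescence
#' cross-correlation in time). The lag/transform pair with the smallest
#' weighted mean squared residual wins; ties go to the smallest `|tau|`,
#' then to the smaller `tau`.
#'
#' Because the cost is weight-normalised it is not comparable between a
#' full overlap and a few dim tail frames, so a lag is only admissible
#' when its fluorescence mass \eqn{\sum_i w_i} reaches a fraction
#' `overlap_frac` of the best lag's mass — the weights being proportional
#' to the fluorescence cross-correlation, this confines the search to
#' temporally plausible lags.
#'
#' @param p,q [trajectory()] objects sharing the same sampling interval.
#' @param min_overlap smallest admissible number of overlapping frames.
#' @param lag_range optional integer vector restricting the lags searched;
#'   by default every lag with sufficient overlap is tried.
#' @param overlap_frac smallest admissible fluorescence mass, as a
#'   fraction of the maximum over lags.
#' @return A list of class `pair_alignment` with elements `transform`
#'   ([iso_transform()]), `tau` (integer lag, frames), `cost` (weighted mean
#'   squared residual, nm^2) and `overlap` (number of overlapping frames).
#' @export
best_pair_alignment <- function(p, q, min_overlap = 5L, lag_range = NULL,
                                overlap_frac = 0.5) {
  dtp <- attr(p, "dt"); dtq <- attr(q, "dt")
  if (!is.null(dtp) && !is.null(dtq) && abs(dtp - dtq) > 1e-6)
    stop("trajectories do not share the same sampling interval")
  np <- nrow(p); nq <- nrow(q)
  if (is.null(lag_range)) lag_range <- (-(np - 1L)):(nq - 1L)
  # visit lags sorted by (|tau|, tau) so that strict improvement implements
  # the tie-break toward small lags
  lag_range <- lag_range[order(abs(lag_range), lag_range)]
  px <- p$x; py <- p$y; pf <- p$f
  qx <- q$x; qy <- q$y; qf <- q$f
  # fluorescence mass per lag (the cross-correlation) gates admissibility
  mass <- vapply(lag_range, function(tau) {
    i0 <- max(1L, 1L - tau); i1 <- min(np, nq - tau)
    if (i1 - i0 + 1L < min_overlap) return(0)
    sum(pf[i0:i1] * qf[(i0:i1) + tau])
  }, numeric(1))
  mass_floor <- overlap_frac * max(mass)
  best_tau <- NA_integer_; best_cost <- Inf; best_overlap <- 0L
  max_overlap <- 0L
  for (k in seq_along(lag_range)) {
    tau <- lag_range[k]
    i0 <- max(1L, 1L - tau)
    i1 <- min(np, nq - tau)
    if (i1 - i0 + 1L < min_overlap) next
    max_overlap <- max(max_overlap, i1 - i0 + 1L)
    if (mass[k] <= 0 || mass[k] < mass_floor) next
    idx <- i0:i1
    jdx <- idx + tau
    w <- pf[idx] * qf[jdx]
    sw <- sum(w)
    w <- w / sw
    # closed-form weighted rigid fit, inlined for speed
    ax <- px[idx]; ay <- py[idx]; bx <- qx[jdx]; by <- qy[jdx]
    cpx <- sum(w * ax); cpy <- sum(w * ay)
    cqx <- sum(w * bx); cqy <- sum(w * by)
    ax <- ax - cpx; ay <- ay - cpy
    bx <- bx - cqx; by <- by - cqy
    s1 <- sum(w * (ax * bx + ay * by))
    s2 <- sum(w * (ax * by - ay * bx))
    # cost = Var_w(q') + Var_w(p') - 2 * |(s1, s2)|
    cost <- sum(w * (ax * ax + ay * ay)) + sum(w * (bx * bx + by * by)) -
      2 * sqrt(s1 * s1 + s2 * s2)
    if (cost < best_cost - 1e-12) {
      best_tau <- tau; best_cost <- cost; best_overlap <- length(idx)
    }
  }
  if (is.na(best_tau))
    stop("no admissible lag: maximum achievable overlap is ", max_overlap,
         " frames (min_overlap = ", min_overlap, ")")
  i0 <- max(1L, 1L - best_tau)
  i1 <- min(np, nq - best_tau)
  idx <- i0:i1
  tr <- fit_rigid_weighted(cbind(px[idx], py[idx]),
                           cbind(qx[idx + best_tau], qy[idx + best_tau]),
                           pf[idx] * qf[idx + best_tau])
  best <- list(transform = tr, tau = best_tau, cost = attr(tr, "cost"),
               overlap = best_overlap)
  class(best) <- "pair_alignment"
  best
}

truncate_at_peak <- function(traj) {
  k <- which.max(traj$f)
  if (k < 2L) k <- 2L
  trajectory(traj$t[1:k], traj$x[1:k], traj$y[1:k], traj$f[1:k],
             id = attr(traj, "id"), channel = attr(traj, "channel"),
             complete = attr(traj, "complete"))
}

unwrap_to <- function(angles, ref) {
  angles - 2 * pi * round((angles - ref) / (2 * pi))
}

#' Align a cohort of trajectories and average them
#'
#' Every trajectory is used in turn as the reference for all others, giving
#' `n(n-1)` pairwise alignments. The pairwise estimates are combined into
#' one transform (and one integer lag) per trajectory mapping it into a
#' common frame anchored at the first trajectory: the frame transform of
#' each reference, composed with the pairwise transform, gives an estimate
#' of the trajectory's own frame transform; rotation angles are averaged
#' after unwrapping, translations averaged, lags combined by median.
#' Aligned trajectories are then averaged per time index.
#'
#' When `cfg$invagination_only` is `TRUE` the pairwise fits use only the
#' points up to each trajectory's fluorescence peak (the rule applied to
#' reference-protein style cohorts); the averaging still uses the full
#' trajectories.
#'
#' @param cohort list of [trajectory()] objects (n >= 2, common dt).
#' @param cfg a [cohort_config()].
#' @return An average trajectory: data frame of class `avg_trajectory` with
#'   columns `i` (common frame index), `t` (s), `x`, `y` (nm), `f`, `dx`,
#'   `dy`, `df` (standard errors of the means; `NA` where only one
#'   trajectory contributes) and `n` (contributing trajectories), plus a
#'   `dt` attribute.
#' @export
align_and_average <- function(cohort, cfg = cohort_config()) {
  n <- length(cohort)
  if (n < 2L) stop("at least 2 trajectories are required")
  dt <- attr(cohort[[1L]], "dt")
  # events from different cells sit at arbitrary field positions; centring
  # each track at its fluorescence-weighted centroid first keeps the
  # pairwise translations small, so that rotation noise in one pairwise
  # estimate cannot be amplified into large translation errors when the
  # estimates are composed into the common frame
  cohort <- lapply(cohort, function(tr) {
    w <- tr$f / sum(tr$f)
    trajectory(tr$t, tr$x - sum(w * tr$x), tr$y - sum(w * tr$y), tr$f,
               id = attr(tr, "id"), channel = attr(tr, "channel"),
               complete = attr(tr, "complete"))
  })
  fit_set <- if (cfg$invagination_only)
    lapply(cohort, truncate_at_peak) else cohort

  # pairwise alignments: ali[[j]][[k]] aligns trajectory j to reference k
  ali <- vector("list", n)
  for (j in seq_len(n)) {
    ali[[j]] <- vector("list", n)
    for (k in seq_len(n)) {
      if (j == k) next
      ali[[j]][[k]] <- tryCatch(
        best_pair_alignment(fit_set[[j]], fit_set[[k]],
                            min_overlap = cfg$min_overlap),
        error = function(e) {
          warning("pair (", attr(cohort[[j]], "id"), ", ",
                  attr(cohort[[k]], "id"), ") excluded: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
    }
  }

  # frame transforms of the references, anchored at trajectory 1
  frames <- vector("list", n)
  frame_lag <- integer(n)
  frames[[1L]] <- iso_transform()
  frame_lag[1L] <- 0L
  for (k in 2:n) {
    a <- ali[[k]][[1L]]
    if (is.null(a))
      stop("trajectory ", attr(cohort[[k]], "id"),
           " cannot be anchored to the common frame")
    frames[[k]] <- a$transform
    frame_lag[k] <- a$tau
  }

  # per-trajectory average transform over all references
  combined <- vector("list", n)
  lag <- integer(n)
  for (j in seq_len(n)) {
    thetas <- c(); txs <- c(); tys <- c(); lags <- c()
    for (k in seq_len(n)) {
      if (j == k || is.null(ali[[j]][[k]])) next
      s <- compose_transforms(frames[[k]], ali[[j]][[k]]$transform)
      thetas <- c(thetas, s$theta)
      txs <- c(txs, s$tx); tys <- c(tys, s$ty)
      lags <- c(lags, frame_lag[k] + ali[[j]][[k]]$tau)
    }
    if (!length(thetas))
      stop("trajectory ", attr(cohort[[j]], "id"),
           " has no usable pairwise alignment")
    thetas <- unwrap_to(thetas, thetas[1L])
    combined[[j]] <- iso_transform(mean(thetas), mean(txs), mean(tys))
    lag[j] <- as.integer(round(stats::median(lags)))
  }

  # transform into the common frame and average per common index
  pieces <- lapply(seq_len(n), function(j) {
    tr <- cohort[[j]]
    xy <- apply_transform(combined[[j]], cbind(tr$x, tr$y))
    data.frame(i = seq_len(nrow(tr)) + lag[j],
               x = xy[, 1L], y = xy[, 2L], f = tr$f)
  })
  all <- do.call(rbind, pieces)
  idx <- sort(unique(all$i))
  agg <- function(v, fun) vapply(idx, function(i)
    fun(all[[v]][all$i == i]), numeric(1))
  n_i <- vapply(idx, function(i) sum(all$i == i), numeric(1))
  sem <- function(v) vapply(idx, function(i) {
    vals <- all[[v]][all$i == i]
    if (length(vals) < 2L) NA_real_ else stats::sd(vals) / sqrt(length(vals))
  }, numeric(1))
  avg <- data.frame(i = idx,
                    t = (idx - 1L) * dt + cohort[[1L]]$t[1L],
                    x = agg("x", mean), y = agg("y", mean),
                    f = agg("f", mean),
                    dx = sem("x"), dy = sem("y"), df = sem("f"),
                    n = n_i)
  if (cfg$recenter) {
    wf <- avg$f / sum(avg$f)
    avg$x <- avg$x - sum(wf * avg$x)
    avg$y <- avg$y - sum(wf * avg$y)
  }
  structure(avg, dt = dt, class = c("avg_trajectory", "data.frame"))
}

#' Construct an average trajectory directly
#'
#' Mostly used to wrap ground-truth templates or externally computed
#' averages so they can enter the two-colour procedure.
#'
#' @param t times (s); `x`, `y` coordinates (nm); `f` fluorescence.
#' @param dx,dy,df standard errors of the means.
#' @param n number of contributing trajectories per point.
#' @return An `avg_trajectory` data frame.
#' @export
avg_trajectory <- function(t, x, y, f, dx = 1, dy = 1, df = 1, n = 1L) {
  m <- length(t)
  stopifnot(m >= 2L, length(x) == m, length(y) == m, length(f) == m)
  dt <- stats::median(diff(t))
  structure(data.frame(i = seq_len(m), t = t, x = x, y = y, f = f,
                       dx = rep_len(dx, m), dy = rep_len(dy, m),
                       df = rep_len(df, m), n = rep_len(n, m)),
            dt = dt, class = c("avg_trajectory", "data.frame"))
}

#' @export
print.avg_trajectory <- function(x, ...) {
  cat(sprintf("average trajectory: %d time points, dt = %g s\n",
              nrow(x), attr(x, "dt")))
  NextMethod()
}
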