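#' Cell geometry for projection calculations
#'
#' @param radius cell radius (nm; a typical yeast cell is ~2500 nm).
#' @param depth_of_field axial detection range around the focal plane (nm).
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(radius = 2500, depth_of_field = 500) {
  stopifnot(radius > 0, depth_of_field > 0, depth_of_field <= 2 * radius)
  structure(list(radius = radius, depth_of_field = depth_of_field),
            class = "cell_geometry")
}

#' Projection foreshortening of membrane-normal movement
#'
#' Movies are acquired at the equatorial plane of the (spherical) cell, so
#' an endocytic event sitting a height `z_offset` above or below that
#' plane moves along a membrane normal that is tilted out of the focal
#' plane. Its in-plane projection underestimates the true inward movement
#' by the fraction
#' \deqn{1 - \sqrt{1 - (z/R)^2}.}
#' At the edge of a 500 nm depth of field (z = 250 nm) on a 2500 nm
#' radius cell this is 0.5%.
#'
#' @param z_offset height above/below the equatorial plane (nm).
#' @param geom a [cell_geometry()].
#' @return The underestimated fraction (0 at the equator).
#' @export
projection_underestimate <- function(z_offset, geom = cell_geometry()) {
  if (any(abs(z_offset) > geom$radius))
    stop("z_offset exceeds the cell radius")
  1 - sqrt(1 - (z_offset / geom$radius)^2)
}

#' Closed membrane contour in the focal plane
#'
#' @param x,y vertex coordinates (nm) of the cell boundary, ordered along
#'   the contour (the polyline is treated as closed).
#' @return A data frame of class `membrane_contour`.
#' @export
membrane_contour <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  structure(data.frame(x = x, y = y),
            class = c("membrane_contour", "data.frame"))
}

closest_contour_segment <- function(contour, pt) {
  # closed polyline: append the first vertex
  vx <- c(contour$x, contour$x[1L]); vy <- c(contour$y, contour$y[1L])
  n <- length(vx) - 1L
  ex <- vx[-1L] - vx[-(n + 1L)]; ey <- vy[-1L] - vy[-(n + 1L)]
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- NA_real_
  u <- ((pt[1L] - vx[-(n + 1L)]) * ex + (pt[2L] - vy[-(n + 1L)]) * ey) / len2
  u <- pmin(pmax(u, 0), 1)
  qx <- vx[-(n + 1L)] + u * ex; qy <- vy[-(n + 1L)] + u * ey
  d2 <- (pt[1L] - qx)^2 + (pt[2L] - qy)^2
  i <- which.min(d2)
  list(d2 = d2[i], point = c(qx[i], qy[i]),
       tangent = c(ex[i], ey[i]) / sqrt(len2[i]))
}

weighted_direction <- function(traj) {
  # fluorescence-weighted total-least-squares direction of the track,
  # signed by the net displacement
  w <- traj$f
  if (sum(w) <= 0) w <- rep(1, nrow(traj))
  w <- w / sum(w)
  mx <- sum(w * traj$x); my <- sum(w * traj$y)
  cx <- traj$x - mx; cy <- traj$y - my
  cov <- matrix(c(sum(w * cx * cx), sum(w * cx * cy),
                  sum(w * cx * cy), sum(w * cy * cy)), 2L)
  v <- eigen(cov, symmetric = TRUE)$vectors[, 1L]
  k <- max(2L, min(3L, nrow(traj) %/% 2L))
  net <- c(mean(utils::tail(traj$x, k)) - mean(utils::head(traj$x, k)),
           mean(utils::tail(traj$y, k)) - mean(utils::head(traj$y, k)))
  if (sum(net * v) < 0) v <- -v
  list(direction = v, net = sqrt(sum(net^2)))
}

#' Angle between a trajectory and the nearest membrane tangent
#'
#' The trajectory direction is the fluorescence-weighted total
#' least-squares line through the track; the membrane tangent is taken at
#' the contour point closest to the track's weighted centroid. The angle
#' is folded into [0, 90] degrees (90 = movement along the inward
#' normal).
#'
#' @param traj a [trajectory()].
#' @param contour a [membrane_contour()].
#' @param max_distance largest allowed distance (nm) between track and
#'   contour.
#' @param min_displacement net displacement (nm) below which the track
#'   direction is considered degenerate (returns `NA` with a warning).
#' @return Angle in degrees, or `NA` for degenerate tracks.
#' @export
membrane_angle <- function(traj, contour, max_distance = 1000,
                           min_displacement = 10) {
  w <- traj$f / sum(traj$f)
  ctr <- c(sum(w * traj$x), sum(w * traj$y))
  seg <- closest_contour_segment(contour, ctr)
  if (sqrt(seg$d2) > max_distance)
    stop("trajectory is ", round(sqrt(seg$d2)), " nm from the contour ",
         "(max_distance = ", max_distance, ")")
  dir <- weighted_direction(traj)
  if (dir$net < min_displacement) {
    warning("net displacement ", signif(dir$net, 3),
            " nm below the noise floor: direction degenerate", call. = FALSE)
    return(NA_real_)
  }
  ca <- abs(sum(dir$direction * seg$tangent))
  acos(min(max(ca, 0), 1)) * 180 / pi
}

#' Align a photobleaching trajectory to an average trajectory
#'
#' The bleached track is projected onto the membrane normal (the inward
#' axis) at its closest contour point. Its pre-bleach segment is aligned
#' to the average trajectory in time (fluorescence cross-correlation) and
#' space (least-squares offset of the inward movement); the post-bleach
#' jump is the difference between the first post-bleach position and the
#' average trajectory at the matched time. A negative jump points toward
#' the membrane.
#'
#' @param bleach_traj the tracked [trajectory()] spanning the bleach.
#' @param bleach_time time of the bleaching pulse (s, on the track's
#'   clock).
#' @param contour a [membrane_contour()].
#' @param P the protein's `avg_trajectory`, oriented so +X is the inward
#'   axis.
#' @param min_overlap minimum pre-bleach overlap (frames).
#' @return A list of class `bleach_alignment`: `aligned` (data frame with
#'   `t` on the average's clock and inward coordinate `x`), `jump` (nm),
#'   `tau` (frames), `offset` (nm).
#' @export
align_photobleach <- function(bleach_traj, bleach_time, contour, P,
                              min_overlap = 3L) {
  pre <- bleach_traj$t < bleach_time
  if (sum(pre) < min_overlap)
    stop("no sufficient pre-bleach overlap (", sum(pre), " frames before ",
         bleach_time, " s)")
  if (!any(!pre))
    stop("trajectory ends before the bleach: nothing to align")
  seg <- closest_contour_segment(contour,
                                 c(bleach_traj$x[1L], bleach_traj$y[1L]))
  normal <- c(-seg$tangent[2L], seg$tangent[1L])
  # inward = away from the membrane, toward the cell interior (the track)
  w <- bleach_traj$f / sum(bleach_traj$f)
  ctr <- c(sum(w * bleach_traj$x), sum(w * bleach_traj$y))
  if (sum((ctr - seg$point) * normal) < 0) normal <- -normal
  b1d <- (bleach_traj$x - seg$point[1L]) * normal[1L] +
         (bleach_traj$y - seg$point[2L]) * normal[2L]
  # temporal alignment on the pre-bleach fluorescence; the pre-bleach
  # segment is short, so the cross-correlation is normalised (a raw inner
  # product would simply lock onto the brightest part of the average)
  tau <- xcorr_lag_norm(bleach_traj$f[pre], P$f, min_overlap)
  pre_idx <- which(pre)
  iP <- pre_idx - tau
  ok <- iP >= 1L & iP <= nrow(P)
  if (sum(ok) < min_overlap)
    stop("pre-bleach segment does not overlap the average trajectory")
  wfit <- bleach_traj$f[pre_idx[ok]] * P$f[iP[ok]]
  if (sum(wfit) <= 0) wfit <- rep(1, sum(ok))
  offset <- sum(wfit * (P$x[iP[ok]] - b1d[pre_idx[ok]])) / sum(wfit)
  aligned_x <- b1d + offset
  t_aligned <- P$t[1L] + (seq_along(b1d) - tau - 1L) * attr(P, "dt")
  j <- which(!pre)[1L]
  iPj <- j - tau
  if (iPj < 1L || iPj > nrow(P))
    stop("first post-bleach point falls outside the average trajectory")
  jump <- aligned_x[j] - P$x[iPj]
  structure(list(aligned = data.frame(t = t_aligned, x = aligned_x,
                                      f = bleach_traj$f, pre = pre),
                 jump = jump, tau = tau, offset = offset),
            class = "bleach_alignment")
}

#' Axisymmetric membrane invagination profile
#'
#' A time-stamped polyline of (axial depth `z`, radius `rho`) points
#' describing the membrane shape as a surface of revolution about the
#' invagination axis; `z` runs from the flat-membrane base (0) to the tip.
#'
#' @param z axial depth from the flat membrane level (nm; non-decreasing).
#' @param rho radius (nm; >= 0).
#' @param time profile time stamp (s), if known.
#' @param id profile identifier.
#' @return A data frame of class `membrane_profile`.
#' @export
membrane_profile <- function(z, rho, time = NA_real_, id = "profile") {
  stopifnot(length(z) == length(rho), length(z) >= 2L)
  if (any(diff(z) < 0)) stop("profile '", id, "': z must be non-decreasing")
  if (any(z < 0) || any(rho < 0))
    stop("profile '", id, "': z and rho must be >= 0")
  structure(data.frame(z = z, rho = rho),
            time = time, id = id,
            class = c("membrane_profile", "data.frame"))
}

profile_arclength <- function(profile) {
  c(0, cumsum(sqrt(diff(profile$z)^2 + diff(profile$rho)^2)))
}

#' Register membrane profiles to the trajectory frame
#'
#' CLEM-derived membrane intermediates carry no absolute clock; they are
#' placed in time by the coat centroid. The position origin is the initial
#' centroid of the tip-bound coat protein (Sla2), taken to lie at the flat
#' membrane level. For each profile, the centre of mass of the coat is
#' modelled as a band of arclength `tip_band` at the invagination tip
#' (surface-area weighted axial mean); the profile is assigned the time at
#' which the coat centroid passes that depth. Finally the clock is shifted
#' so that the peak of the BAR-protein (Rvs) molecule curve — the
#' operational scission time — is t = 0.
#'
#' @param profiles list of [membrane_profile()] objects, ordered by
#'   morphological progression.
#' @param sla2 the coat protein's aligned trajectory (columns `t` and the
#'   inward coordinate `x`).
#' @param rvs_curve a `molecule_curve` for the BAR protein, on the same
#'   clock as `sla2`.
#' @param tip_band coat coverage extent at the tip, as a length interval
#'   (nm); its midpoint is used.
#' @param origin_offset distance (nm) of the initial coat centroid from
#'   the membrane surface (default 0).
#' @return A list of class `profile_registration` with `origin` (nm),
#'   `times` (data frame: profile id, assigned absolute time, time
#'   relative to scission, tip centre-of-mass depth, placed flag) and
#'   `scission_time` (s, absolute clock).
#' @export
register_membrane_profiles <- function(profiles, sla2, rvs_curve,
                                       tip_band = c(30, 40),
                                       origin_offset = 0) {
  L <- mean(tip_band)
  origin <- sla2$x[1L] - origin_offset
  depth_needed <- vapply(profiles, function(pr) {
    s <- profile_arclength(pr)
    total <- s[length(s)]
    if (max(pr$z) <= 1e-9) return(0)  # flat profile
    band <- c(max(0, total - L), total)
    band_centroid_z(pr, band[1L], band[2L])
  }, numeric(1))
  x_rel <- sla2$x - sla2$x[1L]
  assign_time <- function(target) {
    if (target <= 0) return(sla2$t[1L])
    hit <- which(x_rel >= target)
    hit <- hit[hit > 1L]
    if (!length(hit)) return(NA_real_)
    j <- hit[1L]
    # linear interpolation of the first crossing
    frac <- (target - x_rel[j - 1L]) / (x_rel[j] - x_rel[j - 1L])
    sla2$t[j - 1L] + frac * (sla2$t[j] - sla2$t[j - 1L])
  }
  times <- vapply(depth_needed, assign_time, numeric(1))
  unplaced <- is.na(times)
  if (any(unplaced))
    warning(sum(unplaced), " profile(s) unplaced: the coat centroid never ",
            "reaches their tip centre of mass", call. = FALSE)
  scission <- rvs_curve$t[which.max(rvs_curve$n)]
  structure(list(origin = origin,
                 times = data.frame(
                   profile = vapply(profiles, attr, "", which = "id"),
                   time = times,
                   time_rel_scission = times - scission,
                   tip_com_depth = depth_needed,
                   placed = !unplaced),
                 scission_time = scission),
            class = "profile_registration")
}
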