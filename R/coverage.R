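#' BAR-dimer packing model
#'
#' BAR-domain dimers are ~13 nm long and decorate membrane tubules as
#' spirals spaced by 5 nm, so each dimer is modelled as occupying a
#' 13 nm x 5 nm rectangle of membrane surface. Only one subunit of the
#' Rvs161/167 heterodimer carries the fluorophore, so by default two
#' counted molecules correspond to one dimer... set `molecules_per_dimer`
#' to 1 to count every tagged molecule as its own dimer.
#'
#' @param dimer_length dimer footprint length (nm).
#' @param spiral_spacing spacing between adjacent spiral turns (nm).
#' @param molecules_per_dimer tagged molecules per dimer (default 2:
#'   counted molecules are halved into dimers).
#' @return A list of class `packing_model` with `area_per_dimer` (nm^2).
#' @export
packing_model <- function(dimer_length = 13, spiral_spacing = 5,
                          molecules_per_dimer = 2) {
  stopifnot(dimer_length > 0, spiral_spacing > 0, molecules_per_dimer > 0)
  structure(list(dimer_length = dimer_length,
                 spiral_spacing = spiral_spacing,
                 molecules_per_dimer = molecules_per_dimer,
                 area_per_dimer = dimer_length * spiral_spacing),
            class = "packing_model")
}

# cumulative area and first-moment integrals along the profile polyline;
# rho and z are linear in arclength on each segment, so Simpson's rule is
# exact for the quadratic integrands
profile_integrals <- function(profile) {
  s <- profile_arclength(profile)
  n <- length(s)
  ds <- diff(s)
  ra <- profile$rho[-n]; rb <- profile$rho[-1L]
  za <- profile$z[-n];  zb <- profile$z[-1L]
  seg_area <- 2 * pi * (ra + rb) / 2 * ds
  rm <- (ra + rb) / 2; zm <- (za + zb) / 2
  seg_zmom <- 2 * pi * ds / 6 * (ra * za + 4 * rm * zm + rb * zb)
  list(s = s, cum_area = c(0, cumsum(seg_area)),
       cum_zmom = c(0, cumsum(seg_zmom)), total = s[n])
}

interp_cum <- function(s_grid, cum, s) {
  stats::approx(s_grid, cum, xout = s, rule = 2)$y
}

#' Membrane area of an arclength band on an invagination profile
#'
#' The profile is a surface of revolution; the band area is
#' \eqn{\int_{s_0}^{s_1} 2\pi \rho(s)\, ds} with \eqn{\rho} linear in
#' arclength on each polyline segment (exact piecewise quadrature).
#'
#' @param profile a [membrane_profile()].
#' @param s0,s1 arclength interval from the base (nm).
#' @return Band area (nm^2).
#' @export
band_area <- function(profile, s0, s1) {
  pint <- profile_integrals(profile)
  if (s0 < -1e-9 || s1 > pint$total + 1e-9 || s0 > s1)
    stop("band [", s0, ", ", s1, "] outside the profile arclength range [0, ",
         signif(pint$total, 6), "]")
  interp_cum(pint$s, pint$cum_area, s1) - interp_cum(pint$s, pint$cum_area, s0)
}

band_centroid_z <- function(profile, s0, s1) {
  pint <- profile_integrals(profile)
  a <- interp_cum(pint$s, pint$cum_area, s1) -
       interp_cum(pint$s, pint$cum_area, s0)
  if (a <= 0) {
    # degenerate band: fall back to the axial midpoint
    zz <- stats::approx(pint$s, profile$z, xout = (s0 + s1) / 2, rule = 2)$y
    return(zz)
  }
  m <- interp_cum(pint$s, pint$cum_zmom, s1) -
       interp_cum(pint$s, pint$cum_zmom, s0)
  m / a
}

#' Place the BAR coverage band on an invagination profile
#'
#' Assuming all counted molecules are membrane bound and homogeneously
#' distributed, the covered area is (dimer count) x (area per dimer).
#' Among all contiguous arclength bands of that area the one whose
#' surface-weighted axial centre of mass is closest to the tracked
#' centroid position is returned. When the molecule-count uncertainty is
#' given, bands for `n - dn` and `n + dn` molecules are reported as the
#' lower and upper coverage bounds.
#'
#' @param profile a [membrane_profile()].
#' @param n_molecules counted molecules (>= 0).
#' @param centroid_z axial position of the tracked centroid (nm, from the
#'   flat membrane level).
#' @param packing a [packing_model()].
#' @param dn_molecules optional standard error of the molecule count.
#' @param grid_step search grid step along arclength (nm).
#' @return A list of class `coverage_band` with `s0`, `s1` (nm), `area`
#'   (nm^2), `com_z` (nm), `dimers`, `clipped` flag, and optionally
#'   `lower` / `upper` bands.
#' @export
place_coverage <- function(profile, n_molecules, centroid_z,
                           packing = packing_model(), dn_molecules = NULL,
                           grid_step = 0.25) {
  stopifnot(n_molecules >= 0)
  place_one <- function(n) {
    dimers <- n / packing$molecules_per_dimer
    target <- dimers * packing$area_per_dimer
    pint <- profile_integrals(profile)
    total_area <- pint$cum_area[length(pint$cum_area)]
    if (target <= 0)
      return(structure(list(s0 = 0, s1 = 0, area = 0, com_z = NA_real_,
                            dimers = 0, clipped = FALSE),
                       class = "coverage_band"))
    if (target >= total_area) {
      warning("required area ", round(target), " nm^2 exceeds the profile ",
              "area ", round(total_area), " nm^2: band clipped",
              call. = FALSE)
      return(structure(list(s0 = 0, s1 = pint$total, area = total_area,
                            com_z = band_centroid_z(profile, 0, pint$total),
                            dimers = dimers, clipped = TRUE),
                       class = "coverage_band"))
    }
    # dense arclength grid of candidate band starts; the matching band end
    # is read off the cumulative area
    sg <- seq(0, pint$total, by = grid_step)
    a0 <- interp_cum(pint$s, pint$cum_area, sg)
    ok <- a0 + target <= total_area
    s0s <- sg[ok]
    s1s <- stats::approx(pint$cum_area, pint$s, xout = a0[ok] + target,
                         rule = 2)$y
    m0 <- interp_cum(pint$s, pint$cum_zmom, s0s)
    m1 <- interp_cum(pint$s, pint$cum_zmom, s1s)
    com <- (m1 - m0) / target
    k <- which.min(abs(com - centroid_z))
    structure(list(s0 = s0s[k], s1 = s1s[k], area = target,
                   com_z = com[k], dimers = dimers, clipped = FALSE),
              class = "coverage_band")
  }
  out <- place_one(n_molecules)
  if (!is.null(dn_molecules) && dn_molecules > 0) {
    out$lower <- place_one(max(0, n_molecules - dn_molecules))
    out$upper <- place_one(n_molecules + dn_molecules)
  }
  out
}

#' @export
print.coverage_band <- function(x, ...) {
  cat(sprintf(paste0("coverage band: s = [%.1f, %.1f] nm, area = %.0f nm^2,",
                     " %.1f dimers, com z = %.1f nm%s\n"),
              x$s0, x$s1, x$area, x$dimers,
              ifelse(is.na(x$com_z), NaN, x$com_z),
              if (isTRUE(x$clipped)) " (clipped)" else ""))
  invisible(x)
}

#' Interpolate or extrapolate a membrane profile in time
#'
#' Profiles are reparameterised by arclength fraction onto a common vertex
#' count (the largest input count) and interpolated vertexwise, linearly
#' in time. Extrapolation is allowed up to one inter-profile interval
#' beyond the observed time span.
#'
#' @param profiles list of time-stamped [membrane_profile()] objects
#'   (>= 2).
#' @param t target time (s).
#' @return The interpolated [membrane_profile()] at time `t`.
#' @export
extrapolate_profile <- function(profiles, t) {
  stopifnot(length(profiles) >= 2L)
  times <- vapply(profiles, attr, numeric(1), which = "time")
  if (anyNA(times)) stop("all profiles must carry a time stamp")
  o <- order(times)
  profiles <- profiles[o]; times <- times[o]
  span <- range(times)
  iv <- diff(times)
  margin <- if (t < span[1L]) iv[1L] else iv[length(iv)]
  if (t < span[1L] - margin - 1e-9 || t > span[2L] + margin + 1e-9)
    stop("t = ", t, " s is more than one inter-profile interval beyond the ",
         "observed span [", span[1L], ", ", span[2L], "] s")
  K <- max(vapply(profiles, nrow, integer(1)))
  resampled <- lapply(profiles, function(pr) {
    s <- profile_arclength(pr)
    frac <- if (s[length(s)] > 0) s / s[length(s)] else
      seq(0, 1, length.out = length(s))
    fg <- seq(0, 1, length.out = K)
    cbind(z = stats::approx(frac, pr$z, xout = fg, rule = 2)$y,
          rho = stats::approx(frac, pr$rho, xout = fg, rule = 2)$y)
  })
  zmat <- sapply(resampled, function(m) m[, "z"])
  rmat <- sapply(resampled, function(m) m[, "rho"])
  lin <- function(vals) {
    # vertexwise linear interpolation/extrapolation in time
    if (t <= times[1L]) {
      a <- 1L; b <- 2L
    } else if (t >= times[length(times)]) {
      a <- length(times) - 1L; b <- length(times)
    } else {
      b <- which(times >= t)[1L]; a <- b - 1L
    }
    u <- (t - times[a]) / (times[b] - times[a])
    vals[, a] + u * (vals[, b] - vals[, a])
  }
  z <- lin(zmat); rho <- pmax(lin(rmat), 0)
  z <- cummax(z)  # guard monotonicity against extrapolation overshoot
  membrane_profile(z, rho, time = t,
                   id = sprintf("interpolated_t%+g", t))
}
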