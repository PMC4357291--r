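#' Construct a patch centroid trajectory
#'
#' A trajectory is the time-ordered record of one endocytic patch: centroid
#' coordinates in the focal plane and the background-corrected fluorescence
#' intensity of the spot. Internal units are fixed to nanometres and
#' seconds.
#'
#' @param t sampling times (s); strictly increasing and uniformly spaced.
#' @param x,y centroid coordinates (nm).
#' @param f fluorescence intensity (arbitrary units, >= 0).
#' @param id trajectory identifier.
#' @param channel acquisition channel label.
#' @param complete logical; `TRUE` when both the appearance and the
#'   disappearance of the patch were observed within the movie.
#' @return A data frame of class `trajectory` with columns `t`, `x`, `y`,
#'   `f` and attributes `id`, `channel`, `dt`, `complete`.
#' @export
trajectory <- function(t, x, y, f, id = "traj", channel = NA_character_,
                       complete = NA) {
  t <- as.numeric(t); x <- as.numeric(x)
  y <- as.numeric(y); f <- as.numeric(f)
  n <- length(t)
  if (n < 2L)
    stop("trajectory '", id, "': at least 2 points are required")
  if (length(x) != n || length(y) != n || length(f) != n)
    stop("trajectory '", id, "': t, x, y, f must have equal length")
  if (anyNA(t) || any(!is.finite(t)))
    stop("trajectory '", id, "': non-finite time stamps")
  dts <- diff(t)
  if (any(dts <= 0))
    stop("trajectory '", id, "': time stamps must be strictly increasing")
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6))
    stop("trajectory '", id, "': sampling interval is not uniform (dt = ",
         signif(dt, 6), ")")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("trajectory '", id, "': non-finite coordinates")
  if (any(!is.finite(f)) || any(f < 0))
    stop("trajectory '", id, "': fluorescence must be finite and >= 0")
  structure(data.frame(t = t, x = x, y = y, f = f),
            id = id, channel = channel, dt = dt, complete = complete,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s' (%s): %d points, dt = %g s, span %g s\n",
              attr(x, "id"),
              ifelse(is.na(attr(x, "channel")), "-", attr(x, "channel")),
              nrow(x), attr(x, "dt"), x$t[nrow(x)] - x$t[1L]))
  invisible(x)
}

#' Declare the units and layout of a trajectory table
#'
#' File dialects declare their units; values are converted to the internal
#' nm / s convention on read. Coordinates may be given in nm, micrometres or
#' pixels (with `px_nm` nanometres per pixel); time may be given in seconds
#' or frame numbers (with `dt` seconds per frame).
#'
#' @param sep field separator (`"\t"` default, `","` accepted).
#' @param xy_unit one of `"nm"`, `"um"`, `"px"`.
#' @param t_unit one of `"s"`, `"frame"`.
#' @param px_nm pixel size (nm), required when `xy_unit = "px"`.
#' @param dt frame interval (s), required when `t_unit = "frame"`.
#' @return A list of class `trajectory_dialect`.
#' @export
trajectory_dialect <- function(sep = "\t", xy_unit = c("nm", "um", "px"),
                               t_unit = c("s", "frame"), px_nm = NULL,
                               dt = NULL) {
  xy_unit <- match.arg(xy_unit)
  t_unit <- match.arg(t_unit)
  if (xy_unit == "px" && is.null(px_nm))
    stop("xy_unit = 'px' requires px_nm")
  if (t_unit == "frame" && is.null(dt))
    stop("t_unit = 'frame' requires dt")
  structure(list(sep = sep, xy_unit = xy_unit, t_unit = t_unit,
                 px_nm = px_nm, dt = dt),
            class = "trajectory_dialect")
}

xy_factor <- function(dialect) {
  switch(dialect$xy_unit, nm = 1, um = 1e3, px = dialect$px_nm)
}

t_factor <- function(dialect) {
  switch(dialect$t_unit, s = 1, frame = dialect$dt)
}

#' Read patch trajectories from a delimited table
#'
#' Expects columns `id`, `t`, `x`, `y`, `f` and optionally `channel` and
#' `complete`. Each id is validated against the trajectory invariants
#' (strictly increasing, uniformly sampled time; non-negative fluorescence;
#' at least two points).
#'
#' @param path file path.
#' @param dialect a [trajectory_dialect()] describing separator and units.
#' @param movie_frames total frame count of the source movie; when given
#'   (and the dialect carries a frame interval) trajectories touching the
#'   first or last frame are flagged incomplete.
#' @return A list of [trajectory()] objects, named by id.
#' @export
read_trajectories <- function(path, dialect = trajectory_dialect(),
                              movie_frames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "t", "x", "y", "f")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("trajectory table misses column(s): ",
         paste(missing_cols, collapse = ", "))
  fx <- xy_factor(dialect)
  ft <- t_factor(dialect)
  ids <- unique(tab$id)
  out <- lapply(ids, function(one) {
    sub <- tab[tab$id == one, , drop = FALSE]
    tt <- sub$t * ft
    complete <- NA
    if (!is.null(movie_frames) && !is.null(dialect$dt)) {
      first <- min(sub$t); last <- max(sub$t)
      complete <- first > 0 && last < (movie_frames - 1)
    }
    if ("complete" %in% names(sub)) complete <- as.logical(sub$complete[1L])
    trajectory(tt, sub$x * fx, sub$y * fx, sub$f, id = as.character(one),
               channel = if ("channel" %in% names(sub))
                 as.character(sub$channel[1L]) else NA_character_,
               complete = complete)
  })
  names(out) <- as.character(ids)
  out
}

#' Write trajectories to a delimited table
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the numbers bit for bit.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, sep = "\t") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("id", "channel", "t", "x", "y", "f", "complete")
  writeLines(paste(header, collapse = sep), con)
  for (tr in trajs) {
    lines <- paste(attr(tr, "id"), attr(tr, "channel"),
                   sprintf("%.17g", tr$t), sprintf("%.17g", tr$x),
                   sprintf("%.17g", tr$y), sprintf("%.17g", tr$f),
                   attr(tr, "complete"), sep = sep)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Cohort configuration
#'
#' Settings shared by the smoothing and averaging steps.
#'
#' @param smoothing one of `"savitzky_golay"`, `"moving_average"`, `"none"`.
#' @param window filter window length (frames); odd and >= 3 for
#'   Savitzky-Golay.
#' @param order Savitzky-Golay polynomial order (< window).
#' @param invagination_only logical; when `TRUE`, pairwise alignment costs
#'   use only points up to each trajectory's fluorescence peak (the rule
#'   used for the abundant reference-protein cohorts whose post-scission
#'   tail is uninformative).
#' @param min_overlap minimum number of overlapping frames for a lag to be
#'   admissible in pairwise alignment.
#' @param recenter logical; re-centre the cohort average at its
#'   fluorescence-weighted centre of mass.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(smoothing = c("savitzky_golay", "moving_average",
                                        "none"),
                          window = 11L, order = 3L,
                          invagination_only = FALSE, min_overlap = 5L,
                          recenter = TRUE) {
  smoothing <- match.arg(smoothing)
  window <- as.integer(window)
  order <- as.integer(order)
  if (smoothing == "savitzky_golay") {
    if (window < 3L || window %% 2L == 0L)
      stop("Savitzky-Golay window must be odd and >= 3")
    if (order >= window) stop("polynomial order must be < window")
  }
  if (smoothing == "moving_average" && window < 1L)
    stop("moving-average window must be >= 1")
  structure(list(smoothing = smoothing, window = window, order = order,
                 invagination_only = invagination_only,
                 min_overlap = as.integer(min_overlap),
                 recenter = isTRUE(recenter)),
            class = "cohort_config")
}

moving_average_shrink <- function(v, window) {
  # centred moving average; the window shrinks symmetrically at the ends
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    mean(v[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Smooth a trajectory
#'
#' Filters `x`, `y` and `f` independently; time stamps are unchanged.
#' Savitzky-Golay filtering uses [signal::sgolayfilt()] (boundary points are
#' fitted with the same local polynomial); the moving average shrinks its
#' window symmetrically at the boundaries.
#'
#' @param traj a [trajectory()].
#' @param cfg a [cohort_config()]; only the smoothing fields are used.
#' @return The smoothed [trajectory()].
#' @export
smooth_trajectory <- function(traj, cfg = cohort_config()) {
  if (cfg$smoothing == "none") return(traj)
  if (nrow(traj) < cfg$window)
    stop("trajectory '", attr(traj, "id"), "' is shorter (", nrow(traj),
         ") than the smoothing window (", cfg$window, ")")
  filt <- switch(cfg$smoothing,
    savitzky_golay = function(v) signal::sgolayfilt(v, p = cfg$order,
                                                    n = cfg$window),
    moving_average = function(v) moving_average_shrink(v, cfg$window))
  trajectory(traj$t, filt(traj$x), filt(traj$y), pmax(filt(traj$f), 0),
             id = attr(traj, "id"), channel = attr(traj, "channel"),
             complete = attr(traj, "complete"))
}

#' Patch lifetimes from complete trajectories
#'
#' The lifetime of a patch is the time difference between the first and the
#' last point of its trajectory. Only complete trajectories are used, and
#' only those that start within the initial stretch of the movie covering
#' about three times the known lifetime of the protein; this limits the
#' photobleaching suffered by the patches that are measured. Truncation by
#' the finite movie makes the resulting mean an underestimate of the true
#' mean lifetime.
#'
#' @param cohort list of [trajectory()] objects with their `complete` flag
#'   set.
#' @param known_lifetime prior estimate of the patch lifetime (s).
#' @param movie_length movie length (frames).
#' @param lifetime_factor size of the admission window in units of
#'   `known_lifetime` (default 3).
#' @return Numeric vector of lifetimes (s), one per admitted trajectory.
#' @export
patch_lifetimes <- function(cohort, known_lifetime, movie_length,
                            lifetime_factor = 3) {
  if (known_lifetime <= 0) stop("known_lifetime must be > 0")
  if (inherits(cohort, "trajectory")) cohort <- list(cohort)
  window_s <- lifetime_factor * known_lifetime
  out <- vapply(cohort, function(tr) {
    if (!isTRUE(attr(tr, "complete"))) return(NA_real_)
    if (!is.null(movie_length))
      window_s <- min(window_s, movie_length * attr(tr, "dt"))
    if (tr$t[1L] > window_s) return(NA_real_)
    tr$t[nrow(tr)] - tr$t[1L]
  }, numeric(1))
  out[!is.na(out)]
}
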