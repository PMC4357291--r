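#' Chromatic registration warp from bead control points
#'
#' Two-colour acquisitions image the same field through two optical paths;
#' multicolour beads (e.g. TetraSpeck microspheres) visible in both
#' channels provide matched control points from which a warp mapping
#' channel-B coordinates onto channel-A coordinates is built. Two warp
#' types are supported: a global affine map, and the local weighted mean
#' (lwm) method, in which a second-order polynomial is fitted around every
#' control point over its `n_neighbors` nearest neighbours and an arbitrary
#' point is mapped by the weighted mean of the polynomials whose radius of
#' influence covers it (weight \eqn{1 - 3R^2 + 2R^3} with `R` the distance
#' to the control point over its neighbourhood radius).
#'
#' @param beads_a,beads_b two-column matrices of matched bead centroids
#'   (nm) in channel A and channel B.
#' @param type `"affine"` or `"lwm"`.
#' @param n_neighbors neighbourhood size for `"lwm"` (>= 6, the number of
#'   second-order polynomial coefficients).
#' @return A list of class `warp_model` with the fitted mapping, its type,
#'   and leave-one-out residuals (`loo_residuals`, nm; `loo_rms`, nm).
#' @export
build_warp <- function(beads_a, beads_b, type = c("affine", "lwm"),
                       n_neighbors = 12L) {
  type <- match.arg(type)
  beads_a <- as.matrix(beads_a); beads_b <- as.matrix(beads_b)
  stopifnot(ncol(beads_a) == 2L, ncol(beads_b) == 2L,
            nrow(beads_a) == nrow(beads_b))
  m <- nrow(beads_a)
  if (type == "affine") {
    if (m < 3L) stop("affine warp needs >= 3 control points")
    X <- cbind(1, beads_b)
    if (qr(X)$rank < 3L)
      stop("degenerate (collinear) control points: affine warp undefined")
    coefs <- qr.solve(X, beads_a)
    model <- list(coefs = coefs)
  } else {
    n_neighbors <- as.integer(min(n_neighbors, m))
    if (n_neighbors < 6L)
      stop("lwm warp needs >= 6 control points in each neighbourhood")
    model <- lwm_fit(beads_a, beads_b, n_neighbors)
  }
  out <- structure(list(type = type, model = model, beads_a = beads_a,
                        beads_b = beads_b, n_neighbors = n_neighbors),
                   class = "warp_model")
  loo <- rep(NA_real_, m)
  min_m <- if (type == "affine") 4L else n_neighbors + 1L
  if (m >= min_m) {
    for (i in seq_len(m)) {
      sub <- tryCatch(
        build_warp_nolloo(beads_a[-i, , drop = FALSE],
                          beads_b[-i, , drop = FALSE], type, n_neighbors),
        error = function(e) NULL)
      if (is.null(sub)) next
      pred <- predict_warp(sub, beads_b[i, , drop = FALSE])
      loo[i] <- sqrt(sum((pred - beads_a[i, ])^2))
    }
  }
  out$loo_residuals <- loo
  out$loo_rms <- if (all(is.na(loo))) NA_real_ else
    sqrt(mean(loo^2, na.rm = TRUE))
  out
}

build_warp_nolloo <- function(beads_a, beads_b, type, n_neighbors) {
  if (type == "affine") {
    X <- cbind(1, beads_b)
    if (qr(X)$rank < 3L) stop("degenerate control points")
    structure(list(type = "affine", model = list(coefs = qr.solve(X, beads_a)),
                   beads_a = beads_a, beads_b = beads_b),
              class = "warp_model")
  } else {
    n_neighbors <- as.integer(min(n_neighbors, nrow(beads_a)))
    structure(list(type = "lwm",
                   model = lwm_fit(beads_a, beads_b, n_neighbors),
                   beads_a = beads_a, beads_b = beads_b),
              class = "warp_model")
  }
}

poly2_design <- function(xy) {
  cbind(1, xy[, 1L], xy[, 2L], xy[, 1L]^2, xy[, 1L] * xy[, 2L], xy[, 2L]^2)
}

lwm_fit <- function(beads_a, beads_b, n_neighbors) {
  m <- nrow(beads_b)
  polys <- vector("list", m)
  radii <- numeric(m)
  for (i in seq_len(m)) {
    d <- sqrt((beads_b[, 1L] - beads_b[i, 1L])^2 +
              (beads_b[, 2L] - beads_b[i, 2L])^2)
    nb <- order(d)[seq_len(n_neighbors)]
    radii[i] <- max(d[nb])
    X <- poly2_design(beads_b[nb, , drop = FALSE])
    polys[[i]] <- tryCatch(qr.solve(X, beads_a[nb, , drop = FALSE]),
                           error = function(e) NULL)
  }
  list(polys = polys, radii = radii, centers = beads_b)
}

#' Apply a chromatic warp to coordinates
#'
#' @param warp a `warp_model` from [build_warp()].
#' @param xy two-column matrix of channel-B coordinates (nm).
#' @return Matrix of coordinates mapped into channel A.
#' @export
predict_warp <- function(warp, xy) {
  xy <- as.matrix(xy)
  if (warp$type == "affine")
    return(cbind(1, xy) %*% warp$model$coefs)
  ctr <- warp$model$centers
  out <- matrix(NA_real_, nrow(xy), 2L)
  for (j in seq_len(nrow(xy))) {
    d <- sqrt((ctr[, 1L] - xy[j, 1L])^2 + (ctr[, 2L] - xy[j, 2L])^2)
    r <- d / warp$model$radii
    w <- ifelse(r < 1, 1 - 3 * r^2 + 2 * r^3, 0)
    w[vapply(warp$model$polys, is.null, logical(1))] <- 0
    if (sum(w) <= 0) {
      # outside every radius of influence: fall back to the nearest
      # control point's polynomial
      k <- which.min(d)
      w[k] <- 1
    }
    X <- poly2_design(xy[j, , drop = FALSE])
    acc <- c(0, 0)
    for (k in which(w > 0))
      acc <- acc + w[k] * as.numeric(X %*% warp$model$polys[[k]])
    out[j, ] <- acc / sum(w)
  }
  out
}

#' Chromatic-correct a trajectory
#'
#' @param traj a [trajectory()] in channel-B coordinates.
#' @param warp a `warp_model`.
#' @return The trajectory with coordinates mapped into channel A.
#' @export
warp_trajectory <- function(traj, warp) {
  xy <- predict_warp(warp, cbind(traj$x, traj$y))
  trajectory(traj$t, xy[, 1L], xy[, 2L], traj$f, id = attr(traj, "id"),
             channel = attr(traj, "channel"),
             complete = attr(traj, "complete"))
}
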