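#' Planar isometric transforms
#'
#' An isometric transform of the focal plane combines a rotation by `theta`
#' about the origin with a translation `(tx, ty)`:
#' \deqn{T: (x, y) \to (\cos\theta\, x - \sin\theta\, y + T^x,\;
#'                      \sin\theta\, x + \cos\theta\, y + T^y).}
#' These transforms carry individual patch trajectories into a common frame
#' and, in the two-colour procedure, carry a target average trajectory onto
#' the reference frame.
#'
#' @param theta rotation angle (rad).
#' @param tx,ty translation (nm).
#' @return An object of class `iso_transform`.
#' @examples
#' T1 <- iso_transform(pi / 2, 10, 0)
#' apply_transform(T1, cbind(1, 0))
#' @export
iso_transform <- function(theta = 0, tx = 0, ty = 0) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty))
  structure(list(theta = theta, tx = tx, ty = ty), class = "iso_transform")
}

#' @export
print.iso_transform <- function(x, ...) {
  cat(sprintf("iso_transform: theta = %.6g rad, t = (%.6g, %.6g) nm\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

#' Apply an isometric transform to points
#'
#' @param transform an [iso_transform()].
#' @param xy two-column matrix (or data frame) of coordinates (nm).
#' @return Matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  ct <- cos(transform$theta)
  st <- sin(transform$theta)
  cbind(ct * xy[, 1L] - st * xy[, 2L] + transform$tx,
        st * xy[, 1L] + ct * xy[, 2L] + transform$ty)
}

#' Invert an isometric transform
#'
#' @param transform an [iso_transform()].
#' @return The inverse `iso_transform`.
#' @export
invert_transform <- function(transform) {
  ct <- cos(transform$theta)
  st <- sin(transform$theta)
  # inverse rotation applied to the negated translation
  iso_transform(-transform$theta,
                -( ct * transform$tx + st * transform$ty),
                -(-st * transform$tx + ct * transform$ty))
}

#' Compose two isometric transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b [iso_transform()] objects.
#' @return The composed `iso_transform`.
#' @export
compose_transforms <- function(a, b) {
  tb <- apply_transform(a, cbind(b$tx, b$ty))
  iso_transform(a$theta + b$theta, tb[1L, 1L], tb[1L, 2L])
}

#' Weighted rigid 2D registration (closed form)
#'
#' Finds the planar rotation + translation minimising the weighted mean
#' squared residual
#' \deqn{\sum_i w_i \lVert q_i - T(p_i)\rVert^2 / \sum_i w_i}
#' over all isometric transforms. The solution is closed form: with
#' weighted-centred coordinates \eqn{p', q'}, the angle is
#' \eqn{\theta = \mathrm{atan2}(\sum w (p'_x q'_y - p'_y q'_x),
#' \sum w (p'_x q'_x + p'_y q'_y))} and the translation maps the weighted
#' centroid of the source onto the weighted centroid of the target.
#'
#' @param source,target two-column matrices of matched points (nm).
#' @param w non-negative weights, one per point pair.
#' @return An `iso_transform` with attributes `cost` (weighted mean squared
#'   residual, nm^2) and `n` (number of point pairs with positive weight).
#'   A single effective point yields a translation-only transform
#'   (`theta = 0`), the documented degenerate case.
#' @export
fit_rigid_weighted <- function(source, target, w = NULL) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  stopifnot(ncol(source) == 2L, ncol(target) == 2L,
            nrow(source) == nrow(target))
  n <- nrow(source)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  sw <- sum(w)
  if (sw <= 0) stop("all weights are zero: rigid fit is undefined")
  wn <- w / sw
  cp <- c(sum(wn * source[, 1L]), sum(wn * source[, 2L]))
  cq <- c(sum(wn * target[, 1L]), sum(wn * target[, 2L]))
  px <- source[, 1L] - cp[1L]; py <- source[, 2L] - cp[2L]
  qx <- target[, 1L] - cq[1L]; qy <- target[, 2L] - cq[2L]
  s1 <- sum(wn * (px * qx + py * qy))
  s2 <- sum(wn * (px * qy - py * qx))
  theta <- if (s1 == 0 && s2 == 0) 0 else atan2(s2, s1)
  ct <- cos(theta); st <- sin(theta)
  tr <- iso_transform(theta,
                      cq[1L] - (ct * cp[1L] - st * cp[2L]),
                      cq[2L] - (st * cp[1L] + ct * cp[2L]))
  res <- target - apply_transform(tr, source)
  attr(tr, "cost") <- sum(wn * (res[, 1L]^2 + res[, 2L]^2))
  attr(tr, "n") <- sum(w > 0)
  tr
}
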