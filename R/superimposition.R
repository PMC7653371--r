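# Generalized Procrustes analysis for open-curve semi-landmark configurations.
# Translation and scale are removed by centering and unit centroid size;
# orientation by proper rotations only. Reflections are deliberately NOT
# removed: mirror-image sutures ('n' vs 'u' forms) are distinct morphologies
# and must stay apart in shape space. No semi-landmark sliding is applied.

#' Center a configuration and scale it to unit centroid size
#'
#' Centroid size is the root of the summed squared distances of all landmarks
#' to their centroid, the standard size measure removed by Procrustes
#' superimposition.
#'
#' @param shape Two-column coordinate matrix.
#' @return Matrix with centroid at the origin and centroid size 1.
#' @export
center_and_scale <- function(shape) {
  shape <- as.matrix(shape)
  ctr <- colMeans(shape)
  out <- sweep(shape, 2, ctr)
  cs <- sqrt(sum(out^2))
  if (cs == 0) stop("degenerate shape: all points identical")
  out / cs
}

#' Centroid size of a configuration
#' @param shape Two-column coordinate matrix.
#' @return Scalar centroid size.
#' @export
centroid_size <- function(shape) {
  shape <- as.matrix(shape)
  sqrt(sum(sweep(shape, 2, colMeans(shape))^2))
}

#' Rotate one configuration onto a reference
#'
#' Finds the proper rotation (determinant +1; reflections excluded) that
#' minimizes the sum of squared distances between corresponding landmarks,
#' via the singular value decomposition of the cross-covariance matrix.
#'
#' @param shape,reference Centered two-column coordinate matrices with equal
#'   point counts.
#' @return `shape` rotated onto `reference`.
#' @export
optimal_rotation <- function(shape, reference) {
  shape <- as.matrix(shape); reference <- as.matrix(reference)
  if (nrow(shape) != nrow(reference))
    stop("point count mismatch: ", nrow(shape), " vs ", nrow(reference))
  sv <- svd(crossprod(reference, shape))
  # force det(R) = +1 so mirror forms are not collapsed
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  shape %*% R
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of configurations: each is centered and
#' scaled to unit centroid size, then rotated onto the evolving consensus
#' until the consensus stops moving. Total Procrustes sum of squares is
#' non-increasing across iterations.
#'
#' @param shapes List of two-column coordinate matrices with identical point
#'   counts, or a list of [landmark_curve] objects.
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter Maximum number of alignment sweeps.
#' @return An object of class `procrustes_set`: list with `shapes` (aligned
#'   coordinate matrices), `mean_shape` (consensus, unit centroid size),
#'   `iterations`, `residual` (last consensus change) and `converged`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' th <- pi / 5
#' rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
#' fit <- gpa(list(sq, 3 * sq %*% rot + 2))
#' fit$residual
#' @export
gpa <- function(shapes, tol = 1e-8, max_iter = 100) {
  if (length(shapes) && inherits(shapes[[1]], "landmark_curve"))
    shapes <- lapply(shapes, function(cv) cv$coords)
  shapes <- lapply(shapes, as.matrix)
  if (length(shapes) < 2) stop("gpa needs at least 2 shapes")
  np <- vapply(shapes, nrow, integer(1))
  if (length(unique(np)) != 1)
    stop("all shapes must share one point count; got ",
         paste(unique(np), collapse = ", "))
  aligned <- lapply(shapes, center_and_scale)
  consensus <- aligned[[1]]
  residual <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(aligned, optimal_rotation, reference = consensus)
    new_consensus <- Reduce(`+`, aligned) / length(aligned)
    new_consensus <- new_consensus / sqrt(sum(sweep(new_consensus, 2, colMeans(new_consensus))^2))
    residual <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (residual < tol) break
  }
  structure(
    list(shapes = aligned, mean_shape = consensus,
         iterations = it, residual = residual,
         converged = residual < tol),
    class = "procrustes_set")
}

#' @export
print.procrustes_set <- function(x, ...) {
  cat("<procrustes_set> ", length(x$shapes), " shapes, ",
      nrow(x$mean_shape), " landmarks; ", x$iterations, " iterations, ",
      "residual ", format(x$residual, digits = 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Total Procrustes sum of squares around the consensus
#' @param ps A `procrustes_set`.
#' @return Scalar sum of squared deviations of all aligned shapes from the
#'   mean shape.
#' @export
procrustes_ss <- function(ps) {
  sum(vapply(ps$shapes, function(s) sum((s - ps$mean_shape)^2), numeric(1)))
}
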