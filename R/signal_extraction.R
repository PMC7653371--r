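# A suture outline enters the fractal and Fourier estimators as a 1D signal:
# the signed perpendicular offset of each semi-landmark from the endpoint
# chord, indexed by arc-length station. Indexing by station (not by
# x-projection) keeps looping sutures, whose y(x) is multi-valued, well
# defined: every curve yields exactly one value per station.

#' Transform a curve into its chord frame
#'
#' Rigid transform placing the first endpoint at the origin and the last
#' endpoint on the positive x-axis. All pairwise distances are preserved, so
#' the geometry is unchanged; only position and orientation are standardized.
#'
#' @param curve Two-column coordinate matrix or [landmark_curve].
#' @return Coordinate matrix in the chord frame.
#' @export
chord_frame <- function(curve) {
  xy <- if (inherits(curve, "landmark_curve")) curve$coords else as.matrix(curve)
  n <- nrow(xy)
  p1 <- xy[1, ]; pn <- xy[n, ]
  chord <- sqrt(sum((pn - p1)^2))
  if (chord == 0) stop("degenerate chord: curve endpoints coincide")
  out <- sweep(xy, 2, p1)
  co <- (pn[1] - p1[1]) / chord
  si <- (pn[2] - p1[2]) / chord
  R <- matrix(c(co, si, -si, co), 2, 2)  # rotates the chord onto +x
  out <- out %*% R
  out[1, ] <- c(0, 0)
  out[n, ] <- c(chord, 0)
  colnames(out) <- c("x", "y")
  out
}

#' Signed chord-deviation signal of a resampled curve
#'
#' Returns the y-coordinates of the curve in its chord frame, one value per
#' semi-landmark station. Stations are uniform in arc length when the curve
#' has been resampled with [resample_equidistant()], which the fractal and
#' spectral estimators assume. Endpoint values are exactly zero by
#' construction.
#'
#' @param curve Two-column coordinate matrix or [landmark_curve].
#' @return Object of class `deviation_signal`: list with `values` (numeric
#'   vector, length = number of stations), `chord_length`, and `n`.
#' @export
deviation_signal <- function(curve) {
  cf <- chord_frame(curve)
  structure(
    list(values = unname(cf[, 2]),
         chord_length = unname(cf[nrow(cf), 1]),
         n = nrow(cf)),
    class = "deviation_signal")
}

#' @export
print.deviation_signal <- function(x, ...) {
  cat("<deviation_signal> ", x$n, " stations, chord length ",
      format(x$chord_length, digits = 4), ", max |dev| ",
      format(max(abs(x$values)), digits = 4), "\n", sep = "")
  invisible(x)
}

as_signal_values <- function(signal) {
  if (inherits(signal, "deviation_signal")) signal$values
  else as.numeric(signal)
}

# Amplitude below which a signal counts as flat. A chord deviation signal is
# flat when its excursions are negligible against the chord (superimposition
# leaves ~1e-16 noise on straight sutures); a bare numeric vector has no
# external scale, so only an identically-zero vector is flat.
flat_tolerance <- function(signal) {
  if (inherits(signal, "deviation_signal")) 1e-9 * signal$chord_length else 0
}
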