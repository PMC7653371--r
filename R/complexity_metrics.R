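# The five complexity metrics. Each reduces an open suture outline to one
# dimensionless score, with larger meaning more complex:
#   SI      arc-chord ratio (sinuosity), >= 1, parameter-free
#   SCI     SI times a complexity factor from major/minor interdigitation lobes
#   FD_box  fractal dimension of the deviation-signal graph by box counting
#   FD_mad  fractal dimension by madogram (first-order variogram), D = 2 - H
#   PSD     windowed short-time Fourier transform power spectral density sum

#' Sinuosity index of a polyline
#'
#' Total path length (sum of Euclidean distances between consecutive
#' semi-landmarks) divided by the endpoint chord length. Equals 1 exactly for
#' a collinear polyline and grows without bound with interdigitation.
#' Invariant under similarity transforms.
#'
#' @param curve Two-column coordinate matrix or [landmark_curve].
#' @return Scalar >= 1.
#' @examples
#' sinuosity_index(cbind(0:2, c(0, 1, 0)))  # 2*sqrt(2)/2
#' @export
sinuosity_index <- function(curve) {
  xy <- if (inherits(curve, "landmark_curve")) curve$coords else as.matrix(curve)
  n <- nrow(xy)
  chord <- sqrt(sum((xy[n, ] - xy[1, ])^2))
  if (chord == 0) stop("degenerate chord: curve endpoints coincide")
  # path >= chord mathematically; guard against fp undershoot on collinear input
  max(1, sum(sqrt(rowSums(diff(xy)^2))) / chord)
}

# Topographic prominence of each interior local maximum of v.
# For a peak, prominence = height minus the higher of the two saddle minima
# reached before a strictly higher point (or the series end) on each side.
peak_prominences <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(diff(sign(diff(v))) < 0) + 1L
  # plateaus: diff(sign(diff())) misses flat tops; extend via run handling
  if (!length(idx)) return(data.frame(index = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- v[i]
    left <- if (i > 1) v[1:(i - 1)] else numeric(0)
    higher <- which(left > h)
    lbase <- min(left[if (length(higher)) (max(higher) + 1):length(left) else seq_along(left)])
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    higher <- which(right > h)
    rbase <- min(right[if (length(higher)) 1:(min(higher) - 1) else seq_along(right)])
    h - max(lbase, rbase)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Count major and minor interdigitation lobes
#'
#' Lobes are local excursions of the deviation signal on either side of the
#' chord. Both crests (maxima) and troughs (minima) count. A lobe is rated by
#' its topographic prominence relative to the signal's maximum absolute
#' amplitude A: prominence >= `major_frac * A` makes a major lobe; prominence
#' in `[minor_frac, major_frac) * A` a minor lobe; smaller excursions are
#' treated as digitization noise and not counted. Prominence is used rather
#' than raw height because it is stable under reparametrization and baseline
#' shifts.
#'
#' @param signal A [deviation_signal()] or numeric vector.
#' @param major_frac,minor_frac Prominence thresholds as fractions of the
#'   maximum absolute amplitude; `0 < minor_frac < major_frac <= 1`.
#' @return Named integer vector `c(major = ..., minor = ...)`.
#' @export
detect_lobes <- function(signal, major_frac = 0.5, minor_frac = 0.05) {
  if (!(minor_frac > 0 && minor_frac < major_frac && major_frac <= 1))
    stop("need 0 < minor_frac < major_frac <= 1")
  v <- as_signal_values(signal)
  A <- max(abs(v))
  if (A <= flat_tolerance(signal)) return(c(major = 0L, minor = 0L))
  ex <- rbind(peak_prominences(v), peak_prominences(-v))
  major <- sum(ex$prominence >= major_frac * A)
  minor <- sum(ex$prominence >= minor_frac * A & ex$prominence < major_frac * A)
  c(major = as.integer(major), minor = as.integer(minor))
}

#' Complexity factor from lobe counts
#'
#' Deterministic multiplier turning the sinuosity index into the suture
#' complexity index. Major lobes are weighted twice as heavily as minor
#' lobes and the sum is scaled by 1/10, so a suture with a single major lobe
#' has factor 0.2 and a perfectly straight suture factor 0. Strictly
#' increasing in each count.
#'
#' @param major_lobes,minor_lobes Non-negative lobe counts.
#' @return Scalar multiplier >= 0.
#' @export
complexity_factor <- function(major_lobes, minor_lobes) {
  if (any(major_lobes < 0) || any(minor_lobes < 0))
    stop("lobe counts must be non-negative")
  (2 * major_lobes + minor_lobes) / 10
}

#' Suture complexity index
#'
#' The sinuosity index multiplied by the lobe-based complexity factor, so the
#' score responds jointly to path elongation and to interdigitation number.
#'
#' @param si Sinuosity index (>= 1).
#' @param factor Multiplier from [complexity_factor()].
#' @return Scalar score.
#' @export
suture_complexity_index <- function(si, factor) {
  if (any(si < 1)) stop("si must be >= 1")
  si * factor
}

#' Fractal dimension of a signal by box counting
#'
#' Embeds the graph of the deviation signal in its bounding square
#' (normalized to the unit square), overlays dyadic grids of box size
#' `s = 2^-j`, counts the boxes the graph occupies at each scale, and
#' estimates the dimension as the negated slope of an ordinary least-squares
#' fit of `log2 N(s)` on `log2 s`. Scales run from the full square down
#' through `octaves` halvings or until boxes are narrower than two stations.
#'
#' @param signal A [deviation_signal()] or numeric vector with >= 64
#'   stations.
#' @param octaves Maximum number of dyadic halvings of the box size.
#' @param keep_scales Optional integer indices into the dyadic ladder
#'   (1 = full square) restricting which scales enter the OLS fit; `NULL`
#'   fits over all scales.
#' @return List with `fd` (estimate clamped to `[1, 2]`), `raw_slope`,
#'   `scales` and `counts`.
#' @export
fd_boxcount <- function(signal, octaves = 8, keep_scales = NULL) {
  v <- as_signal_values(signal)
  n <- length(v)
  if (n < 64) stop("box counting needs at least 64 stations, got ", n)
  rng <- diff(range(v))
  if (rng <= flat_tolerance(signal))  # flat graph: a line, dimension 1
    return(list(fd = 1, raw_slope = 1, scales = numeric(0), counts = numeric(0),
                degenerate = TRUE))
  x <- seq(0, 1, length.out = n)
  y <- (v - min(v)) / rng
  jmax <- min(octaves, floor(log2((n - 1) / 2)))
  js <- 0:jmax
  counts <- vapply(js, function(j) {
    m <- 2^j            # boxes per side; box size s = 1/m
    col <- pmin(floor(x * m), m - 1)
    lo <- tapply(y, col, min)
    hi <- tapply(y, col, max)
    sum(pmin(floor(hi * m), m - 1) - floor(lo * m) + 1)
  }, numeric(1))
  usable <- counts > 0
  if (!is.null(keep_scales)) usable <- usable & seq_along(js) %in% keep_scales
  if (sum(usable) < 3) stop("fewer than 3 usable box-count scales")
  slope <- stats::coef(stats::lm(log2(counts[usable]) ~ js[usable]))[2]
  raw <- as.numeric(slope)   # log2 s = -j, so dimension = +slope in j
  list(fd = min(2, max(1, raw)), raw_slope = raw,
       scales = 2^-js[usable], counts = counts[usable], degenerate = FALSE)
}

#' Fractal dimension of a signal by the madogram method
#'
#' The madogram (first-order variogram) is
#' `gamma1(t) = mean |X(u + t) - X(u)|` over stations u, for lags
#' `t = 1..max_lag`. For a self-affine signal `gamma1(t) ~ t^H`, so the Hurst
#' exponent H is the OLS slope of `log gamma1` on `log t`, and the graph
#' dimension is `D = 2 - H`. Smoother signals have larger H, hence smaller D.
#'
#' @param signal A [deviation_signal()] or numeric vector with >= 64
#'   stations.
#' @param max_lag Largest lag in stations; default 8, keeping the fit in the
#'   small-lag scaling regime where the power law holds best (large lags
#'   inflate the estimate on smooth signals). Must lie in `[2, n/4]`.
#' @return List with `fd` (clamped to `[1, 2]`), `hurst` (raw slope),
#'   `lags`, `gamma`, and `degenerate` (TRUE for a constant signal, where
#'   the slope is undefined and `fd = 1` is returned).
#' @export
fd_madogram <- function(signal, max_lag = NULL) {
  v <- as_signal_values(signal)
  n <- length(v)
  if (n < 64) stop("madogram needs at least 64 stations, got ", n)
  if (is.null(max_lag)) max_lag <- 8
  if (max_lag < 2 || max_lag > n / 4)
    stop("max_lag must be in [2, n/4]")
  lags <- seq_len(max_lag)
  gamma <- vapply(lags, function(t) mean(abs(v[(1 + t):n] - v[1:(n - t)])),
                  numeric(1))
  if (any(gamma <= flat_tolerance(signal)))
    return(list(fd = 1, hurst = NA_real_, lags = lags, gamma = gamma,
                degenerate = TRUE))
  H <- as.numeric(stats::coef(stats::lm(log(gamma) ~ log(lags)))[2])
  list(fd = min(2, max(1, 2 - H)), hurst = H, lags = lags, gamma = gamma,
       degenerate = FALSE)
}

taper_window <- function(name, m) {
  x <- seq(0, m - 1)
  switch(name,
    boxcar  = rep(1, m),
    hamming = 0.54 - 0.46 * cos(2 * pi * x / (m - 1)),
    hanning = 0.5 - 0.5 * cos(2 * pi * x / (m - 1)),
    stop("unknown taper: ", name, " (use boxcar, hamming or hanning)"))
}

#' Short-time Fourier transform of a deviation signal
#'
#' Slides a tapered window along the signal and applies a discrete Fourier
#' transform to each segment. Windows start every `hop` stations; the number
#' of windows is `floor((n - window_length)/hop) + 1`. Coefficients are kept
#' for harmonics `0..floor(window_length/2)`.
#'
#' @param signal A [deviation_signal()] or numeric vector.
#' @param window_length Window size in stations (<= signal length).
#' @param hop Stations between successive window starts (>= 1).
#' @param taper `"boxcar"`, `"hamming"` or `"hanning"`.
#' @return Object of class `stft_matrix`: complex coefficient matrix
#'   (windows x harmonics) plus the parameters.
#' @export
stft <- function(signal, window_length = 50, hop = 25, taper = "hamming") {
  v <- as_signal_values(signal)
  n <- length(v)
  if (window_length > n)
    stop("window_length (", window_length, ") exceeds signal length (", n, ")")
  if (hop < 1) stop("hop must be >= 1")
  w <- taper_window(taper, window_length)
  nwin <- floor((n - window_length) / hop) + 1L
  nharm <- floor(window_length / 2) + 1L
  coef <- matrix(complex(1), nwin, nharm)
  for (i in seq_len(nwin)) {
    seg <- v[((i - 1) * hop + 1):((i - 1) * hop + window_length)] * w
    coef[i, ] <- stats::fft(seg)[1:nharm]
  }
  structure(
    list(coefficients = coef, windows = nwin,
         harmonics = 0:(nharm - 1L),
         window_length = window_length, hop = hop, taper = taper),
    class = "stft_matrix")
}

#' @export
print.stft_matrix <- function(x, ...) {
  cat("<stft_matrix> ", x$windows, " windows x ", length(x$harmonics),
      " harmonics (window ", x$window_length, ", hop ", x$hop, ", ",
      x$taper, " taper)\n", sep = "")
  invisible(x)
}

#' Power spectral density score from an STFT
#'
#' For each harmonic, the squared coefficient magnitudes are averaged across
#' the local transforms; the score is the sum of these averages over all
#' harmonics. The raw sum scales quadratically with signal amplitude. An
#' optional monotone normalization `log10p` reports `log10(1 + raw)` for
#' compressed-scale comparisons.
#'
#' @param m An `stft_matrix` from [stft()].
#' @param normalization `"none"` (raw sum) or `"log10p"`.
#' @return Scalar score >= 0.
#' @export
psd_score <- function(m, normalization = c("none", "log10p")) {
  normalization <- match.arg(normalization)
  raw <- sum(colMeans(Mod(m$coefficients)^2))
  switch(normalization, none = raw, log10p = log10(1 + raw))
}

#' Metric configuration
#'
#' Collects the tunable parameters of the five metrics with their defaults:
#' 500 equidistant semi-landmarks; STFT window 50 stations (a tenth of the
#' signal) with half-window hop and a Hamming taper; lobe prominence
#' thresholds 0.5 (major) and 0.05 (minor) of the maximum amplitude; an
#' 8-octave box-count ladder; madogram lags up to n/8.
#'
#' @param resample_n Semi-landmarks per suture.
#' @param stft_window,stft_hop,stft_taper STFT parameters; see [stft()].
#' @param psd_normalization `"none"` or `"log10p"`; see [psd_score()].
#' @param lobes_major_frac,lobes_minor_frac Lobe thresholds; see
#'   [detect_lobes()].
#' @param fd_box_octaves Box-count scale ladder depth; see [fd_boxcount()].
#' @param fd_max_lag Madogram lag cap, or `NULL` for the default of 8; see
#'   [fd_madogram()].
#' @return A named list of class `metric_config`.
#' @export
metric_config <- function(resample_n = 500,
                          stft_window = 50, stft_hop = 25,
                          stft_taper = "hamming",
                          psd_normalization = "none",
                          lobes_major_frac = 0.5, lobes_minor_frac = 0.05,
                          fd_box_octaves = 8, fd_max_lag = NULL) {
  structure(
    list(resample_n = resample_n,
         stft_window = stft_window, stft_hop = stft_hop,
         stft_taper = stft_taper,
         psd_normalization = psd_normalization,
         lobes_major_frac = lobes_major_frac,
         lobes_minor_frac = lobes_minor_frac,
         fd_box_octaves = fd_box_octaves, fd_max_lag = fd_max_lag),
    class = "metric_config")
}

#' Compute all five complexity scores for one suture
#'
#' The curve is expected to be resampled to equidistant semi-landmarks and
#' Procrustes-superimposed, so scores are comparable across specimens. The
#' result is deterministic for a fixed configuration.
#'
#' @param curve A [landmark_curve] or coordinate matrix.
#' @param cfg A [metric_config()].
#' @return One-row data frame with columns `specimen_id`, `si`, `sci`,
#'   `fd_box`, `fd_mad`, `psd`, `major_lobes`, `minor_lobes`, `hurst`.
#' @export
compute_all <- function(curve, cfg = metric_config()) {
  id <- if (inherits(curve, "landmark_curve")) curve$specimen_id else "curve"
  res <- tryCatch({
    sig <- deviation_signal(curve)
    si <- sinuosity_index(curve)
    lobes <- detect_lobes(sig, cfg$lobes_major_frac, cfg$lobes_minor_frac)
    fb <- fd_boxcount(sig, cfg$fd_box_octaves)
    fm <- fd_madogram(sig, cfg$fd_max_lag)
    ps <- psd_score(stft(sig, cfg$stft_window, cfg$stft_hop, cfg$stft_taper),
                    cfg$psd_normalization)
    data.frame(
      specimen_id = id,
      si = si,
      sci = suture_complexity_index(si, complexity_factor(lobes["major"], lobes["minor"])),
      fd_box = fb$fd, fd_mad = fm$fd, psd = ps,
      major_lobes = unname(lobes["major"]), minor_lobes = unname(lobes["minor"]),
      hurst = fm$hurst,
      row.names = NULL)
  }, error = function(e) {
    stop("complexity metrics failed for specimen ", id, ": ",
         conditionMessage(e), call. = FALSE)
  })
  res
}
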