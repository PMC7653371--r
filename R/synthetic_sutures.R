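# Parametrized generator of synthetic suture outlines spanning the
# morphological spectrum seen across mammal crania: straight, moderately and
# highly interdigitated, irregular, and looping (crest-overhanging) forms.
# Every stage of the package is testable on these curves without external
# data. A single integer seed governs all randomness.

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Synthetic suture parameters
#'
#' @param n_points Semi-landmark count of the generated curve.
#' @param amplitude Interdigitation depth relative to the unit chord.
#' @param frequency Number of interdigitation cycles along the chord.
#' @param irregularity Standard deviation of per-cycle amplitude and phase
#'   jitter (0 = perfectly regular).
#' @param loopiness Fraction in `[0, 1)` controlling how far crests lean past
#'   vertical; above 0.5 the outline becomes multi-valued in x (overhanging
#'   fingers) while remaining non-self-intersecting.
#' @param seed Integer seed; identical parameters and seed give identical
#'   curves.
#' @param specimen_id Label for the generated curve.
#' @return A named list of class `suture_params`.
#' @export
suture_params <- function(n_points = 500, amplitude = 0, frequency = 0,
                          irregularity = 0, loopiness = 0, seed = 1,
                          specimen_id = "synthetic") {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (frequency < 0) stop("frequency must be >= 0")
  if (loopiness < 0 || loopiness >= 1) stop("loopiness must be in [0, 1)")
  if (irregularity < 0) stop("irregularity must be >= 0")
  structure(list(n_points = n_points, amplitude = amplitude,
                 frequency = frequency, irregularity = irregularity,
                 loopiness = loopiness, seed = seed,
                 specimen_id = specimen_id),
            class = "suture_params")
}

# TRUE if any two non-adjacent segments of the polyline cross.
polyline_self_intersects <- function(xy) {
  n <- nrow(xy) - 1  # segments
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  p1x <- xy[1:n, 1]; p1y <- xy[1:n, 2]
  p2x <- xy[2:(n + 1), 1]; p2y <- xy[2:(n + 1), 2]
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n   # skip shared-endpoint neighbour
    d1 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p1x[j], p1y[j])
    d2 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p2x[j], p2y[j])
    d3 <- cross(p1x[j], p1y[j], p2x[j], p2y[j], rep(p1x[i], length(j)), rep(p1y[i], length(j)))
    d4 <- cross(p1x[j], p1y[j], p2x[j], p2y[j], rep(p2x[i], length(j)), rep(p2y[i], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Generate one synthetic suture outline
#'
#' The base waveform is `amplitude * sin(2*pi*frequency*t)` on the unit
#' chord, with smoothly interpolated per-cycle amplitude and phase jitter
#' scaled by `irregularity`. Positive `loopiness` applies a crest-leaning
#' warp `x = t - lambda * y` (with `lambda` set so the steepest crest tangent
#' passes vertical once loopiness exceeds 0.5), producing outlines that
#' double back in x while provably remaining simple curves; a brute-force
#' segment-intersection check guards the construction. The curve runs from
#' (0,0) to (1,0) and is resampled to `n_points` equidistant semi-landmarks.
#'
#' @param p A [suture_params()] object.
#' @return A [landmark_curve].
#' @export
generate_suture <- function(p) {
  stopifnot(inherits(p, "suture_params"))
  with_seed(p$seed, {
    m <- max(4L * p$n_points, 2000L)
    t <- seq(0, 1, length.out = m)
    if (p$amplitude == 0 || p$frequency == 0) {
      xy <- cbind(t, 0)
    } else {
      ncyc <- max(1L, ceiling(p$frequency))
      amp_c <- pmax(0.1, 1 + p$irregularity * stats::rnorm(ncyc))
      ph_c <- p$irregularity * stats::rnorm(ncyc) * (pi / 2)
      centers <- (seq_len(ncyc) - 0.5) / p$frequency
      amp_t <- if (ncyc > 1) stats::approx(centers, amp_c, xout = t, rule = 2)$y
               else rep(amp_c, m)
      ph_t <- if (ncyc > 1) stats::approx(centers, ph_c, xout = t, rule = 2)$y
              else rep(ph_c, m)
      y <- p$amplitude * amp_t * sin(2 * pi * p$frequency * t + ph_t)
      # pin endpoints to the chord
      y <- y - (1 - t) * y[1] - t * y[m]
      lambda <- if (p$loopiness > 0)
        2 * p$loopiness / (2 * pi * p$frequency * p$amplitude) else 0
      x <- t - lambda * y
      xy <- cbind(x, y)
    }
    curve <- resample_equidistant(landmark_curve(p$specimen_id, xy), p$n_points)
    if (p$loopiness > 0 && polyline_self_intersects(curve$coords))
      stop("generated outline self-intersects; reduce loopiness or amplitude")
    curve
  })
}

#' Generate a labelled spectrum of synthetic sutures
#'
#' Five classes of increasing morphological complexity, mirroring the range
#' observed across mammal cranial sutures: `straight` (no interdigitation),
#' `low_amplitude` (shallow regular interdigitations), `high_frequency`
#' (many shallow interdigitations), `high_amplitude_irregular` (deep,
#' irregular interdigitations) and `looping` (deep interdigitations with
#' overhanging crests). Deterministic for a fixed seed.
#'
#' @param n_per_class Curves per class (>= 1).
#' @param seed Integer master seed; per-curve seeds are derived from it.
#' @param n_points Semi-landmarks per curve.
#' @return List with `curves` (list of [landmark_curve]) and `classes`
#'   (character vector of class labels, parallel to `curves`).
#' @export
generate_spectrum <- function(n_per_class, seed = 1, n_points = 500) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  presets <- list(
    straight = list(amplitude = 0, frequency = 0, irregularity = 0, loopiness = 0),
    low_amplitude = list(amplitude = 0.03, frequency = 8, irregularity = 0.1, loopiness = 0),
    high_frequency = list(amplitude = 0.03, frequency = 25, irregularity = 0.1, loopiness = 0),
    high_amplitude_irregular = list(amplitude = 0.12, frequency = 12, irregularity = 0.35, loopiness = 0),
    looping = list(amplitude = 0.18, frequency = 8, irregularity = 0.2, loopiness = 0.85))
  curves <- list(); classes <- character(0)
  k <- 0L
  for (cls in names(presets)) {
    pr <- presets[[cls]]
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      p <- suture_params(
        n_points = n_points,
        amplitude = pr$amplitude, frequency = pr$frequency,
        irregularity = pr$irregularity, loopiness = pr$loopiness,
        seed = (seed * 1000L + k) %% .Machine$integer.max,
        specimen_id = sprintf("%s_%02d", cls, i))
      curves[[k]] <- generate_suture(p)
      classes[k] <- cls
    }
  }
  list(curves = curves, classes = classes)
}

#' Simulate fractional Brownian motion as a deviation signal
#'
#' Exact synthesis by the Davies-Harte circulant-embedding method: the
#' fractional Gaussian noise autocovariance is embedded in a circulant
#' matrix whose eigenvalues are obtained by FFT, a complex Gaussian vector
#' is coloured accordingly, and the increments are cumulated. Endpoints are
#' pinned to zero by a bridge correction so the path is a valid chord
#' deviation signal. Used as the oracle input for the fractal-dimension
#' estimators: the madogram estimate should recover `D = 2 - H`.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n Signal length, a power of 2.
#' @param seed Integer seed.
#' @return A `deviation_signal` of length `n` with unit nominal chord.
#' @export
generate_fbm <- function(H, n, seed = 1) {
  if (!(H > 0 && H < 1)) stop("H must be in (0, 1)")
  if (n < 8 || bitwAnd(n, n - 1L) != 0) stop("n must be a power of 2 (>= 8)")
  with_seed(seed, {
    k <- 0:n
    gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    circ <- c(gam, rev(gam[2:n]))                 # length 2n
    lam <- Re(stats::fft(circ))
    lam[lam < 0] <- 0                             # clip fp-negative eigenvalues
    m <- 2L * n
    xi <- complex(length.out = m)
    xi[1] <- sqrt(lam[1]) * stats::rnorm(1)
    xi[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
    u <- stats::rnorm(n - 1); v <- stats::rnorm(n - 1)
    xi[2:n] <- sqrt(lam[2:n] / 2) * complex(real = u, imaginary = v)
    xi[m:(n + 2)] <- Conj(xi[2:n])
    fgn <- Re(stats::fft(xi))[1:n] / sqrt(m)
    path <- c(0, cumsum(fgn))[1:n]
    i <- seq_len(n) - 1
    path <- path - (i / (n - 1)) * path[n]        # bridge: pin both endpoints
    structure(list(values = path, chord_length = 1, n = n),
              class = "deviation_signal")
  })
}
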