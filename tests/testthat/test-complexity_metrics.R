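test_that("sinuosity is 1 iff the polyline is collinear without backtracking", {
  expect_identical(sinuosity_index(rbind(c(0, 0), c(1, 0), c(2, 0))), 1)
  # brute force over 3-point configurations on a small coordinate grid
  g <- -2:2
  for (x2 in g) for (y2 in g) for (x3 in g) for (y3 in g) {
    pts <- rbind(c(0, 0), c(x2, y2), c(x3, y3))
    if (any(duplicated(pts)) || (x3 == 0 && y3 == 0)) next
    collinear <- (x2 * y3 - y2 * x3) == 0
    # the middle point lies on the segment iff p2 = t*p3 with t in [0, 1]
    between <- collinear && (x2 * x3 + y2 * y3 >= 0) &&
      (x2^2 + y2^2 <= x3^2 + y3^2)
    si <- sinuosity_index(pts)
    if (between) expect_lt(abs(si - 1), 1e-12)
    else expect_gt(si, 1 + 1e-9)
  }
})

test_that("sinuosity of a dense semicircle approaches pi/2", {
  arc <- resample_equidistant(semicircle(2000), 500)
  expect_equal(sinuosity_index(arc), pi / 2, tolerance = 1e-4)
})

test_that("lobe detection counts extrema by prominence class", {
  expect_identical(detect_lobes(rep(0, 100)), c(major = 0L, minor = 0L))
  # pure sine, k full periods: every crest and trough is a major lobe
  t <- seq(0, 1, length.out = 1000)
  for (k in c(2L, 5L, 8L))
    expect_identical(detect_lobes(sin(2 * pi * k * t)),
                     c(major = 2L * k, minor = 0L))
  # two-scale signal: ripple extrema are minor
  two_scale <- sin(2 * pi * 3 * t) + 0.2 * sin(2 * pi * 40 * t)
  lobes <- detect_lobes(two_scale, major_frac = 0.5, minor_frac = 0.05)
  expect_identical(unname(lobes["major"]), 6L)
  expect_gt(lobes["minor"], 30)
  expect_error(detect_lobes(two_scale, major_frac = 0.5, minor_frac = 0.6), "minor_frac")
})

test_that("complexity factor is zero-lobed at baseline and strictly monotone", {
  expect_identical(complexity_factor(0, 0), 0)
  expect_identical(complexity_factor(1, 0), 0.2)
  for (m in 0:20) for (k in c(0, 3, 20)) {
    expect_gt(complexity_factor(m + 1, k), complexity_factor(m, k))
    expect_gt(complexity_factor(m, k + 1), complexity_factor(m, k))
  }
  expect_error(complexity_factor(-1, 0), "non-negative")
})

test_that("SCI is bilinear in sinuosity and factor", {
  expect_identical(suture_complexity_index(1, 0.7), 0.7)
  expect_identical(suture_complexity_index(2, 0.7), 2 * 0.7)
  expect_identical(suture_complexity_index(2, 1.4), 2 * suture_complexity_index(2, 0.7))
  expect_error(suture_complexity_index(0.9, 1), ">= 1")
})

test_that("box-count dimension of a line is 1 and of a Koch profile ~ log4/log3", {
  line <- fd_boxcount(seq(0, 1, length.out = 500))
  expect_lt(abs(line$fd - 1), 0.05)
  flat <- fd_boxcount(deviation_signal(resample_equidistant(rbind(c(0, 0), c(1, 1)), 128)))
  expect_identical(flat$fd, 1)
  expect_true(flat$degenerate)

  kc <- resample_equidistant(koch_curve(4), 512)
  est <- fd_boxcount(deviation_signal(kc))
  expect_lt(abs(est$fd - log(4) / log(3)), 0.08)
  expect_true(est$fd >= 1 && est$fd <= 2)
})

test_that("madogram dimension is ~1 for smooth signals and flags constants", {
  ramp <- fd_madogram(seq(0, 1, length.out = 512))
  expect_lt(abs(ramp$fd - 1), 0.05)
  const <- fd_madogram(deviation_signal(resample_equidistant(rbind(c(0, 0), c(2, 0)), 128)))
  expect_identical(const$fd, 1)
  expect_true(const$degenerate)
  expect_error(fd_madogram(rnorm(128), max_lag = 64), "max_lag")
})

test_that("madogram recovers the Hurst exponent of simulated fBm", {
  # moderate-size version; the full sweep runs in the acceptance tests
  est <- vapply(1:30, function(s) fd_madogram(generate_fbm(0.5, 1024, s))$fd, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.05)
})

test_that("single-window STFT equals a direct DFT", {
  set.seed(11)
  v <- rnorm(128)
  m <- stft(v, window_length = 128, hop = 128, taper = "boxcar")
  expect_equal(m$windows, 1L)
  direct <- stats::fft(v)[1:65]
  expect_equal_tol(Mod(m$coefficients[1, ] - direct), rep(0, 65), 1e-10)
})

test_that("STFT window bookkeeping and zero-signal behaviour", {
  m <- stft(rep(0, 500), 50, 25, "hamming")
  expect_equal(m$windows, floor((500 - 50) / 25) + 1L)
  expect_true(all(Mod(m$coefficients) == 0))
  expect_error(stft(rnorm(40), window_length = 50), "exceeds")
  expect_error(stft(rnorm(100), 50, hop = 0), "hop")
})

test_that("a pure integer-bin sinusoid concentrates energy in its bin", {
  n <- 400; wl <- 50
  v <- sin(2 * pi * 5 * seq_len(n) / wl)  # harmonic 5 of every 50-sample window
  m <- stft(v, wl, 25, "boxcar")
  mag2 <- Mod(m$coefficients)^2
  for (w in seq_len(m$windows))
    expect_gt(mag2[w, 6] / sum(mag2[w, ]), 0.99)
})

test_that("STFT agrees with the e1071 reference implementation", {
  set.seed(12)
  v <- rnorm(600)
  ref <- e1071::stft(v, win = 128, inc = 32, coef = 64, wtype = "hanning.window")
  mine <- stft(v, window_length = 128, hop = 32, taper = "hanning")
  expect_equal(nrow(mine$coefficients), nrow(ref$values))
  expect_equal_tol(Mod(mine$coefficients[, 1:64]) - ref$values,
                   matrix(0, nrow(ref$values), 64), 1e-10)
})

test_that("PSD score is zero for silence and quadratic in amplitude", {
  expect_identical(psd_score(stft(rep(0, 500))), 0)
  set.seed(13)
  v <- rnorm(500)
  raw <- psd_score(stft(v))
  expect_equal(psd_score(stft(3 * v)), 9 * raw, tolerance = 1e-9)
  expect_equal(psd_score(stft(v), "log10p"), log10(1 + raw))
})

test_that("compute_all is deterministic and complete", {
  curve <- generate_suture(suture_params(500, 0.1, 7, 0.25, 0, seed = 5))
  aligned <- landmark_curve("c", center_and_scale(curve$coords))
  r1 <- compute_all(aligned)
  r2 <- compute_all(aligned)
  expect_identical(r1, r2)
  expect_true(all(c("specimen_id", "si", "sci", "fd_box", "fd_mad", "psd",
                    "major_lobes", "minor_lobes", "hurst") %in% names(r1)))
  expect_gte(r1$si, 1)
  expect_true(r1$fd_box >= 1 && r1$fd_box <= 2)
  expect_true(r1$fd_mad >= 1 && r1$fd_mad <= 2)

  straight <- landmark_curve("s", center_and_scale(
    resample_equidistant(rbind(c(0, 0), c(1, 0)), 500)))
  rs <- compute_all(straight)
  expect_equal(rs$si, 1, tolerance = 1e-12)
  expect_identical(rs$fd_box, 1)
  expect_identical(rs$fd_mad, 1)
  expect_identical(rs$major_lobes + rs$minor_lobes, 0L)
  expect_lt(rs$psd, 1e-20)
})

test_that("scores are invariant under rigid motion and SI/FD under scaling", {
  curve <- generate_suture(suture_params(500, 0.12, 9, 0.3, 0, seed = 6))$coords
  base <- compute_all(landmark_curve("a", center_and_scale(curve)))
  set.seed(14)
  for (rep in 1:3) {
    moved <- rigid(curve * runif(1, 0.2, 5), runif(1, -pi, pi), rnorm(2, sd = 10))
    m <- compute_all(landmark_curve("a", center_and_scale(moved)))
    expect_equal(m$si, base$si, tolerance = 1e-6)
    expect_equal(m$psd, base$psd, tolerance = 1e-6 * base$psd)
    expect_equal(m$fd_box, base$fd_box, tolerance = 1e-6)
    expect_equal(m$fd_mad, base$fd_mad, tolerance = 1e-6)
    expect_identical(m$major_lobes, base$major_lobes)
  }
  # SI and FD need no centroid scaling at all
  raw <- compute_all(landmark_curve("a", curve * 11))
  expect_equal(raw$si, base$si, tolerance = 1e-9)
  expect_equal(raw$fd_box, base$fd_box, tolerance = 1e-9)
  expect_equal(raw$fd_mad, base$fd_mad, tolerance = 1e-9)
})

test_that("SI and PSD rise with amplitude; lobes rise with frequency", {
  amps <- c(0.02, 0.05, 0.1, 0.18)
  si <- psd <- numeric(length(amps))
  for (i in seq_along(amps)) {
    cv <- generate_suture(suture_params(500, amps[i], 8, 0, 0, seed = 1))
    si[i] <- sinuosity_index(cv)
    psd[i] <- psd_score(stft(deviation_signal(cv)))
  }
  expect_true(all(diff(si) > 0))
  expect_true(all(diff(psd) > 0))

  freqs <- c(4, 8, 16, 25)
  lobes <- vapply(freqs, function(f) {
    cv <- generate_suture(suture_params(500, 0.05, f, 0, 0, seed = 1))
    sum(detect_lobes(deviation_signal(cv)))
  }, numeric(1))
  expect_true(all(diff(lobes) > 0))
})
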