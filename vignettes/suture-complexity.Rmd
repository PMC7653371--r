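---
title: "Quantifying suture complexity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying suture complexity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturemetrics)
```

# The problem

A cranial suture's two-dimensional trace is an open curve with no discrete
homologous landmarks. Its geometry is captured as an ordered chain of
semi-landmarks from one endpoint to the other, and its "complexity" — how far
the trace departs from a straight line along its whole path — is the quantity
of biological interest: interdigitated sutures absorb and distribute
biomechanical stress, and complexity changes with diet, behaviour and
development. No single number can encode a suture's full shape, and different
complexity metrics emphasize different features. This package computes five
established metrics side by side, together with the comparative statistics
needed to see what each one responds to.

# The pipeline and its assumptions

1. **Resampling.** Every outline is resampled to `resample_n` (default 500)
   semi-landmarks at exactly equal arc-length spacing, by linear
   interpolation along the input polyline. Stations are equispaced in arc
   length along the *input* polyline; chord distances between consecutive
   output points are therefore only asymptotically equal where the resampling
   cuts corners. No spline smoothing is applied anywhere: smoothing is a
   low-pass filter and would systematically depress every complexity score.
   The default of 500 follows common practice for suture outlines; users
   digitizing unusually fine (fractal-like) sutures should confirm their
   landmark count does not erase detail, since all five metrics are computed
   from the sampled polyline.

2. **Superimposition.** Generalized Procrustes analysis removes translation
   (centering), size (unit centroid size) and orientation (least-squares
   rotation to an iteratively updated consensus; tolerance `1e-8` on the
   consensus root-mean-square change, at most 100 sweeps). Two deliberate
   restrictions:

   - *Proper rotations only.* Reflections are never fitted, so mirror-image
     sutures ('n'- vs 'u'-shaped arches) remain distinct in shape space.
     This is essential: the dominant axis of shape variation in suture
     datasets is typically exactly this inversion, and silently normalizing
     it away would misrepresent the data.
   - *No semi-landmark sliding.* Sliding (by bending energy or chord
     distance) redistributes points along the curve and thus changes the
     deviation signal the metrics consume. It is out of scope by design,
     not an omission.

3. **Signal extraction.** Each aligned curve is rigidly mapped to its chord
   frame (first endpoint at the origin, last on the positive x-axis) and read
   off as a 1D signal: the signed y-offset at each station, i.e. the signed
   perpendicular deviation from the endpoint chord. The signal is indexed by
   arc-length station, *not* by x-projection. For looping sutures the path
   doubles back in x and y(x) is multi-valued; arc-length indexing is the
   only convention that assigns every curve exactly one value per station.
   Endpoint values are zero by construction. No detrending or mean removal
   is applied beyond the chord frame itself.

4. **Metrics** (per suture, on the superimposed curve):
   - `sinuosity_index()`: path length over chord length.
   - `detect_lobes()` + `complexity_factor()` + `suture_complexity_index()`.
   - `fd_boxcount()`, `fd_madogram()`.
   - `stft()` + `psd_score()`.

5. **Comparative statistics.** PCA of the flattened superimposed coordinates
   (unstandardized: all coordinates share units); PCA of the score table
   (standardized by default: the five metrics live on incommensurable
   scales, SI near 1–7 against SCI up to tens — both modes are exposed
   because either convention is defensible); pairwise Pearson correlations
   with two-sided t-test p-values and Fisher-z 95% intervals, uncorrected
   for multiple testing; equal-width binning for heatmaps; and correlations
   of each metric against every shape PC that explains more than
   `pc_retain` (default 5%) of shape variance.

# Parameter choices that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `resample_n` | 500 | stations | standard semi-landmark density for sutures |
| `lobes_major_frac` | 0.5 | fraction of max amplitude | a "major" lobe excursion is at least half the deepest excursion |
| `lobes_minor_frac` | 0.05 | fraction of max amplitude | excursions under 5% are digitization noise |
| `stft_window` | 50 | stations | one tenth of the default signal; resolves ~25 harmonics |
| `stft_hop` | 25 | stations | half-window overlap, the usual STFT compromise |
| `stft_taper` | Hamming | — | standard leakage control for short windows |
| `psd_normalization` | none | — | raw quadratic scale; `log10p` available |
| `fd_box_octaves` | 8 | dyadic halvings | down to boxes two stations wide at n = 500 |
| `fd_max_lag` | 8 | stations | small-lag scaling regime (see below) |
| `bins` | 10 | — | equal-width heatmap convention |
| `pc_retain` | 0.05 | variance fraction | "meaningful axis" threshold |

**Lobe counting.** Lobes are rated by topographic prominence (height above
the higher of the two saddles separating a peak from higher terrain), not by
raw height. Prominence is stable under reparametrization and baseline shifts,
and it cleanly separates a two-scale signal — deep fingers carrying a small
ripple — into major and minor counts. The thresholds are fractions of the
maximum absolute amplitude, making the counts scale-invariant.

**The SCI complexity factor.** The factor is
`(2 × major + minor)/10`: strictly increasing in each count, counting a major
lobe as two minors, zero for a lobe-free suture. With this parametrization a
near-straight suture carrying a single dominant excursion has factor 0.2, and
SCI spans roughly zero to tens across realistic morphologies. The weighting
is the package's own convention (exposed through `complexity_factor()`), and
any monotone alternative can be substituted upstream of
`suture_complexity_index()`.

**Madogram lags.** The madogram `γ₁(t)` of an exactly self-affine signal is
a power law at every lag, but empirical deviation signals are bridge-like
(pinned to zero at both endpoints), which flattens `γ₁` at large lags and
biases the fitted H downward — hence D upward — on smooth signals. The
estimator recovery experiment (madogram on pinned fractional Brownian motion,
H ∈ {0.2, 0.5, 0.8}, n = 1024, 100 paths per level; run by both the test
suite and `scripts/acceptance.R`) shows the mean absolute error growing
steadily as the lag cap rises from 8 toward n/8. The default is therefore
`max_lag = 8`; any cap in [2, n/4] is available via `metric_config()`.

**Box-count ladder.** The ladder starts at the signal's bounding square and
halves eight times or until boxes are under two stations wide; the fit is
ordinary least squares over *all* scales. On strongly oscillatory sutures the
coarse scales sit in a regime where the graph nearly fills the square, which
pulls the estimate up — box counting is the least scale-consistent of the
five metrics, and this is visible in its scores. `keep_scales` lets users
prune the ladder; the default deliberately does not, so that the reported
number is the plain textbook estimator.

**PSD reporting scale.** The raw score is a sum of window-averaged squared
DFT magnitudes and scales quadratically with signal amplitude (verified as an
exact identity in the tests). Because squared-magnitude sums can span orders
of magnitude across a morphologically diverse sample, an optional monotone
`log10p` transform (`log10(1 + raw)`) is provided; the manifest records which
normalization produced any given score table.

# The synthetic spectrum

`generate_spectrum()` emulates the morphological range seen across mammal
crania with five labelled classes (per-curve parameters in
`generate_suture()` units: amplitude relative to the unit chord, frequency in
cycles per chord):

| class | amplitude | frequency | irregularity | loopiness |
|---|---|---|---|---|
| straight | 0 | 0 | 0 | 0 |
| low_amplitude | 0.03 | 8 | 0.1 | 0 |
| high_frequency | 0.03 | 25 | 0.1 | 0 |
| high_amplitude_irregular | 0.12 | 12 | 0.35 | 0 |
| looping | 0.18 | 8 | 0.2 | 0.85 |

The base waveform is a sine with smoothly interpolated per-cycle amplitude
and phase jitter. The looping class applies a crest-leaning shear
`x = t − λy`, with λ set so that crest tangents pass vertical once
`loopiness > 0.5`. A shear is a bijection of the plane, so the warped outline
is provably simple (non-self-intersecting) while genuinely doubling back in
x — a symmetric "breaking-wave" fold was rejected because it self-intersects
exactly when the crest overhangs. A brute-force segment-intersection check
guards the construction regardless. The looping preset is deeper and less
finely divided than the interdigitated preset, reflecting folded-lobe
morphologies; the interdigitated preset carries more, narrower fingers. This
is what lets the score table discriminate the two morphological strategies
rather than merely ranking overall waviness.

What the generator does *not* emulate: digitization noise and operator
placement error, multi-scale (fractal) interdigitation within a single
suture, anatomical constraints between neighbouring sutures, and genuinely
self-similar roughness (the fBm generator covers that case separately for
estimator validation). Passing tests on the spectrum therefore demonstrate
correct geometry handling and the qualitative metric contrasts, not
performance under real digitization noise.

`generate_fbm()` synthesizes exact fractional Gaussian noise by Davies–Harte
circulant embedding (eigenvalues of the embedded covariance via FFT, clipped
at zero where floating-point round-off makes them infinitesimally negative),
cumulates it to fractional Brownian motion, and pins both endpoints with a
bridge correction so the path is a legitimate chord-deviation signal.

# Numerical conventions and degenerate inputs

- **Flatness.** A deviation signal whose amplitude is below `1e-9` of its
  chord length is treated as flat: FD estimators return 1 with a degenerate
  flag and no lobes are counted. Without this, the ~1e-16 rounding noise
  left by superimposition on a perfectly straight suture would be
  renormalized to full scale and scored as rough.
- **Sinuosity floor.** The arc–chord ratio is clamped from below at 1;
  floating-point summation can otherwise undershoot by one ulp on exactly
  collinear input.
- **FD clamping.** Both estimators report a `[1, 2]`-clamped dimension and
  retain the raw slope, since estimator noise can exit the theoretical
  range.
- **PC sign convention.** Each loading vector is flipped so its
  largest-magnitude entry is positive; eigenvector signs are otherwise
  arbitrary and would make runs non-comparable.
- **Binning ties.** The maximum value belongs to the top bin; a constant
  vector falls entirely in bin 1.
- **Coincident endpoints** (closed outlines) have no chord: signal
  extraction raises a degenerate-chord error, which the pipeline logs per
  specimen (`errors.csv`) without aborting the run.
- **Zero-variance columns** in a correlation table flag their pairs as `NA`
  rather than failing the whole report.

# Problem sizes

The test suite and acceptance script size their experiments as follows: the
spectrum runs use 500-station curves with 2–16 curves per class (80 sutures
in the acceptance run, comparable to a realistic comparative sample);
estimator recovery uses 100 fBm paths of length 1024 per Hurst level and a
level-4 Koch profile resampled to 512 stations; the permutation oracle for
correlation p-values uses 10,000 draws at n = 12. These sizes give stable
statistics while keeping a full run in the order of seconds.

# Known limitations

- Strictly two-dimensional; three-dimensional suture surfaces are out of
  scope.
- Complexity scores depend on the sampled extent of the suture; partial
  traces of the same suture can score differently, so sampling protocols
  must be consistent across a comparative dataset.
- Box counting is biased upward on oscillatory non-fractal curves (see
  above) and is retained for comparability, not as the recommended
  fractal estimator; the madogram is the more robust of the two.
- The STFT assumes uniformly spaced stations, which resampling guarantees,
  but window parameters interact with suture length: strongly different
  `resample_n` values require rescaling `stft_window`/`stft_hop` to keep
  scores comparable.
- No phylogenetic or developmental interpretation is attempted; the package
  stops at scores and their comparative statistics.
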