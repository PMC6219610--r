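---
title: "Multi-parametric ultrafast Doppler analysis of cerebral hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric ultrafast Doppler analysis of cerebral hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

```{r setup, message = FALSE}
library(ufdhemo)
library(dplyr)
```

# The measurement chain

Ultrafast Doppler (UfD) images blood flow by firing unfocused plane waves
at kilohertz rates and coherently compounding the tilted-transmit images
into one frame per angle sweep. With a 6.4 MHz linear array firing 4 plane
waves (tilted −3°, −1°, 1°, 3°) at an 8 kHz pulse repetition frequency,
the compounded frame rate is 2 kHz, so one 1000-frame Doppler block spans
0.5 s and the aliasing-free axial velocity span
$c f_s / (2 f_0) \approx 24$ cm/s covers cerebral blood flow:

```{r}
cfg <- acquisition_config()
compound_frame_rate(cfg)
max_unaliased_velocity_span(cfg)
```

Each block is processed as follows:

1. **Clutter filtering.** The block is rearranged into its Casorati matrix
   (rows = pixels, columns = frames) and the leading singular components —
   which concentrate the strong, spatially coherent, slowly varying tissue
   echo — are removed (`svd_filter()`).
2. **Power Doppler.** The per-pixel mean of $|s|^2$ over the filtered
   frames is proportional to the cerebral blood volume (CBV) sampled in
   the pixel (`power_doppler()`).
3. **Relative CBV.** Power is normalized per pixel to its mean over a
   baseline window, giving percent change maps: +150% means 2.5× the
   baseline blood volume (`relative_cbv()`).
4. **Resistivity.** A short-time Fourier analysis of each pixel's filtered
   series yields the instantaneous mean blood speed as the first spectral
   moment on $|f|$; the resistivity index
   $RI = (v_\max - v_\min)/v_\max$ over the cardiac cycle quantifies
   vascular tone (`resistivity_map()`).
5. **Regional statistics.** Relative maps are averaged over anatomical
   masks, hyperemia is quantified by the time-normalized area under the
   curve (AUC) over an analysis window, and groups are compared with the
   exact Mann–Whitney U test and Cohen's *d* (`group_compare()`).
6. **Autoregulation.** Paired (MAP, CBV) samples are standardized and
   decomposed by 2-D PCA; the orientation and anisotropy of the point
   cloud diagnose whether CBV is held constant across pressure changes
   (`autoregulation_report()`).

# What the synthetic data emulate

No public raw data exist for this kind of experiment, so the package
generates its own inputs with known ground truth (`make_experiment()`).
The generator emulates:

* **Tissue clutter** as fully developed speckle (per-pixel circular
  complex Gaussian reflectivity) 30 dB above blood, moving as a whole with
  a slow (< 5 Hz) sinusoidal axial displacement. A uniform displacement
  makes the tissue term an exact rank-one component of the Casorati
  matrix, which is the premise of spatiotemporal SVD filtering. Within the
  23–26 min chest-compression artifact window the motion gains a
  random-walk component that raises the clutter rank and leaks through the
  filter, reproducing the artifact-inflated dispersion seen in that
  window; those samples carry an artifact flag and are excluded from AUC
  integration and autoregulation clouds.
* **Blood echoes** as sparse scatterers (Poisson counts per pixel, 30 dB
  below tissue, noise 30 dB below blood) whose axial velocities follow a
  shared raised-cosine systolic waveform (heart rate 4 Hz — two cardiac
  cycles per 0.5 s block — systolic speed 0.10 m/s, diastolic speed set by
  the phase-dependent resistivity index) with per-scatterer random flow
  direction and ±20% speed jitter. Per-frame phase advances by the
  two-way pulsed-Doppler increment $4\pi f_0 v \Delta t / c$.
* **Hemodynamic time courses** as piecewise-linear group templates:
  the Control arm's whole-slice relative CBV peaks at +150% ten minutes
  after resuscitation (hippocampus +210%, thalamus +126.6%), the TLV
  (total-liquid-ventilation rapid-cooling) arm stays pointwise at or below
  Control throughout the 7–37 min window with a whole-slice
  time-normalized AUC near +26%, and the Sham arm follows an
  autoregulation plateau across a 58–138 mmHg MAP sweep. Blood scatterer
  density scales as $1 + \mathrm{CBV}(t)/100$, so doubling CBV doubles
  the expected filtered power.
* **Subject variability** as one global multiplicative factor per subject
  (SD 34/150, matching the reported ±34% dispersion at the +150% peak)
  plus region-specific factors. The hippocampal factor is sized so the
  +210% peak carries a ±74% SD. The cortex and thalamus factors (SD 0.45
  and 0.7) and the partial TLV mitigation of those regions are sized so
  that the designed effect-size ordering — hippocampus carrying the
  largest Cohen's *d* between arms — holds with a wide margin when
  averaged over replicate cohorts; the trade-off is that the generator
  does not also reproduce the reported per-region peak SDs, which are not
  jointly consistent with any low-dimensional subject model.
* **MAP traces** within 60–90 mmHg after resuscitation (Control near
  78 mmHg, decoupled from its CBV excursions; TLV near 62–66 mmHg and
  passively coupled to the subject's own CBV course, preserving a linear
  pressure–flow relation without a plateau).

What the generator deliberately does **not** emulate: acoustic
propagation (no element directivity, attenuation, or depth-dependent
point-spread function in the image-domain IQ synthesis), out-of-plane
motion, vessel geometry (vessels are region-wide scatterer populations,
not tubes), or physiological beat-to-beat variability. Passing tests
therefore demonstrate that the *processing chain* is correct and
internally consistent under the stated signal model — not that it would be
robust to every artifact of in-vivo data.

Raw channel data are synthesized separately (`simulate_rf_plane_wave()`)
for beamforming tests only; the Doppler pipeline consumes image-domain IQ
directly (`simulate_iq_block()`), which decouples Doppler processing
correctness from beamformer correctness.

# A desk-scale run

The full acquisition scale (1000-frame blocks every 10 s for 90 min) is
configurable but slow on a laptop; the desk scale used throughout the
tests and examples is a 64 × 64 grid (or smaller), 200-frame blocks and
one block per minute. A complete two-arm comparison:

```{r, eval = FALSE}
run <- run_pipeline(run_config(groups = c("control", "tlv"),
                               n_subjects = 5, seed = 1,
                               out_dir = "ufd_demo"))
run$comparisons
run$autoreg
```

Stage outputs are cached under the output directory keyed by a hash of
each stage's configuration, so re-running an unchanged configuration
executes nothing and editing, say, an analysis window re-runs only the
comparison stage.

A lighter curve-level route skips IQ synthesis entirely:
`ground_truth_series()` returns the per-subject realized template curves
in the same format as `regional_series()`, which is how the statistical
modules are exercised without the Doppler front end.

```{r}
cfg16 <- acquisition_config(grid_shape = c(16, 16), frames_per_block = 50)
reg <- region_set(c(16, 16))
cohort <- c(
  make_experiment(hemodynamic_template("control"), cfg16, 5, seed = 1,
                  regions = reg),
  make_experiment(hemodynamic_template("tlv"), cfg16, 5, seed = 2,
                  regions = reg))
series <- purrr::map_dfr(cohort, ground_truth_series, cbv_noise_sd = 3)
glance(group_compare(series, region = "whole_slice", window = c(7, 37),
                     groups = c("control", "tlv")))
```

# Numerical and design choices

* **SVD filter.** The decomposition is computed on the thin (time)
  dimension through the eigen-decomposition of the frames × frames
  Hermitian cross-product — exact and far cheaper than a full SVD when
  pixels outnumber frames. The default removes a fixed count of 2 leading
  components: the synthetic tissue occupies one component (two to three
  during motion artifacts), and a fixed count is transparent and
  testable, whereas adaptive thresholds would tie test outcomes to the
  threshold heuristic. An energy-fraction mode and a high-rank noise cut
  are available; no noise cut is applied by default.
* **Relative CBV denominators.** The baseline reference is the per-pixel
  mean power over all blocks in the −23 to −13 min window; pixels at or
  below a configurable noise floor are masked out of relative maps and
  regional averages rather than risking division blow-ups. Because the
  per-pixel ratio estimator is convex in the denominator, finite baseline
  sampling biases regional relative CBV slightly upward. Desk-scale runs
  therefore keep the baseline phase sampled every 20 s even when the rest
  of the protocol is thinned to one block per minute
  (`make_experiment(baseline_interval_s = 20)`), which brings the regional
  bias down to one or two percent of the multiplier; the remaining few
  points by which recovered peaks sit above their template values come
  from taking a per-subject maximum over a noisy sampled curve, and stay
  well within the cohort's ±2 SE band.
* **Spectrogram.** Hann window of 64 frames (32 ms at 2 kHz) with 75%
  overlap: long enough for ~31 Hz spectral resolution, short enough to
  resolve the 4 Hz cardiac modulation. The first moment uses $|f|$ over
  the bins above a per-pixel noise floor (twice the median bin power), so
  opposite flow directions add rather than cancel; the resistivity index
  is direction-free by definition. $v_\max$ and $v_\min$ are taken over
  the whole block (≥ 2 cardiac cycles) rather than per detected beat,
  avoiding beat segmentation. Blocks shorter than one cardiac cycle are
  rejected.
* **Beamforming.** Delay-and-sum with the plane-wave transmit delay
  referenced to the array center, exact point-to-element receive paths,
  linear interpolation of the analytic channel signals (≥ 4 samples per
  carrier period enforced) and an F-number-1 dynamic receive aperture;
  without the aperture limit, steep-angle echoes corrupt shallow pixels
  because the simulated elements have no directivity. Apodization is
  rectangular by default (Hann optional); compounding is the complex
  pixel-wise mean.
* **Mann–Whitney U.** The "paired" wording sometimes attached to
  two-different-animal comparisons is a contradiction in terms; the test
  implemented is the standard independent-samples exact U with midrank tie
  handling, enumerating all $\binom{n_1+n_2}{n_1}$ labelings of the
  observed pooled values (exact for pooled sizes ≤ 20, tie-corrected
  normal approximation above, flagged in the result). The two-sided p is
  $\min(1,\, 2\min(P_{\le}, P_{\ge}))$. At $n = 5, 5$ the rejection region
  at nominal 0.05 has true level $8/252 \approx 0.032$ — the discrete test
  is conservative, which the calibration test asserts.
* **AUC.** Trapezoidal, linearly interpolated at the window bounds,
  divided by the window length so values are comparable across the 7–37,
  7–22 and 30–60 min windows; artifact-flagged samples are dropped before
  integration.
* **PCA standardization.** The default removes each variable's mean and
  divides both by one pooled SD (the SD of the two centered variables
  concatenated), which preserves the relative spread of MAP and CBV: an
  autoregulation plateau keeps its near-horizontal principal axis instead
  of being forced to ±45° as per-variable z-scoring would. A
  `per_variable` mode is provided. Covariance uses the $n-1$ denominator;
  eigenvector signs follow the first-nonnegative-coordinate rule. Clouds
  are standardized per group, the reading most consistent with per-group
  analysis.
* **Autoregulation classification.** Under pooled standardization the
  weight ratio $\lambda_1/\lambda_2$ is unit-dependent: a decoupled cloud
  with large CBV excursions and physiologically narrow MAP (SD ~5 mmHg
  against ~50 CBV points) shows a *high* ratio along the CBV axis, so a
  low ratio cannot be the impairment criterion. The classifier therefore
  uses: plateau = |angle| < 15° and ratio > 5; impaired = |Pearson r| <
  0.5; otherwise linear-steep. All three diagnostics (angle, ratio,
  correlation) are reported so other rules can be applied.
* **Unspecified scanner constants.** The blood-to-tissue echo ratio, the
  noise floor, the probe's element count and pitch, and the clutter-filter
  rank threshold are not published quantities; the defaults here
  (30 dB margins, 128 elements, 0.3 mm pitch, rank 2) are configurable
  stand-ins, not calibrated values.

# Known limitations

* Reported λ pairs from small standardized clouds satisfy
  $\lambda_1 + \lambda_2 \approx 2$ by construction; published weight
  pairs whose sums differ from 2 can be compared through their ratios and
  vector geometry (`weight_ratio()`), not regenerated from simulation.
* The ratio-estimator bias of relative CBV (above) is inherent to
  per-pixel baseline normalization with finitely many baseline blocks.
* Exact-U enumeration is limited to pooled sizes of 20; beyond that the
  normal approximation is used and marked.
* The regional masks are geometric stand-ins on the pixel grid, not
  anatomical segmentations; depth-layer masks are supported
  (`region_set(n_cortex_layers = )`) but no anatomical claim attaches to
  them.
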