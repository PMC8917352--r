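---
title: "Quantifying condensin binding dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensin binding dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapkit)
```

## The measurement problem

Fluorescence recovery after photobleaching (FRAP) infers the exchange
kinetics of a chromatin-bound protein from the return of fluorescence to a
deliberately bleached spot. In the dosage-compensation setting that
motivates this package, the protein of interest is an SMC4-variant subunit
of the X-specific condensin complex, imaged in large polyploid intestine
nuclei of *C. elegans*: a small spot inside the X-chromosome territory is
bleached with a brief high-power pulse after ~20 baseline frames, and
~500 recovery frames are collected at 0.21 s per frame. Two quantities
summarize the kinetics:

* the **mobile fraction** `m` — the proportion of molecules exchanged into
  the bleached region over the course of the experiment, and
* the **recovery half-time** — the time to recover half of the
  fluorescence maximum, read directly from the data.

## The model and the pipeline

The recovery is modelled as reaction-limited single-exponential exchange
of a mobile pool. After double normalization (below), the post-bleach
curve is fitted with

$$F(t) = M\,(1 - e^{-t/\tau}),$$

with no offset term, because normalization pins `F(0) = 0` exactly. The
mobile fraction is the fitted model evaluated at the last recorded
recovery time `T_last` (for `tau << T_last` it coincides with the plateau
`M`). The half-time is *not* derived from `tau`: it is the first time the
normalized data crosses half of the observed maximum (mean of the final
5% of points), linearly interpolated between frames. For a model-true
curve these agree analytically, `t_half = tau * ln 2`.

Each movie passes through five stages (`analyze_movie()`):

1. **Drift correction.** Every frame is registered to the mean of the
   pre-bleach frames by upsampled cross-correlation: the integer-pixel
   estimate from the inverse-FFT correlation peak is refined by a
   matrix-multiply DFT evaluated only in a 1.5 x 1.5-pixel neighborhood
   of the peak at 1/`upsample` resolution. The pre-bleach mean is used as
   the fixed reference because it has the highest signal-to-noise ratio
   and is unaffected by the bleach pulse; whether the original analyses
   used a fixed or running reference is not documented, so the simpler
   fixed-reference rule was chosen and is stated here. Registration is
   estimated on the whole frame (a stage drift is global), with periodic
   boundary handling — acceptable because nuclei are interior.
2. **Bleach-spot detection.** The difference between the mean pre-bleach
   image and the mean of the first five post-bleach images is thresholded
   with Otsu's method (256 equal-width bins over the observed range,
   computed from in-nucleus pixels only). Among supra-threshold pixels,
   the 8-connected component containing the difference maximum — the
   bleach point — is taken as the ROI. Selecting by seed rather than by
   largest area makes the rule robust to bright-speckle artifacts. No
   morphological post-processing is applied by default (`roi_dilate`
   exposes it), since none is documented for the original analysis.
3. **Acquisition-bleaching correction.** Repeated imaging itself bleaches
   the sample. The whole-nucleus mean intensity over the post-bleach
   frames is fitted with `A * exp(-k t)` and every curve is divided by
   `exp(-k t)` on the shared experiment clock (pre-bleach frames carry
   negative `t`). The whole-nucleus trace deliberately *includes* the
   bleached spot, matching the described procedure; recovery
   redistribution therefore biases `k` very slightly (the spot is ~2% of
   the nucleus area at default geometry), and `decay_exclude_roi = TRUE`
   is available. Whether pre-bleach frames were decay-corrected before
   computing the pre-bleach mean is not documented; correcting them on
   the shared clock is self-consistent and exact for the simulator's
   per-frame decay model, and is flagged here as a divergence risk for
   real Leica acquisitions.
4. **Double normalization.** `(corrected - C0) / (C_pre - C0)`, with
   `C_pre` the mean corrected pre-bleach value and `C0` the corrected
   value at the *single* first post-bleach frame (not an average), so the
   normalized curve starts at exactly 0 and has pre-bleach mean exactly 1.
   Curves with no bleach depth (`C_pre = C0`) are rejected, not silently
   normalized.
5. **Recovery fit.** `tau` is profiled out on `log(tau)` by a bounded 1-D
   search with the amplitude solved in closed form at each candidate
   (clamped to `[0, 1.5]`); this is numerically robust for zero-residual
   synthetic curves and degenerate flat curves alike, and recovers exact
   inputs to ~1e-9 relative. Non-identifiable fits are flagged
   (`no_recovery`, `tau_at_bound`, `fit_failed`) rather than clamped;
   mobile fractions outside `[0, 1]` are flagged, never truncated.

Cohort statistics follow the original plotting conventions: per-time-point
mean and s.e.m. after truncation to the shortest series (so each band has
a constant n); boxplot summaries as median, IQR and 5th/95th-percentile
whiskers; group comparison by a pooled-variance two-tailed t-test (the
unqualified "independent two-sample t-test"; Welch is available by flag);
pixel-intensity distributions binned at width 20, summed across images
and divided by the image count; and a Mann-Whitney U test with midranks,
tie correction and continuity correction, using the normal approximation
(pixel samples are far too large for the exact distribution).

## What the synthetic movies do and do not emulate

The generator (`simulate_frap_movie()`) renders exactly the stated model:
a hard-edged disk nucleus (radius 40 px in a 128 x 128 frame) at baseline
intensity 1000 AU over a background of 100 AU, a hard-edged bleach disk
(radius 6 px; a Gaussian edge is available) whose mean follows
`S(t) = S_pre [(1 - beta) + beta m (1 - e^{-t/tau})]`, global per-frame
decay `e^{-k f}` counted from frame 0 (a constant-exposure scan bleaches
per frame, not per second), cumulative lateral drift applied by Fourier
phase shift (so sub-pixel ground truth is exact; edges wrap), and
additive Gaussian noise clipped at zero (Poisson shot noise is an
option, off by default). Baseline/background levels are not stated in any
protocol; 1000/100 AU gives the ~10:1 nuclear contrast typical of the
induced-GFP images and their absolute scale cancels in normalization.

Deliberately *not* emulated: diffusion-coupled recovery (the fitted model
family is reaction-limited exchange, so recovery tests are
self-consistent), 3D acquisition, photophysics (blinking, reversible
bleaching), and intensity redistribution — bleached molecules are not
conserved, so the out-of-spot nucleus does not dim as the spot recovers.
A green pipeline test therefore establishes correctness of the *analysis*
under its own model assumptions, not the physical fidelity of that model
to any particular microscope.

Drift: the validation suite specifies "0.1 px/frame" drift. Held to a
constant direction over 520 frames this is a 52 px excursion, which would
carry the default nucleus out of the frame; the generator therefore ships
`drift_random_walk()`, a fixed step length in a uniformly random
per-frame direction (cumulative excursion ~ `0.1 * sqrt(520) ~ 2.3` px),
which is both bounded and a fair model of thermal stage drift.

## The chromosome-scale statistics

ChIP spreading profiles: ChIP/input ratios in fixed bins are z-scored
against the mean and s.d. of an **explicit** background chromosome set
(autosomes I-IV in the standard karyotype — never inferred from names),
optionally scaled so the total signal over a target (fusion) chromosome
equals 1, and smoothed with a 500 kb window stepped at 50 kb. Windows
never span chromosomes and trailing partial windows are dropped (padding
policy is undocumented in the source analyses; dropping is the
conservative choice). `simulate_spreading_track()` provides a fusion
chromosome with an enrichment plateau decaying exponentially across the
fusion boundary (plateau 2x background, 500 kb decay length, Gaussian
bin noise sd 0.3 — chosen as a visually realistic spreading profile).

Hi-C contact decay: on 5 kb-binned, already-balanced matrices (matrix
balancing is out of scope by design — this module is the post-balancing
statistics layer), `P(s)` is the mean entry at each off-diagonal distance
up to 20 Mb, unity-normalized so the sum over 5 kb <= s <= 4 Mb is exactly
1 per chromosome, and the X/A curve divides the X by the **unweighted**
mean of the autosomal curves (no length weighting is documented; the
unweighted mean was chosen and either convention is a one-line change).
The generator draws symmetric Poisson counts around
`depth * d^{-alpha}` with an X-specific multiplicative band. The default
`depth = 20000` expected counts at one-bin separation corresponds to a
deeply sequenced merged map and was fixed a priori by a power
calculation: at the far edge of the default 50 kb-1 Mb band (d = 200 of
400 bins) the per-distance relative s.e. is ~2.2% for X and ~1.1% for the
4-autosome mean, so the enrichment-band ratio of ~1.37 (1.5 shrunk by
X's own unity renormalization) clears the 1.2 assertion with > 3 sigma
at every point.

## Numerical choices, degenerate inputs, limitations

* Otsu ties break toward the lower threshold; histogram is 256 equal-width
  bins over the observed in-nucleus range; constant difference images are
  reported as "bleach not detected" rather than thresholded.
* The correlation refinement grid spans +/- 0.75 px around the integer
  peak at 1/`upsample` spacing; anti-symmetry holds to 1/`upsample`.
* Curves are rejected, with stage-tagged errors, when: the mask is empty,
  fewer than 10 post-bleach points feed the decay fit, fewer than 20 feed
  the recovery fit, or the bleach depth is zero.
* `t_half` is undefined (NA + QC flag) when the curve never crosses half
  its maximum — deliberately so for near-immobile proteins, mirroring the
  exclusion of histone controls from half-time plots.
* The 5% tail window defining the recovery "maximum" is a configurable
  choice (`tail_fraction`); the original window is unstated.
* Known limitations: TIFF support is baseline uncompressed grayscale
  (LZW, tiles and vendor dialects are rejected with clear errors);
  metadata lives in a JSON sidecar, not microscope tags; no background
  ROI subtraction (not part of the described procedure); single-exponential
  recovery only — no diffusion-reaction or double-exponential model
  selection.

## A small worked example

```{r example, eval = FALSE}
p <- frap_sim_params(mobile_fraction = 0.30, tau = 3.75,
                     bleach_depth = 0.9, acquisition_decay_rate = 0.001)
sim <- simulate_frap_movie(p)
res <- analyze_movie(sim$movie, sim$truth$nucleus_mask)
res$fit
#> recovery fit 'sim-seed1': mobile fraction 0.301, tau 3.772 s, t_half 2.615 s
```

The estimates sit within 1% (mobile fraction), 0.6% (tau) and one frame
interval (half-time vs `tau * ln 2 = 2.60` s) of the ground truth — the
regime the acceptance suite locks in.
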