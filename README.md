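# frapkit

Quantitative analysis of **fluorescence recovery after photobleaching
(FRAP)** time-lapse movies, plus the chromosome-scale enrichment
statistics used in X-chromosome dosage-compensation studies. The package
was built for experiments that probe the binding dynamics of chromatin
proteins — e.g. the X-specific condensin of *C. elegans* — by bleaching a
spot inside a nucleus and fitting the recovery, and for the companion
genomics readouts (ChIP spreading profiles, Hi-C contact-decay curves).

## What it computes

Per bleached nucleus, the pipeline runs:

1. **Drift correction** — sub-pixel registration of every frame to the
   pre-bleach mean by upsampled DFT cross-correlation.
2. **Bleach-spot detection** — Otsu thresholding of the difference
   between the mean pre-bleach image and the mean of the first five
   post-bleach images, restricted to the nucleus; the 8-connected
   component containing the difference maximum is the ROI.
3. **Acquisition-bleaching correction** — a monoexponential
   `A e^{-kt}` fitted to the whole-nucleus post-bleach trace divides out
   imaging-induced bleaching.
4. **Double normalization** — each curve rescaled to a pre-bleach mean
   of 1 and an immediate post-bleach value of 0.
5. **Recovery fit** — nonlinear least squares of

   `F(t) = M (1 - exp(-t / tau))`

   on the normalized post-bleach curve; the **mobile fraction** is the
   fitted model at the last recorded time point, and the **half-time**
   is the first crossing of half the observed maximum, read directly
   from the data.

Cohort statistics: mean ± s.e.m. curves, median/IQR/5-95% group
summaries, pooled-variance two-sample t-tests, bin-width-20 pixel
intensity densities and the Mann-Whitney U test.

Chromosome-scale statistics: z-scoring of ChIP/input ratios to an
autosomal background, total-signal equalization, 500 kb / 50 kb sliding
windows, Hi-C contact-decay curves `P(s)` (5 kb bins, up to 20 Mb),
unity normalization over 5 kb–4 Mb and X-to-autosome ratio curves.

A synthetic-data layer (`simulate_frap_movie`, `simulate_cohort`,
`simulate_contact_matrix`, `simulate_spreading_track`) generates inputs
with known ground truth so every stage is testable without raw
microscopy or sequencing data.

## Worked example

```r
library(frapkit)

p <- frap_sim_params(mobile_fraction = 0.30, tau = 3.75,
                     bleach_depth = 0.9, acquisition_decay_rate = 0.001)
sim <- simulate_frap_movie(p)          # 20 + 500 frames at 0.21 s/frame
res <- analyze_movie(sim$movie, sim$truth$nucleus_mask)
res$fit
#> recovery fit 'sim-seed1': mobile fraction 0.301, tau 3.772 s, t_half 2.615 s
```

The simulated ground truth is `m = 0.30`, `tau = 3.75 s` (so
`t_half = tau ln 2 = 2.60 s`): the pipeline recovers the mobile fraction
within 1%, the time constant within 0.6% and the half-time within one
frame interval. The Hi-C side:

```r
sim <- simulate_contact_matrix(noise = "poisson", seed = 1)  # 4 autosomes + X
decays <- lapply(contact_decay(sim$matrices), unity_normalize_decay)
ratio <- xa_ratio(decays, x_chrom = "chrX")
range(ratio$ratio[ratio$s >= 5e4 & ratio$s <= 1e6])   # enriched band
#> [1] 1.29 1.45
```

## Command line

```sh
frap simulate --out movies/ --n 40 --seed 7
frap analyze  --stack movies/movie_001.tif --meta movies/movie_001.json \
              --mask nucleus.tif --out results/
frap cohort   --group wt=results/wt_fit.csv --group mut=results/mut_fit.csv \
              --out cohort/
xa   simulate --out-bins bins.tsv --out-triplets trips.tsv --noise poisson
xa   ratio    --bins bins.tsv --triplets trips.tsv --x chrX \
              --autosomes chrI,chrII,chrIII,chrIV --out ratio.tsv
```

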