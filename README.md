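# domainscope

Quantitative analysis of DNA **replication domains (RDs)** — the ~150-nm,
~500-kbp structural units of interphase chromosomes — from correlative
confocal + single-molecule localization (STORM) imaging, dual-color
confocal spacing data, and live-cell trajectory pairs. The package is
aimed at microscopists and chromatin biologists who label replicating DNA
with fluorescent nucleotide pulses and want the full measurement chain —
localization QC, registration, clustering morphometrics, spacing, motion
coupling, combing calibration — as tested, scriptable R functions.

## What it computes

**Domain ultrastructure (STORM).** Localization event lists
(frame, x, y, photons) are photon-filtered (≥ 500), drift-corrected by
temporal-block cross-correlation (gate: residual < 10 nm), rendered at
10 nm/px, and resolution-gated by Fourier ring correlation with the
3σ criterion (gate: ≤ 50 nm). Co-replicating stretches are detected as
grayscale-dilation maxima after Perona–Malik + median filtering, and
clustered into domains with DBSCAN (MinPts = 2, Eps = 14 px). Reported
per scene: stretches/domain, intra-domain nearest-neighbor distances
(NND), horizontal Feret diameters, solitary fraction.

**Inter-domain spacing (dual-color confocal).** 3D particle detection
(intensity-quantile threshold, 26-connected components,
intensity-weighted centroids) per channel, then the directed
cross-channel NND

d_i = min_j ‖ x_i^(ch1) − x_j^(ch2) ‖,

summarized by medians/quartiles as a function of the pulse interval Δt.

**Mechanical coupling (live-cell tracks).** For each cross-channel
trajectory pair with 15–50 s overlap, the per-step correlation angle

α_t = arccos( u_t · v_t / (|u_t||v_t|) )

between the simultaneous displacement vectors (0° = coupled, mean 90° =
uncoupled). Two OLS lines fitted to the per-pair (mean distance, mean α)
points below 400 nm and above 600 nm intersect at the coupling
transition point (d\*, α\*).

**Combing calibration.** Stretching rate s (kb/µm) fitted on λ-DNA
standards (4.36 / 9.41 / 23.13 kbp), comet-length → kbp conversion with
propagated uncertainty, and the fork-yield consistency product
(4 forks × 2 kb/min × 60 min = 480 kb).

Because the methods are validated without external data, a first-class
**synthetic-data generator** produces ground-truth scenes (shifted-
geometric stretch counts, rejection-sampled stretch placement at a target
NND, solitary stretches excluded beyond the clustering reach), STORM
event lists with localization noise + stage drift, diffraction-limited
confocal stacks, distance-coupled trajectory pairs, and combed fibers.

## Worked example

```r
library(domainscope)
report <- run_pipeline(list(seed = 1))
print(report)
#> <run_report> domainscope 0.1.0
#>   median stretches/RD: 4
#>   median intra-RD NND: 63.2 nm
#>   median Feret:        115 nm
#>   spacing median (dt=60): 307.5 nm
#>   coupling transition: 472 nm
```

Reading the numbers: on the default synthetic preset (30 domains, median
4 stretches at a 63-nm target NND, 12.6% solitary, 8-nm localization
precision), the full chain recovers the count median exactly and the NND
within a few percent; the Feret median (115 nm) measures peak-center
extent, which is systematically below the 150-nm disc diameter; the
Δt = 60 min spacing median recovers the generator's 300-nm neighbor law;
the transition estimate scatters around the 550-nm coupling cutoff at
this problem size (see the vignette for the estimator's bias analysis).

The numbered scripts under `analysis/` run the same stages as a
stepwise workflow (`01_simulate.R` → `06_combing.R`), printing what each
stage finds and writing tables under `results/`. The methods vignette
(`vignettes/domainscope-methods.Rmd`) documents the models, defaults,
numerical choices and limitations.

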