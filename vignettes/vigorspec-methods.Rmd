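---
title: "Methods: simulating and classifying LIBS spectra of seed lots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying LIBS spectra of seed lots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigorspec)
```

## The problem

Laser-induced breakdown spectroscopy (LIBS) records the atomic and ionic
emission of a laser-ablated plasma; the line intensities fingerprint a
sample's elemental composition. For forage-grass seed lots (*Brachiaria
brizantha*, cultivars Marandu and Paiaguás), physiological quality ("vigor",
high HV vs low LV) correlates with the Mg, Ca and K content that drives
enzymatic activity during germination, so high- and low-vigor lots can in
principle be discriminated from their emission spectra — across cultivars,
which contribute their own nuisance structure.

`vigorspec` implements the complete analysis as a reusable, tested pipeline,
driven by a synthetic spectrum generator so that every stage can be exercised
and validated without instrument data:

1. **Acquisition optimization**: a 2³ factorial design with center point over
   laser pulse energy, delay time and gate time, scored by per-line
   signal-to-background ratios (SBR) aggregated through desirability
   functions.
2. **Preprocessing**: per-replicate standard normal variate (SNV)
   normalization, spectral angle mapper (SAM) outlier rejection against the
   sample mean, and per-sample averaging.
3. **Classification**: stratified 90/30 external hold-out, PCA on the
   training block, leave-one-out cross-validated (LOO-CV) grid search over
   four classifiers (KNN, LDA, QDA, SVM), heat-map export, external
   validation of the chosen models.

## The synthetic-data generator

`generator_config()` defaults encode the study conditions the analysis
assumes:

* 120 samples — 20 Marandu-HV, 40 Paiaguás-HV, 40 Marandu-LV, 20
  Paiaguás-LV;
* 50 replicate spectra per sample in each of two detector bands, UV
  (175–330 nm, 0.02 nm step) and VIS (275–775 nm, 0.05 nm step);
* a line library of the monitored macro/micronutrient transitions plus the
  further lines identified in typical spectra (`emission_lines()`);
* a multiplicative **vigor effect** (default 1.3) on all Mg, Ca and K line
  amplitudes of HV samples, and a **cultivar effect** (default 1.2) on the
  disjoint Na/Si line set for Paiaguás — so the nuisance cultivar clustering
  the score plots show is present but carries no vigor information;
* per-sample log-normal amplitude variability (`sample_cv`), per-replicate
  per-line log-normal shot jitter (`shot_jitter_cv`, default 0.10), a flat
  continuum (50 a.u.) and additive Gaussian noise (sd 5 a.u.);
* 2% of replicates per band corrupted into outliers.

A note on the VIS range: the instrument nominally covers 275–750 nm, yet the
monitored K I doublet sits at 766.49/769.90 nm; the default VIS grid
therefore extends to 775 nm so those lines (and their background windows)
are representable.

Lines are rendered as unit-height pseudo-Voigt profiles (fixed 50/50
Gaussian/Lorentzian mix) — a pragmatic shape with realistic wings that is
cheap to evaluate; no physical plasma model (Saha–Boltzmann, self-absorption,
matrix effects) is attempted. Line centers are snapped to the nearest grid
node, so a rendered peak equals its amplitude exactly; with grid steps of
0.02–0.05 nm against FWHMs of 0.1–0.2 nm the displacement is negligible, and
it makes peak-height and SBR arithmetic exactly testable.

### Calibration of the free parameters

Raw intensity scales and noise magnitudes are not reported for the real
instrument, so they are calibration choices of the generator. Base
amplitudes (200–2000 a.u.) follow the qualitative prominence of the lines in
published seed spectra (Ca II 393.36 and Mg II 279.55 strongest). The one
genuinely sensitive choice is `sample_cv`, the between-sample amplitude
variability: the vigor effect acts on the same Mg/Ca/K lines whose
variability dominates within-class spread, and SNV renormalization couples
every line's fluctuation into every other line. In the UV band (where only
the Mg lines carry vigor signal) the class margin along the first principal
component is roughly `log(1.3)` divided by `sample_cv` in units of
within-class SD; the default `sample_cv = 0.025` puts that margin near 4 SD,
which reproduces the reference behavior — 100% external accuracy for every
algorithm in both bands — while keeping within-class spread real (samples
range over ±3 SD within a class). Raising `sample_cv` to ~0.08 degrades UV
external accuracy into the low 0.9s, which is useful for studying the
workflow away from its clean regime.

### What passing tests do and do not show

The generator emulates the *statistical structure* of the study — class
composition, replicate counts, effect placement on Mg/Ca/K vs Na/Si,
multiplicative shot noise, corrupted replicates — not the physics of a real
plasma (no self-absorption, no line-shape changes with gate timing, no
matrix effects, no wavelength drift). Pipeline results on synthetic data
therefore validate the *implementation* (no leakage, correct formulas,
correct selection logic), and the 100%-accuracy acceptance run shows the
workflow recovers a class structure of the assumed kind; it says nothing new
about real seeds.

## Outlier injection and the SAM filter

Corrupted replicates receive a random non-empty subset of three distortions
(strong baseline ramp; suppression of the strongest 60% of the band's lines;
a broad spurious spike of 10× the spectrum maximum), each calibrated to
push the SNV-SAM similarity to the sample mean well below the 0.90
threshold. The filter is single-pass: the reference is the mean of *all*
input replicates and is not recomputed after discards — the simplest
auditable reading; whether the original analysis re-averaged after exclusion
is not stated. Replicates are counted per band, and the number corrupted is
`round(n × fraction)` with halves rounded away from zero. SAM is reported as
the cosine of the spectral angle (larger = more similar), matching a
threshold of 0.90 under which spectra are "discarded"; an angle in radians
would order the other way.

The order of operations is fixed as SNV → SAM filter → average. SNV uses the
sample (n−1) standard deviation; SAM is scale-invariant, so this choice only
matters for making averaged outputs bit-reproducible.

## Factorial design and desirability

The design is the standard 2³ corner set plus three center replicates
(11 runs), with the fixed coded→real mapping: energy {29.73, 42.29,
54.86} mJ, delay {0.5, 1.0, 1.5} µs, gate {1, 11, 20} µs. SBR is
`(I_peak − Ī_bg)/Ī_bg` with the peak searched in the line's signal window
and the background averaged over two flanking line-free windows (the cited
SBR literature does not print a formula; peak-over-local-continuum is the
common LIBS reading, and fixing it makes the arithmetic exactly testable).
Individual desirability is one-sided larger-is-better min–max scaling of
each line's SBR across the 11 experiments; if a line's SBR is flat across
experiments it carries no preference and is set to 0.5 everywhere with a
warning rather than aborting the whole design. The overall desirability is
the *arithmetic* mean of the line desirabilities — deliberately not the
geometric mean, which is annihilated by any single zero. Main effects are
plain corner contrasts (mean at +1 minus mean at −1); significance testing
of a response-surface model is out of scope.

## Classification choices

* **Split**: 15 HV + 15 LV samples held out, stratified by vigor only —
  cultivar is deliberately ignored, since the point of the workflow is
  cultivar-independent vigor discrimination.
* **PCA**: mean-centering only, no column autoscaling; loadings from the
  training block only; validation samples are always projected with the
  training-fitted model. Sign convention: each loading's largest-magnitude
  entry is positive.
* **PCA and LOO**: the PCA is fitted once on the 90-sample training block
  and LOO-CV runs in score space. Refitting PCA inside each fold is the
  stricter variant and is available (`pca_in_fold = TRUE`); the default
  follows the described workflow (scores precede classification) and its
  mild optimism only affects model selection, never the external
  validation, which uses held-out samples end to end.
* **Grids**: 1–20 PCs throughout; KNN k 1–45; LDA solvers
  svd/lsqr/eigen — three numerical routes to the same pooled-covariance
  discriminant, required to agree, which the test suite checks; QDA
  regularization r ∈ {0.0, …, 0.5} with the sklearn-style shrinkage
  `Σ_r = (1−r)·Σ̂ + r·(tr Σ̂/p)·I`; SVM C ∈ {0.1, 1, 10, 100, 1000, 10000}
  with an RBF kernel of bandwidth `1/(p · mean feature variance)` (the
  kernel is not stated in the reference workflow; this is the de-facto
  default). The printed C grid omits 1.0 even though the best reported
  model uses C = 1.0; the grid here includes it.
* **Tie-breaks** (not stated in the reference workflow, fixed here so runs
  are reproducible): grid search takes max accuracy, then fewest PCs, then
  the earlier hyperparameter in grid order; KNN breaks vote ties by the
  single nearest neighbor and distance ties by the lower training index.
* **Degenerate folds**: a LOO fold that cannot be fit (e.g. single-class
  for a discriminant) counts as an error on that fold rather than aborting
  the search.
* Bands are processed as fully independent pipelines, never fused.

## Reproducibility and problem sizes

Every stage seed is derived from one master seed by a stable string hash of
the stage name (`stage_seed()`), so adding or reordering stages never
shifts another stage's random stream; two runs with the same configuration
produce byte-identical CSV/JSON artifacts. The acceptance script and the
end-to-end tests run the full default conditions (120 samples × 50
replicates × 2 bands, all four 20-row grids; about 2–3 minutes on one
core). Unit and property tests use reduced generators — typically 120 or
fewer samples, 4–12 replicates, a single coarsened UV grid — which exercise
identical code paths; the chance-level (no-vigor-effect) property is checked
over 20 seeds at 6 replicates per sample on a 0.1 nm UV grid, pooling 600
external predictions per algorithm against the 99% binomial band around
0.5.

## Known limitations

* No physical plasma modeling; the factorial design's response surface is
  flat in the generator unless amplitudes are made to depend on the design
  point explicitly (as `simulate_doe_spectra()` does).
* The SBR definition and the per-line desirability anchoring (observed
  min–max across experiments, rather than absolute anchors) are the
  package's readings of under-specified conventions; both are stated
  explicitly above and fixed in code.
* LDA/QDA/KNN are binary here by construction of the workflow; nothing in
  the implementation generalizes to more than two classes intentionally.
* Heat maps on well-separated synthetic data saturate at 100% over wide
  regions, so the *chosen* cells (smallest PCs / earliest hyperparameter
  among the maximal set) are not comparable to choices made on noisier real
  data.
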