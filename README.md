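# vigorspec

Chemometric discrimination of high- vs low-vigor forage seed lots from
laser-induced breakdown spectroscopy (LIBS), with a synthetic spectrum
generator that makes the whole workflow testable end to end.

LIBS ablates a sample with a pulsed laser and records the plasma's atomic
and ionic emission lines; the Mg, Ca and K lines in particular track the
physiological quality ("vigor") of *Brachiaria brizantha* seed lots. The
package is aimed at spectroscopists and chemometricians who want the full
analysis — acquisition optimization, preprocessing, outlier rejection, and
supervised classification with honest external validation — as composable,
tested R functions rather than a one-off script.

## What it implements

**Acquisition optimization** over a 2³ factorial design with center point
(laser pulse energy × delay time × gate time, 11 runs). Each run is scored
by the signal-to-background ratio of ten monitored emission lines,

&nbsp;&nbsp;&nbsp;&nbsp;SBR = (I_peak − Ī_bg) / Ī_bg,

each line's SBR is converted to an individual desirability by larger-is-
better min–max scaling across runs, DI = (SBR − min)/(max − min), and runs
are ranked by the overall desirability OD = mean(DI) (arithmetic mean, so a
single DI = 0 line cannot annihilate the score).

**Preprocessing**: each replicate spectrum x is SNV-normalized,
z = (x − x̄)/s; replicates whose spectral-angle-mapper similarity to the
sample mean, cos θ = ⟨z, z̄⟩/(‖z‖‖z̄‖), falls below 0.90 are discarded; the
survivors are averaged into one spectrum per sample per band.

**Classification**: a stratified external hold-out (15 HV + 15 LV of the
120 samples), PCA (mean-centering only) fitted on the 90 training samples,
and a leave-one-out cross-validated grid search over the number of PCs
(1–20) and each algorithm's hyperparameter — KNN (k = 1–45), LDA (three
solver routes, required to agree), regularized QDA
(Σ_r = (1−r)Σ̂ + r·(trΣ̂/p)·I, r = 0–0.5), and an RBF SVM
(C = 0.1–10000). The chosen models are then validated on the untouched
30-sample hold-out; accuracy matrices are exportable as heat-map CSVs.

**Synthetic data**: `generate_dataset()` renders pseudo-Voigt emission
spectra for the 120-sample study composition (50 replicates per sample in
UV and VIS bands) with a vigor effect on the Mg/Ca/K lines, a cultivar
nuisance effect on Na/Si, log-normal sample and shot-to-shot variability,
additive noise, and a ground-truth-labelled fraction of corrupted
replicates. See `vignettes/vigorspec-methods.Rmd` for every modeling
choice and its rationale.

## Worked example

A reduced configuration (30 samples, 10 replicates, one coarsened UV band)
that runs in a few seconds:

```r
library(vigorspec)

cfg <- run_config(
  generator = generator_config(
    composition = data.frame(
      cultivar = c("Marandu", "Paiaguas", "Marandu", "Paiaguas"),
      vigor    = c("HV", "HV", "LV", "LV"),
      n        = c(5, 10, 10, 5)),
    replicates_per_sample = 10,
    bands = list(UV = list(min = 175, max = 330, step = 0.05))),
  algorithms = c("knn", "lda"),
  grids = list(knn = grid_spec("knn", pc_grid = 1:8, hyper_grid = c(1, 3, 5)),
               lda = grid_spec("lda", pc_grid = 1:8)),
  n_validation_per_class = c(HV = 4, LV = 4),
  master_seed = 42)

run <- run_pipeline(cfg)
run$results[, 1:6]
#> # A tibble: 2 × 6
#>   algorithm band  n_pcs hyper cv_accuracy accuracy
#>   <chr>     <chr> <int> <chr>       <dbl>    <dbl>
#> 1 knn       UV        2 1               1        1
#> 2 lda       UV        2 svd             1        1
```

`cv_accuracy` is the best LOO-CV accuracy on the training block (here both
algorithms reach 1.0 with 2 PCs; ties resolve toward fewer PCs and the
earlier hyperparameter), and `accuracy` is the external accuracy on the 8
held-out samples the models never saw:

```r
run$results$report[[2]]
#> <validation_report> LDA [UV]: accuracy 1.000 on 8 samples
#>      predicted
#> truth HV LV
#>    HV  4  0
#>    LV  0  4

sprintf("discarded: %.2f%% of replicate spectra", 100 * run$discarded_fraction)
#> "discarded: 2.00% of replicate spectra"
```

The 2% discarded are exactly the corrupted replicates the generator
injected. `autoplot()` on any grid-search map draws its heat map;
`tidy()`/`glance()` turn maps, PCA models and validation reports into
tibbles. `run_all(cfg, out_dir)` additionally writes heat-map CSVs,
`filter_report.csv` and `report.json`, and `exec/vigorspec` exposes
`simulate`, `preprocess`, `doe` and `run-all` as shell subcommands.

For the acquisition-optimization side:

```r
select_best(c(0.64, 0.63, 0.95, 0.68, 0.64, 0.49, 0.33, 0.30, 0.42, 0.83, 0.67))
#> [1] 3
```

ranks 11 factorial runs by overall desirability — run 3 (54.86 mJ, 0.5 µs
delay, 20 µs gate) wins with OD 0.95 — and `doe_results()` computes the
same ranking from spectra.

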