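# roiclass

Multi-site ROI classification with empirical-Bayes harmonization, repeated
nested cross-validation, permutation significance and ROI importance maps.

## The problem

Consortium neuroimaging studies pool region-of-interest (ROI) tables — one
scalar per atlas region per subject (cortical thickness, surface area,
subcortical volume, or white-matter FA/RD) — across many acquisition
sites, and ask whether patients (for example temporal lobe epilepsy, with
or without hippocampal sclerosis, left- or right-onset) can be classified
from those features at the individual level. Site effects and
case/control imbalance both break naive classifiers. `roiclass` is for
analysts running such studies: it packages the full workflow and ships a
multi-site synthetic cohort generator with known ground truth so that
every stage can be validated end to end without clinical data.

## What it computes

* **Harmonization** (`fit_combat`/`apply_combat`): per feature $g$,
  site $i$, subject $j$, the location/scale model
  $y_{ijg} = \alpha_g + X_{ij}\beta_g + \gamma_{ig} +
  \delta_{ig}\varepsilon_{ijg}$ is fit by least squares; site effects
  $\hat\gamma_{ig}, \hat\delta^2_{ig}$ are shrunk to empirical-Bayes
  posteriors $\gamma^*_{ig}, \delta^*_{ig}$ (normal / inverse-gamma
  priors, iterated to $10^{-4}$) and removed:
  $y^{adj}_{ijg} = \hat\sigma_g (z_{ijg} - \gamma^*_{ig})/\delta^*_{ig} +
  \hat\alpha_g$.
* **Evaluation** (`run_repeated_evaluation`): per iteration, undersample
  the majority class, stratified 80/20 split, 10-fold grid search (linear
  SVC over $C \in [0.1, 2]$, or a 2-hidden-layer softmax network over the
  standard learning-rate/epochs/width/L2/dropout ranges), select the best
  fold pipeline, and score the untouched test rows: PPV, NPV, SEN, SPC,
  AUC (Mann-Whitney), ACC. Repeated R times (study scale: 1000).
* **Significance** (`run_null_evaluation`, `compute_p`): the same protocol
  with permuted training labels and grid search replaced by the optimal
  hyperparameters gives a null distribution; $p = \#\{\text{null} \ge
  \bar m_{opt}\}/R$ (an optimal mean beating 980 of 1000 nulls gives
  $p = 0.02$).
* **Model comparison** (`compute_fdci`): frequency distribution comparison
  index — the fraction of (SVC, DLC) accuracy pairs where SVC is higher,
  ties at half weight; 0.5 is equipoise.
* **Importance** (`svc_importance`, `dlc_importance`): mean absolute SVC
  weights, or absolute connection-weight backtracking through the network,
  min-max normalized to [0, 1] per schema feature.

## Worked example

```r
library(roiclass)

# two-site synthetic cohort, 41 diffusion-FA features, effect d = 1.5 on
# the first 10 (left-hemisphere) tracts
cfg <- generator_config(d = 1.5, n_sites = 2, gamma_bar = c(0, 0.05),
                        n_per_group = c(HC = 80, "TLE-HS-L" = 50), seed = 42)
sim <- generate_cohort(cfg)
sim$cohort
#> <roi_cohort> 260 subjects x 41 features (diffusion_FA)
#>   groups: HC=160 TLE-HS-L=100
#>   sites:  2

study <- run_config(
  "TLE-HS-L", "HC", models = c("svc", "dlc"), R = 25, R_null = 100,
  master_seed = 42,
  grid_dlc = grid_spec("dlc", values = list(
    learning_rate = c(0.002, 0.005), epochs = c(100, 200),
    hidden1 = c(10, 20), hidden2 = c(5, 10),
    l2_penalty = 0.1, dropout_rate = 0.2), subsample_k = 4))
rep <- run_study(study, sim$cohort, outdir = "results/demo")
rep
#> <study_report> task: {TLE-HS-L} vs {HC}
#>   SVC: ACC 0.947 +/- 0.033 (R = 25), p[ACC] = 0
#>   DLC: ACC 0.950 +/- 0.037 (R = 25), p[ACC] = 0
#>   FDCI (SVC vs DLC): 0.474

head(export_importance(rep$importance$svc)[
  , c("name", "measure", "hemisphere", "importance")], 5)
#>        name measure hemisphere importance
#> 1  CST_L_FA      FA       left  1.0000000
#> 2   IC_L_FA      FA       left  0.7862726
#> 3  CGH_L_FA      FA       left  0.7461316
#> 4  ACR_L_FA      FA       left  0.7217330
#> 5 ALIC_L_FA      FA       left  0.6810663
```

Reading the output: both classifiers separate cases from controls at ~95%
mean test accuracy over 25 repetitions; neither real-label mean accuracy
is ever reached by the 100 permuted-label pipelines, so both p-values are
0 under the counting rule; the FDCI of 0.474 says the two accuracy
distributions are near equipoise (0.5); and the most influential ROIs are
left-hemisphere tracts — exactly where the simulated effect was placed.
`results/demo/` holds per-iteration metrics, null metrics, significance
tables, importance maps (CSV) and a `summary.json` embedding the resolved
configuration and seeds.

A command-line surface with `simulate`, `harmonize`, `evaluate`,
`compare` and `run-study` subcommands is installed at
`system.file("cli", "roiclass", package = "roiclass")`.

## More detail

The methods vignette (`vignettes/methods.Rmd`) documents the generative
model, the harmonization conventions, the evaluation protocol, the
tie-breaking and degenerate-input rules, and what the synthetic benchmarks
do and do not establish.
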