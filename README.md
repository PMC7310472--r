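# immunofrail

Machinery for studying how the cellular composition of peripheral blood
relates to **frailty** in older adults, and for testing that machinery end
to end on synthetic data with known ground truth.

The scientific question: as people age, the balance of leukocyte
subpopulations shifts — does that shift track *general health* (measured as
a deficit-accumulation frailty index), and does it do so differently in men
and women once age and cytomegalovirus (CMV) serostatus are accounted for?
Answering it takes a pipeline with many moving parts, each implemented and
tested here:

* **Synthetic cohorts** (`generate_cohort`, `generate_tube_events`):
  participants aged 60–87 sampled in healthiest/intermediate/frailest
  strata, 36 probit-model deficit items driven by a latent health score,
  two-component lognormal CMV IgG titers, and event-level two-tube flow
  cytometry. Log cell concentrations are tied to the latent score by a
  Gaussian copula, *calibrated* so the within-block Spearman correlation
  between each targeted phenotype and the frailty index equals its
  configured effect size (defaults: neutrophils ρ = 0.25 in men; in women
  neutrophils 0.40, CD16− monocytes 0.24, CD56+ T cells −0.20, CD4 TemRA
  −0.13).
* **Hierarchical gating** (`classify_events`): 37 leukocyte subpopulations
  as conjunctions of channel-band predicates down a tree rooted at CD45+
  leukocytes — neutrophils, monocytes (±CD16), four CD56×CD16 NK subsets,
  B cells (transitional/naive/memory), CD56+ T cells, and the full
  CCR7/CD45RA × CD27/CD28 differentiation grid of CD4 and CD8 T cells plus
  regulatory and follicular-helper T cells.
* **Absolute enumeration** (`trucount_concentration`, `falcon_scaling`):
  bead-ratio arithmetic for the counting-bead tube (cells/µL =
  events × beads-per-tube / bead-events / volume) and a CD3 bridge scaling
  the second tube's counts; proportions of designated parent populations;
  manual debris-exclusion flags.
* **Frailty index** (`frailty_index`): mean of 36 deficit items in [0, 1],
  with the usual ≥30-observed-items convention and a square-root transform
  for prediction.
* **CMV serostatus** (`fit_two_component_mixture`,
  `seropositivity_cutoff`): EM on log titers with restarts; the cutoff is
  the intersection of the weighted component densities, solved in closed
  form in the log domain.
* **Blocked permutation tests** (`blocked_permutation_test`,
  `run_association_study`): within-block permutation of the outcome with a
  block-weighted Spearman rho (frailty) or a van Elteren-style blocked
  Wilcoxon–Mann–Whitney statistic (sex, CMV), add-one simulated p-values
  with Monte-Carlo SEs, and Benjamini–Hochberg control at FDR 15% per study
  family. Blocks are age quartiles × CMV status.
* **Random-forest prediction** (`fit_frailty_forest`, `pct_inc_mse`,
  `partial_dependence`): per-sex forests predicting sqrt-frailty from all
  37 counts plus age, CMV and measurement date; importance as the raw
  percentage increase in out-of-bag MSE under predictor permutation;
  partial dependence over the central data range.
* **One-command pipeline** (`run_all`, `inst/cli/immunofrail.R`): simulate
  → gate → count → frailty → serostatus → 10 association studies → 2
  forests, all tables written with provenance metadata, byte-reproducible
  from a seed.

## Worked example

```r
library(immunofrail)

sim <- generate_cohort(cohort_spec(seed = 7))
sim
#> Synthetic cohort: 289 participants ( 145 men, 144 women ), 37 phenotypes, seed 7

sero <- serostatus_pipeline(sim$cohort$cmv_igg, seed = 11)
sero$fit
#> Two-component Gaussian mixture (log scale), n = 289
#>   comp 1: mu = 0.940, sigma = 0.644, weight = 0.415
#>   comp 2: mu = 3.847, sigma = 0.888, weight = 0.585
#>   loglik = -510.61 after 43 iterations (converged: TRUE)
round(as.numeric(sero$cutoff), 2)   # IgG concentration cutoff
#> [1] 8.66

sim$cohort$cmv_status <- sero$status
cm <- truth_count_matrix(sim)
res <- run_association_study(cm, sim$cohort, "frailty_by_sex",
                             n_perm = 10000, seed = 12)
res[res$stratum == "F" & res$bh_reject, c("phenotype", "weighted_rho", "p")]
#>          phenotype weighted_rho      p
#>        neutrophils         0.43 0.0001
#>          monocytes         0.27 0.0026
#>  monocytes_cd16neg         0.24 0.0074

fit <- fit_frailty_forest(cm, sim$cohort, "F", seed = 13)
fit
#> Frailty forest (F): 1000 trees, mtry 13, n = 137
#>   OOB MSE = 0.05898, PEV = 9.7%
head(rank_importance(pct_inc_mse(fit, n_repeats = 5, seed = 14)), 3)
#>          predictor pct_inc_mse ...
#>        neutrophils        18.2
#>  monocytes_cd16neg         2.2
#>          monocytes         1.6
```

Reading the output: in the 137 women with an observed frailty index,
frailty correlates with higher neutrophil (block-weighted ρ = 0.43) and
classical-monocyte counts after stratifying on age group and CMV status,
and those phenotypes pass Benjamini–Hochberg at FDR 15%; the forest
explains 9.7% of the variance of sqrt-frailty out of bag, with neutrophils
the clearly dominant predictor (18% MSE increase when permuted). At this
cohort size the weaker planted effects (CD56+ T cells, CD4 TemRA) do not
always clear the FDR bar — exactly the behaviour a power calculation would
predict.

The full pipeline from a config file:

```sh
Rscript inst/cli/immunofrail.R run --config run.yaml --out results/
```

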