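---
title: "Methods: simulating and analysing immune profiles against frailty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing immune profiles against frailty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunofrail)
```

## The scientific setting

Peripheral-blood leukocyte composition changes with age, and it does so
differently in people who stay healthy and in people who become frail.
`immunofrail` implements the full analytical machinery for studying that
relationship in a cohort of older adults (ages 60–87): absolute
enumeration of 37 leukocyte subpopulations from two-tube flow cytometry, a
36-item deficit-accumulation (Rockwood-type) frailty index,
cytomegalovirus (CMV) serostatus from an IgG mixture model, sex-stratified
blocked permutation association tests, and a random-forest prediction
study. Because event-level cytometry and cohort data of this kind are not
freely redistributable, the package is built around a synthetic-data
generator that reproduces the statistical structure the analysis assumes;
every downstream stage is exercised and tested against generator ground
truth.

## The synthetic cohort generator

### Latent health and deficits

Each participant carries a latent health score $H$ (higher = frailer).
The cohort emulates a frailty-stratified subcohort design: equal numbers
of participants are drawn from the healthiest 15%, the middle 70%, and the
frailest 15% of the latent distribution of their sex (the strata
boundaries are configurable; `strata_fractions` must sum to 1). The
36 deficit items are noisy probit indicators of the latent score: item $j$
is present when

$$a\,(H + \delta\,(g - \bar g)) + \sqrt{1-a^2}\,\varepsilon_{ij} > \tau_j,$$

with item loading $a$ (`deficit_loading`, default 0.6), an age-group trend
$\delta$ (`age_effect`, default 0.2 per age-quartile step), and cutpoints
$\tau_j$ set from marginal prevalences spread over 0.02–0.40. The frailty
index is the mean of the 36 items. The loading below 1 matters: perfectly
nested (Guttman-type) items would put a large point mass at index 0 and
cap the attainable rank correlations around 0.89, whereas noisy items give
a realistic right-skewed index (median ≈ 0.17, ≈ 15% exact zeros in the
selected cohort) and a ceiling near 0.95. The item identities are not
modelled — only the index enters any analysis — so exchangeable items
driven by one latent score are sufficient.

### Calibrated rank correlations

Log cell concentrations are tied to the latent health score by a Gaussian
copula: for leaf population $k$,

$$\log C_k = \log(\text{base}_k \cdot m_k) + \sigma_k\,(r_k H + \sqrt{1-r_k^2} Z_k),$$

where $m_k$ collects sex, CMV and age multipliers that are constant within
an age-group × CMV block (so they cannot create within-block correlation),
and $r_k$ is chosen so that the within-block Spearman correlation between
$C_k$ and the *frailty index* equals the configured target. Because the
index is a noisy, tied, monotone transform of $H$ and the cohort is
selected on $H$, the classical sin transform $r = 2\sin(\pi\rho/6)$ is
only the no-selection, no-ties limit. The generator therefore inverts the
map $\rho(r)$ numerically: a deterministic grid of latent draws under the
selection design (mid-probability points, 16,384 of them), one common
random residual vector, Spearman correlations on an $r$-grid, and monotone
interpolation. The calibration is cached and runs on a private RNG stream,
so warm and cold caches leave the main stream untouched and cohorts are
byte-reproducible from their seed.

When one effect entry covers several generator leaves (e.g. "CD4 TemRA"
spans its early/late/intermediate stages), giving each leaf the
single-leaf $r$ would overshoot: idiosyncratic noise partially cancels in
the sum, raising the aggregate's rank correlation. The generator inverts
the aggregate map directly in that case, simulating the summed
concentration on the same latent grid.

The default effect profile encodes the study conditions: in men,
neutrophils at $\rho = 0.25$; in women, neutrophils at $0.40$, classical
(CD16−) monocytes at $0.24$ (non-classical at $0.10$, so total monocytes
land near $0.23$), CD56+ T cells at $-0.20$ and CD4 TemRA cells at
$-0.13$. Unattainable targets (beyond the index's correlation ceiling)
fail with an error naming the offending phenotype rather than silently
truncating.

### Event-level data

Each participant yields two tubes. Event counts per leaf population are
Poisson with mean (concentration × stained volume × acquisition
fraction); channel intensities are lognormal with band centres $e^2$,
$e^4$, $e^6$ (negative/dim/bright) and common log-sd 0.25, which puts
every population about 4 SD from the default gate cuts ($e^3$, $e^5$) —
separable by design, as the classification-accuracy tests require. The
bead tube adds a counting-bead population (bright in all antibody
channels, CD45-negative and low scatter so it stays outside the leukocyte
tree) with the same acquisition fraction as the cells, which is what makes
the bead arithmetic exact in expectation. Stained volume (50 µL), beads
per tube (50,000) and acquisition fraction (0.5) are configurable
defaults declared by this package, not inferred from any instrument.

What the generator deliberately does *not* emulate: spectral spillover,
doublets, debris, instrument drift, day effects, or heavy-tailed marker
distributions. Passing the round-trip and accuracy tests therefore shows
the pipeline's arithmetic and logic are right, not that the gates would
survive real cytometer artefacts; on real data the thresholds are meant to
be adjusted per channel (they are a plain config table).

## Gating and quantification

Phenotypes are conjunctions of channel-band predicates inherited down a
tree rooted at CD45+ leukocytes; a child's events are a subset of its
parent's by construction, and ties exactly at a cut fall in the higher
band (documented and tested). The default table enumerates exactly 37
subpopulations. The published gating text leaves two points open, which
this package resolves as follows: the neutrophil gate is read as
side-scatter-bright AND CD45-dim (the standard CD45/SSC picture and the
only self-consistent reading), and the NK compartment is subdivided into
four CD56-by-CD16 subsets (CD56 bright CD16−, CD56 dim CD16±, CD56− CD16+)
— choosing four rather than three is also what brings the enumerated table
to 37. Regulatory T cells are defined by CD25-bright (naive subset
CD45RA+), reflecting a panel without FoxP3/CD127.

Bead-tube phenotypes convert to cells/µL by the bead ratio
(events × beads-per-tube / bead-events / volume); the differentiation
panel in the bead-free tube is bridged through CD3: its gated counts are
scaled by the bead-tube CD3 concentration divided by the plain tube's CD3
event count — the only dimensionally consistent reading of a "CD3 ratio
between tubes". Concentrations are kept as real numbers (no rounding):
the downstream statistics are rank-based, and rounding would manufacture
ties. Debris-exclusion flags are input metadata mirroring manual
judgment, never auto-detected.

## Frailty index conventions

The index is the mean of the 36 items in $[0,1]$; graded items are
allowed (deficit-accumulation indices commonly grade severity) though the
generator default is binary. With missing items the index is computed
over the observed ones when at least 30 of 36 are observed, otherwise it
is missing — the usual deficit-index convention, made configurable.
Participants without an index are excluded from frailty analyses only;
sex and CMV contrasts keep the full cohort. The prediction response is
the square root of the index, a monotone transform that symmetrizes the
right-skewed distribution; predictions and explained variance are
reported on that scale without back-transforming.

## CMV serostatus

IgG concentrations are fitted on the log scale with a two-component
Gaussian mixture by EM (quantile-based start plus random restarts, best
converged fit kept, components relabelled so $\mu_1 < \mu_2$). The
mixture family is a package choice: log-Gaussian components are standard
for titer data. The seropositivity cutoff is the point between the
component means where the weighted densities intersect, solved from the
quadratic in the log domain (with equal variances it reduces to
$(\mu_1+\mu_2)/2 + \sigma^2\log(w/(1-w))/(\mu_2-\mu_1)$); titers at the
cutoff are called positive. The fit set may differ from the classify set,
emulating a cutoff derived from a larger pooled reference sample.
Degenerate collapses ($\sigma \to 0$) trigger restarts and, if universal,
an error rather than a silent point-mass fit.

## Blocked permutation association tests

All association tests are stratified: blocks are age-quartile groups
(boundaries from the cohort's own age distribution) crossed with CMV
serostatus for the sex and frailty analyses, age groups only for the CMV
analyses. Within each block the outcome side is permuted; across blocks
the statistic is combined as

* **frailty**: the block-weighted Spearman rho, $\sum_b w_b \rho_b /
  \sum_b w_b$ with $w_b = n_b$ (the weight is a package choice — the
  source analysis says "weighted" without stating the weight; $w_b =
  n_b - 1$ is available via the `weights` argument), and
* **sex / CMV contrasts**: a van Elteren-style Wilcoxon–Mann–Whitney
  statistic, the sum over blocks of centered within-block rank sums each
  scaled by its tie-corrected permutation SD.

Midranks are used throughout; blocks with fewer than 3 usable pairs (or a
missing group) are dropped and reported. Two-sided p-values use the
add-one estimator $(1 + \#\{|T^\ast| \ge |T|\})/(B+1)$, which is valid for
any $B$; the Monte-Carlo SE is reported so users can scale $B$ up. The
desk default is $B = 10^4$ (the original analysis used $10^8$; the
estimator is the same, only the SE changes). Because both statistics are
linear in a per-block-permuted score vector, one permuted outcome matrix
is shared across all phenotypes of a study, which is what keeps a
37-phenotype × 10-study run cheap. Benjamini–Hochberg step-up decisions at
FDR 15% are taken separately within each study family (per sex stratum,
per scale), and the proportions analysis reuses identical machinery on
the percent-of-parent matrix.

Exactness is tested against full within-block enumeration on small
instances, validity ($P(p \le \alpha) \le \alpha$) by simulation, and the
pipeline-level FDR on 100 simulated 30-null/7-effect studies.

## Random-forest prediction

Per sex stratum, a regression forest (1000 trees, `mtry` = p/3 — the
regression convention; the source analysis states no settings) predicts
sqrt-frailty from all 37 absolute counts plus age, CMV serostatus and the
measurement date encoded as days since the earliest draw. Performance is
PEV = 100(1 − OOB MSE / response variance). Importance is the *raw*
percentage increase in OOB MSE when a predictor is permuted — computed
from per-tree OOB predictions, averaged over repeats with an SE — because
that is the verbal definition of the measure; the SD-scaled variant many
implementations report by default is available via `sd_scaled = TRUE`.
Raw percentages are only comparable against the same baseline MSE, which
is why the negative-control bound (CMV below a 7% MSE increase) is
evaluated within each fitted forest. Partial dependence fixes one or two
predictors on a grid restricted to the central 1st–99th percentile range
(plots are meant to show where the data are) and averages predictions
over the observed rows; predictor deciles are returned for axis rugs.
Ties in the importance ranking break by predictor-name order, a stable
documented rule.

## Reproducibility and problem sizes

Every stage consumes a seed derived from the run seed and the stage name
(`derive_seed`), so stages are independently reproducible and a rerun of
`run_all()` with the same config is byte-identical; output tables carry
the config hash and seed. The problem sizes used by the package's own
checks are chosen to make the statistical assertions sharp but cheap:
correlation-recovery cohorts of 40,000 (≈5,000 per block, Monte-Carlo SE
≈ 0.005 on a weighted rho), 100 simulated studies at $B = 2000$ for the
FDR check, and 10–20 forest seeds for the importance checks. Users
reproducing the full-scale analysis should raise `n_perm` toward the
original $10^8$ only if they need p-values resolved beyond the reported
Monte-Carlo SE.

## Known limitations

* The 37-phenotype table is a reconstruction from the published gating
  descriptions; the full original definition table is not public, so the
  table ships as an editable config and the package asserts only its own
  default.
* Gate thresholds are global per channel; real panels need per-batch
  tuning and compensation, which are out of scope.
* The generator's effect profile induces rank correlations with the
  frailty index but no interactions among cell populations; the
  random-forest stage will therefore underestimate the value of
  interaction-sensitive methods on real data.
* Event tables are read from CSV; binary cytometry formats are not
  parsed.
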