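---
title: "Trait-based analysis of range change from atlas records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based analysis of range change from atlas records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangetraits)
```

`rangetraits` implements a complete workflow for asking which species
traits predict distributional change between two atlas-recording periods:
from raw occurrence records on the British national grid, through
effort-aware range-change indices and outlier screening, to all-subsets
multimodel averaging of trait effects and phylogenetic robustness checks.
A packaged 23-species Orthoptera dataset (two decadal periods, 844
surveyed 10 km squares) exercises every step, and a synthetic-data
generator supports power and recovery experiments.

## From records to occupancy

Occurrence records carry a species name, an Ordnance Survey grid
reference, and a year. `parse_gridref()` accepts references from 10 km
(hectad) down to metre precision, including 2 km tetrad letters, and
reports each reference's hectad and precision:

```{r}
parse_gridref(c("SU1234", "SU13", "SU13A", "TQ123456"))
```

`summarize_occupancy()` converts records to per-period
species-by-hectad presence matrices, and `surveyed_squares()` restricts
attention to hectads with at least `k` species recorded in *both*
periods, a standard control for uneven recording coverage. Species
occupying fewer than 5 surveyed squares in the first period are dropped
by `apply_inclusion_filter()`.

## Range-change indices

With `x1` and `x2` occupied squares out of `n` surveyed squares in the
two periods, the *uncorrected* index is the difference of empirical
logits,

\[ u = \mathrm{logit}^*(x_2/n) - \mathrm{logit}^*(x_1/n), \qquad
   \mathrm{logit}^*(x/n) = \log\frac{x + 0.5}{n - x + 0.5}, \]

where the +0.5 adjustment stabilizes small counts. Because recording
effort roughly doubled between the packaged periods, the uncorrected
index confounds true change with effort. The *corrected* index regresses
the second-period logits on the first-period logits across species and
takes each species' internally studentized residual
(`telfer_index()`), a relative measure that is insensitive to any
common effort shift:

```{r}
fix <- orthoptera_traits()
tab <- range_change_table(fix$species, fix$x1, fix$x2, n = 844)
head(tab[c("species", "x1", "x2", "uncorrected", "corrected")])
```

The effort-doubling design property is easy to verify by simulation:
doubling detection effort alone shifts every uncorrected index upward
but leaves the corrected index centred on zero.

## Outlier screening

Species undergoing extreme expansion distort a cross-species
regression. `sequential_grubbs()` applies the Grubbs test
(maximum standardized deviation, one-sided p capped at 1)
iteratively: test, remove the most extreme value if significant,
retest.

```{r}
unc <- uncorrected_change(fix$x1, fix$x2, 844)
sequential_grubbs(unc, labels = fix$species)
```

On the packaged data this flags the two strongly expanding bush-cricket
species and then stops, so trait models are reported both for all
species and excluding the two.

## Traits and collinearity

The trait table holds 11 predictors: five continuous (habitat breadth,
body size, wing load, phenology, average latitude) and six categorical
(vegetation structure, oviposition site, diet, generations per year,
overwintering stage, wing morph). `model_transforms()` log-transforms
the two right-skewed traits (habitat breadth, body size). Before
modelling, `collinearity_screen()` runs all 55 pairwise
association tests, matching the test to the trait types (Pearson,
Kendall, or Kruskal–Wallis) with Holm correction; on the packaged table
no pair is significant, so all 11 traits enter the candidate set.

## All-subsets multimodel averaging

`fit_all_subsets()` fits a Gaussian linear model for every non-empty
subset of the 11 traits (2,047 models; factors enter as whole terms) and
ranks them by AIC (or small-sample AICc). `select_top()` keeps models
within 4 AIC units of the best; Akaike weights are renormalized within
this top set. `average_coefficients()` then reports, per term, the
weight-averaged coefficient, its unconditional standard error
\(\sum_i w_i \sqrt{SE_i^2 + (b_i - \bar b)^2}\), confidence intervals at
z = 1.96/2.58/3.29 with significance stars, and the summed Akaike weight
of models containing the term (a relative importance measure):

```{r}
y <- setNames(unc, fix$species)
top <- select_top(fit_all_subsets(fix, y))
avg <- average_coefficients(top)
head(avg[c("term", "b_all", "se_all", "inclusion_pct", "stars")])
```

`weighted_adjusted_D2()` summarizes explanatory power with the
adjusted deviance explained, \(1 - \frac{s-1}{s-t}(1 - D^2)\) for *s*
species and *t* traits, averaged over the top set, and
`weighted_fitted()` ranks species by their averaged residuals.
`residual_normality()` checks the Gaussian assumption per top model.

At 23 species and 11 candidate traits, plain AIC retains very large
models whose many estimated coefficients fit noise; the small-sample
`ic = "AICc"` option applies the standard correction and is the
recommended setting for data of this size (see the simulation section).

## Phylogenetic robustness

Related species are not independent data points. Lacking a dated
phylogeny, `build_working_phylogeny()` turns a taxonomy
(suborder/family/subfamily/genus) into an ultrametric working tree with
unit branch segments, and `phylo_covariance()` derives the implied
species covariance (verified against an independent implementation).
`morans_I()` tests each top model's residuals for phylogenetic
autocorrelation; if any model is significant or near-significant
(p below the trigger, default 0.1), `phylo_pipeline()` reruns the whole
all-subsets analysis with phylogenetic generalized least squares
(`pgls_fit()`), estimating Pagel's λ by profile maximum likelihood on
[1e-6, 1]. As λ approaches the lower bound, PGLS coincides with
ordinary least squares, so negligible signal reproduces the ordinary
results.

```{r}
tree <- build_working_phylogeny(orthoptera_taxonomy())
ph <- phylo_pipeline(top, tree, fix)
ph$rerun_triggered
```

## Synthetic data and parameter recovery

The generator mirrors the packaged study's conditions: 23 species, 844
hectads, a doubling of recording effort, and the observed mix of
grid-reference precisions (55% 100 m, 27% 1 km, 3% tetrad, 15%
hectad). `simulate_traits()` draws a trait table matched to the fixture
marginals, `simulate_range_change()` plants a known trait signal
\(y = X\beta + \varepsilon\), and `simulate_records()` emits records
whose period-2 occupancy is shifted by *y* on the logit scale:

```{r}
cfg <- simulation_config(seed = 42)
tr <- simulate_traits(23, seed = 42)
yy <- simulate_range_change(tr, c(habitat_breadth = 3,
                                  average_latitude = -2), sigma = 0.5,
                             seed = 43)
rec <- simulate_records(tr, yy, cfg)
nrow(rec)
```

Recomputing the corrected index from such records correlates with the
true *y* above r = 0.8, and with a strong planted signal the averaged
coefficients recover the true β with near-nominal confidence-interval
coverage under AICc. Under plain AIC at this sample size, coverage and
variable-importance rankings degrade noticeably — the basis for the
AICc recommendation above.

## The full pipeline and the command line

`run_pipeline(pipeline_config())` executes every stage on the packaged
data (or on supplied records/traits/taxonomy), writes delimited outputs
and a run log when `out_dir` is set, and is deterministic given the
seed. An installed `exec/rangetraits` script exposes the same
functionality as subcommands (`simulate`, `range-change`, `outliers`,
`screen`, `fit`, `phylo`, `all`).

```{r}
res <- suppressMessages(run_pipeline(pipeline_config()))
res$grubbs$label
round(res$all_species$adjusted_D2, 2)
```
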