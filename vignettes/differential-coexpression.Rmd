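---
title: "Differential co-expression analysis with switchcor: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression analysis with switchcor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchcor)
```

# The problem

Most co-expression studies ask which genes are correlated. This package asks
a sharper question: for which gene pairs does the *correlation itself change*
between two biological conditions — here labelled `normal` and `tumor`? A
pair that is positively correlated in normal tissue and negatively correlated
in tumors (or vice versa) has, by definition, undergone a rewiring of its
regulatory relationship; we call such pairs *switching pairs*. Because a
pair can switch without either gene changing its mean, and can shift its mean
without switching, differential correlation and differential expression are
complementary signals; the pipeline intersects them.

The workflow is:

1. build a weighted gene co-expression network and detect modules;
2. find the modules most associated with the condition;
3. within those modules, test every gene pair for a difference in
   correlation between conditions (Fisher z-difference, local FDR);
4. extract sign-flipping pairs whose genes are also differentially expressed;
5. summarize cluster-level rewiring with eigen-molecule module networks;
6. follow up with gene-set enrichment and an expression-cutoff survival scan.

# Models and statistics

## Weighted network, soft threshold, and modules

With Pearson correlations $r_{ij}$ between genes, the unsigned weighted
adjacency is $a_{ij} = |r_{ij}|^\beta$. The soft-threshold power $\beta$ is
chosen by the scale-free criterion: connectivities $k_i = \sum_{u \ne i}
a_{iu}$ are binned, and the fit index is the $R^2$ of the linear regression
of log-density on log-connectivity, set to 0 whenever the slope is positive
(the criterion demands that frequency *decrease* with connectivity). The
smallest candidate power reaching `r2_floor` (default 0.8) is selected;
when none does, the best-fitting power is used with a warning.

Two binning details are deliberate. We use *equal-occupancy* (quantile) bins
rather than equal-width bins, and we regress the per-bin *density*
(count divided by total times bin width) on the per-bin mean connectivity.
With equal-occupancy bins the counts are constant by construction, so raw
frequency would be degenerate; the density form measures the same power-law
slope while keeping every bin populated. Zero-width bins produced by ties
are merged, and a power with fewer than three usable bins is recorded as
fit 0.

The topological overlap matrix is
$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$
with unit diagonal; the rare zero-denominator case (fully isolated pair) is
defined as 0. Modules come from average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$ with a *static* cut. The cut height defaults to 0.995 of
the maximal merge height; clusters smaller than `min_module_size` (default
30, the size of the smallest module we aim to resolve) are relabelled
`grey`, and surviving modules are named from a fixed, size-ordered color
palette (largest = `turquoise`) so runs are reproducible. A static cut was
chosen over dynamic tree cutting because it is fully deterministic and
single-parameter; the trade-off is that module *counts* are not comparable
with dynamic-cut analyses of the same data, and deeply nested modules are
not split.

Module eigengenes are first principal components of the row-standardized
module submatrix, scaled to unit variance and sign-aligned with the module
mean profile. Module–trait association codes the trait 0 = normal,
1 = tumor (so a tumor-up module gets a positive correlation), with p-values
from the $t$ distribution on $n-2$ degrees of freedom; per-gene Gene
Significance and Module Membership are absolute correlations with the trait
and with the own-module eigengene.

## Fisher z-difference and local FDR

For a pair with per-condition correlations $r_A, r_B$ and sample sizes
$n_A, n_B$, the variance-stabilized difference statistic is
$$Z = \frac{z_A - z_B}{\sqrt{\frac{1}{n_A-3} + \frac{1}{n_B-3}}},
\qquad z = \tfrac12 \log\frac{1+r}{1-r},$$
compared two-sided against the standard normal. Multiplicity is handled
with a *local* false discovery rate under an empirical-Bayes two-component
model with a theoretical standard-normal null:
$\mathrm{lfdr}(z) = \hat\eta_0\,\varphi(z)/\hat f(z)$, where
$\hat\eta_0 = \min(1,\, 2\,\overline{[p > 0.5]})$ and $\hat f$ is a Gaussian
kernel density estimate (Silverman bandwidth) of the observed statistics,
clipped to $[0,1]$. This estimator was chosen over a Grenander-type density
for its simplicity; its calibration is validated by simulation in the test
suite (null-fraction estimate within $[0.9, 1]$ on pure nulls, over 80%
power at $|Z| \sim N(6,1)$ signals at the 10% mixture rate). Below 200
statistics the density estimate is unstable and the implementation falls
back to Benjamini–Hochberg adjusted p-values with a notice.

A *switching pair* must satisfy: opposite-signed per-condition correlations;
`lfdr < 0.05`; optionally $|r| \ge$ `min_abs_r` in both conditions (default
0 — no magnitude filter is imposed beyond significance, though the filter is
exposed); and differential expression of *both* genes at BH-adjusted
$p < 0.05$ (the conservative reading of "switching with differential
expression at the same time"; `de_rule = "either"` relaxes it). Output is
ordered by ascending lfdr, then descending $|Z|$, then pair name — fully
deterministic.

## Eigen-molecule module networks

Within the analyzed genes, each condition is clustered by average linkage on
the *signed* correlation distance $d = 1 - r$ (range $[0,2]$), cut at
$1 - 0.6$ so molecules correlated above 0.6 share a cluster; the signed
distance (not $1-|r|$) keeps anti-correlated molecules apart, matching the
"one minus correlation" distance the method is built on. Each cluster is
summarized by its eigen-molecule (first PC, computed within each condition's
samples under a common sign convention), and all eigen-molecule pairs get
the same z-difference treatment, yielding a module-level rewiring network.

## Downstream statistics

Differential expression uses the pooled-variance Student's $t$ (Welch
behind a flag), BH-adjusted across genes; zero-variance genes are flagged
with $p = 1$ rather than erroring. Gene-set enrichment is the upper-tail
hypergeometric test within a user-stated universe, BH-adjusted across sets.
Survival follow-up dichotomizes a gene's expression at 90 evenly spaced
quantile levels from 5% to 95% inclusive (interpreted as quantile levels
with linear-interpolation quantiles; ties at a cutoff go to the high, $\ge$,
group), runs a log-rank test at each split, and reports the minimum-p
cutoff with Kaplan–Meier curves and a descriptive univariate Cox hazard
ratio (Breslow ties) at that cutoff. The minimum-p scan is deliberately
reported *uncorrected* for the 90-fold selection, as is conventional for
this screening procedure, but the inflation is real: on null genes the
fraction with $\min p < 0.05$ exceeds 0.05, and the test suite asserts that
inflation rather than pretending calibration.

# The synthetic-data generator

`simulate_expression()` plants known structure so that recovery can be
measured exactly:

- **Modules**: $x = \lambda f_m + \sqrt{1-\lambda^2}\,\varepsilon$ with a
  shared per-module factor; expected within-module correlation $\lambda^2$.
  The default loading in validation runs is $\lambda = 0.8$.
- **Switching pairs**: both genes load $\sqrt{r_s}$ on a shared factor in
  the normal condition; one gene's loading flips sign in tumors, so the
  expected correlations are $+r_s$ and $-r_s$ (default $r_s = 0.6$,
  matching the magnitude range of reported switching pairs).
- **Differential expression**: a mean shift $\delta$ (in residual-SD units)
  added to tumor samples, either on dedicated background genes or on a
  designated gene set (e.g. a whole module, to make it trait-linked).
- **Survival**: tumor samples draw exponential times with hazard
  $h_0 \exp(\sum \beta_g x_g)$, administratively censored at a horizon;
  defaults ($h_0 = 5\times10^{-4}$ per day, horizon 2000 days) give roughly
  60% events in a null cohort, a realistic follow-up profile.
- **Design imbalance**: default sample sizes are 58 normal and 468 tumor,
  mirroring the unbalanced tumor/normal cohorts typical of TCGA-scale
  studies, so the z-difference denominators are exercised asymmetrically.
- **RNG**: one root seed with per-stage child streams, so adding a stage
  (say, survival) never perturbs the expression draws.

`simulate_scale_free()` serves one purpose: producing data whose weighted
network is scale-free *at a designated power and not below it*. Gene
loadings on a single factor follow the deterministic quantile grid of the
density $p(b) \propto b^{\beta_0 - 2}$, and the sample design is an exact
orthonormal (discrete-cosine) basis, so sample correlations equal
$b_i b_j$ exactly. Connectivity at power $\beta$ is then proportional to
$b_i^\beta$, and the binned log-log slope is $(\beta_0 - 1 - \beta)/\beta$:
positive below $\beta_0 - 1$ (forcing the signed fit index to 0), flat at
$\beta_0 - 1$, and an exact power law from $\beta_0$ on. The concentration
of genes at high loadings mimics the dense moderate-correlation background
that makes soft-threshold selection non-trivial in real data. This is a
topology-validation construct, not a realistic expression simulator: use it
to test power selection, nothing else.

What the generator does **not** emulate: count-based noise
(negative-binomial mean–variance), batch effects, outlying samples,
non-linear dependence, and correlated censoring. Passing recovery tests on
these simulations therefore demonstrates correctness of the statistical
machinery under its own assumptions, not robustness to the full messiness
of RNA-seq data.

# Numerical choices and degenerate inputs

- Missing expression values are a **hard error at load**; imputation would
  silently distort correlations. An optional, logged `log2(x+1)` transform
  is available but off by default, since abundance units vary by upstream
  quantification.
- Genes with zero variance (pooled, or within either condition when a
  phenotype is supplied) are removed by an explicit filter step; reaching
  the correlation engine with a constant gene is an error naming the gene.
- Correlations numerically at $\pm 1$ (duplicated genes) are clamped to
  $\pm(1 - 10^{-12})$ inside the pair engine so Fisher transforms stay
  finite; the standalone `fisher_z()` refuses $|r| \ge 1$ outright.
- Tie-breaking is deterministic everywhere: module labels by decreasing
  size then cluster id; trait-module selection by $|r|$, then p, then
  label; switching output by lfdr, $|Z|$, pair name; survival-scan ties by
  the lower quantile.
- BH adjustment is *not* idempotent (re-adjusting adjusted values inflates
  them again by construction); the suite asserts reorder-stability and rank
  monotonicity instead.
- A cluster or module with one gene uses that gene's standardized profile
  as its eigen-profile, with a log message.

# Validation problem sizes

The test suite validates each estimator against independent brute-force
oracles on small random instances (up to 20 genes / 30 subjects, tolerance
$10^{-10}$), and the method-level properties on: 20,000 null pairs at the
58/468 design (type-I error within $[0.044, 0.056]$ at $\alpha = 0.05$);
50 planted switching pairs among >20,000 pairs at $n = 100/100$ (recall
$\ge 0.9$, empirical FDR $\le 0.1$); 8 planted modules among 2,000 genes at
200 samples and power 6 (adjusted Rand index $\ge 0.8$, shifted module
ranked first for the trait); a planted log-hazard of 1.1 at $n = 300$
(minimum-p below $10^{-3}$ in $\ge 90\%$ of 50 replicates) plus the
documented null inflation over 500 genes; and the scale-free construction
at generating power 6 ($R^2 \ge 0.95$, selector agreement). These sizes
keep the full validation run within a few minutes on a single core while
leaving comfortable statistical margins.

# A worked example

```{r example, eval = FALSE}
library(switchcor)

cfg <- pipeline_config(
  simulation = sim_config(
    n_genes = 260, n_samples_a = 60, n_samples_b = 60,
    module_sizes = c(40, 35), module_loading = 0.9,
    n_switch_pairs = 6, switch_r = 0.65,
    n_de_genes = 30, de_shift = 1.5,
    survival_genes = data.frame(gene = 1, beta = 0.8),
    seed = 5),
  power = 6, min_module_size = 25, diffcorr_scope = "all",
  alpha_de = 1, seed = 5)

manifest <- run_pipeline(cfg, outdir = tempfile("run"))
manifest$selected_modules
```

Every intermediate lands in the run directory as a TSV (plus GraphML
networks and a JSON manifest with per-stage counts, timings, and captured
warnings), so a run is fully auditable from its outputs.

# Known limitations

- The static tree cut makes module counts depend on a single height; very
  close module factors can merge that a dynamic cut would separate.
- The theoretical-null lfdr assumes the z-difference statistics are
  unit-variance under the null; strong violations (tiny samples, heavy
  dependence among pairs sharing a gene) shift $\hat\eta_0$.
- Pair tests within a module share genes and are therefore dependent; lfdr
  controls the local rate marginally, not family-wise error.
- The survival scan's minimum p is anti-conservative by construction and
  should be treated as a screening statistic.
- All-pairs differential correlation grows quadratically; the pipeline
  restricts to selected modules by default and exposes `diffcorr_scope =
  "all"` as an explicit opt-in.
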