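# switchcor

Differential co-expression analysis for two-condition (normal vs tumor)
gene-expression studies: weighted co-expression modules, Fisher z-difference
testing of per-condition correlations with local-FDR control, detection of
**switching gene pairs** — pairs whose correlation flips sign between
conditions while both genes are differentially expressed — eigen-molecule
module networks, hypergeometric gene-set enrichment, and a minimum-p
expression-cutoff Kaplan–Meier/log-rank survival scan.

## Who this is for

Computational biologists who have a gene-by-sample expression matrix with a
two-level phenotype (plus optional survival follow-up) and want to go beyond
"which genes are co-expressed" to "which regulatory relationships are
*rewired* between conditions", with every statistical step testable against
planted ground truth.

## The statistics at the core

For a gene pair with per-condition Pearson correlations $r_A, r_B$ and
sample sizes $n_A, n_B$:

$$Z = \frac{z_A - z_B}{\sqrt{\dfrac{1}{n_A-3} + \dfrac{1}{n_B-3}}},
\qquad z = \tfrac{1}{2}\,\log\frac{1+r}{1-r}$$

compared two-sided against the standard normal, with multiplicity handled by
a local false discovery rate under an empirical-Bayes two-component model
(theoretical N(0,1) null, kernel-density marginal, null fraction
$\hat\eta_0 = \min(1, 2\,\overline{[p>0.5]})$). A switching pair has
$\mathrm{sign}(r_A)\,\mathrm{sign}(r_B) = -1$, $\mathrm{lfdr} < 0.05$, and
both genes differentially expressed (pooled-variance Student's *t*,
Benjamini–Hochberg adjusted *p* < 0.05).

Upstream, modules come from the standard weighted co-expression
construction: unsigned adjacency $|r|^\beta$ with $\beta$ selected by the
scale-free topology criterion ($R^2 \ge 0.8$ of the binned log-log
connectivity fit, sign-aware), topological-overlap dissimilarity,
average-linkage clustering with a static cut, eigengenes (first principal
components), and module–trait correlation. Downstream, a per-gene survival
scan splits samples at 90 expression quantiles (5%–95%), takes the log-rank
minimum-p cutoff, and reports Kaplan–Meier curves and a univariate Cox
hazard ratio at that cutoff.

## A worked example

Simulate a study with planted structure, run the full pipeline, and compare
detections with the truth:

```r
library(switchcor)

cfg <- pipeline_config(
  simulation = sim_config(
    n_genes = 260, n_samples_a = 60, n_samples_b = 60,
    module_sizes = c(40, 35), module_loading = 0.9,
    n_switch_pairs = 6, switch_r = 0.65,
    n_de_genes = 30, de_shift = 1.5,
    survival_genes = data.frame(gene = 1, beta = 0.8),
    seed = 5),
  power = 6, min_module_size = 25,
  diffcorr_scope = "all", alpha_de = 1, seed = 5)

outdir <- tempfile("switchcor-run")
manifest <- run_pipeline(cfg, outdir)

sw <- read.table(file.path(outdir, "switching.tsv"), header = TRUE)
truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                             simplifyVector = TRUE)
evaluate_switching(sw, tibble::as_tibble(truth$switch_pairs))
```

```
# A tibble: 1 × 4
  n_detected n_true recall   fdr
       <int>  <int>  <dbl> <dbl>
1          7      6      1 0.143
```

All six planted sign-flip pairs are recovered (recall 1), along with one
borderline false positive among the 33,670 tested pairs — the price of
screening at lfdr < 0.05. `switching.tsv` lists each pair with its
per-condition correlations (`r_a`, `r_b`), the z-difference statistic, and
its lfdr; the top planted pair appears as `r_a = 0.67, r_b = -0.68,
lfdr = 7e-14`, i.e. a strong positive correlation in normal samples that
flips to a strong negative one in tumors. The run directory also contains the module assignment,
module–trait table, differential expression results, eigen-module network
(GraphML), per-gene survival scans, and a JSON manifest with per-stage
counts and timings.

Single steps work standalone and pipe naturally:

```r
sim <- simulate_expression(sim_config(n_genes = 205, n_samples_a = 100,
                                      n_samples_b = 100, n_switch_pairs = 50,
                                      switch_r = 0.6, seed = 11))
de <- differential_expression(sim$expression, sim$phenotype)

sw <- diffcorr_pairs(sim$expression, sim$phenotype) |>
  estimate_lfdr() |>
  detect_switching(de, alpha_de = 1)
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted objects
(soft-threshold reports, module assignments, module–trait results, survival
scans, pair tables).

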