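#' Per-gene scaling transforms
#'
#' Pretreatment transforms applied per gene across samples, as used in
#' metabolomics-style correlation pipelines. With per-gene mean `m`, standard
#' deviation `s`, minimum and maximum: auto `(x-m)/s`; range
#' `(x-m)/(max-min)`; pareto `(x-m)/sqrt(s)`; vast `((x-m)/s)*(m/s)`; level
#' `(x-m)/m`; power `sqrt(x) - mean(sqrt(x))` (requires non-negative values).
#'
#' @param x gene-by-sample matrix.
#' @param method one of `"auto"`, `"range"`, `"pareto"`, `"vast"`, `"level"`,
#'   `"power"`.
#' @return transformed matrix of the same shape.
#' @export
scale_expression <- function(x, method = c("auto", "range", "pareto", "vast",
                                           "level", "power")) {
  method <- match.arg(method)
  validate_expression(x)
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  fail <- function(cond, what) {
    if (any(cond)) {
      abort(sprintf("%s scaling undefined for gene(s) %s (%s)", method,
                    paste(head(rownames(x)[cond], 5L), collapse = ", "), what))
    }
  }
  out <- switch(method,
    auto = { fail(s == 0, "zero SD"); (x - m) / s },
    range = {
      rng <- apply(x, 1L, function(r) diff(range(r)))
      fail(rng == 0, "max equals min"); (x - m) / rng
    },
    pareto = { fail(s == 0, "zero SD"); (x - m) / sqrt(s) },
    vast = { fail(s == 0, "zero SD"); ((x - m) / s) * (m / s) },
    level = { fail(m == 0, "zero mean"); (x - m) / m },
    power = {
      fail(apply(x, 1L, min) < 0, "negative values")
      sq <- sqrt(x); sq - rowMeans(sq)
    }
  )
  dimnames(out) <- dimnames(x)
  out
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing map for
#' Pearson correlations; an odd function of `r`.
#'
#' @param r numeric vector of correlations with `|r| < 1`.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("transform undefined: |r| must be < 1")
  }
  atanh(r)
}

#' Fisher z-difference test for two correlations
#'
#' Tests whether a gene pair's correlation differs between two conditions:
#' `Z = (z_A - z_B) / sqrt(1/(n_A - 3) + 1/(n_B - 3))`, compared with a
#' standard normal (two-sided).
#'
#' @param r_a,r_b per-condition correlations (`|r| < 1`).
#' @param n_a,n_b per-condition sample sizes (both > 3).
#' @return tibble with columns `z_diff` and `p_diff`. Vectorized over pairs.
#' @export
z_difference <- function(r_a, r_b, n_a, n_b) {
  if (any(n_a <= 3L) || any(n_b <= 3L)) {
    abort("sample sizes must exceed 3 (n - 3 denominators)")
  }
  z_a <- fisher_z(r_a)
  z_b <- fisher_z(r_b)
  se <- sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  z <- (z_a - z_b) / se
  tibble::tibble(z_diff = z, p_diff = 2 * pnorm(-abs(z)))
}

# Correlations numerically at +/-1 (duplicated genes) are clamped just inside
# the open interval so the z machinery stays finite.
clamp_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' Per-condition correlation tests for all gene pairs
#'
#' Computes, for every unordered pair within `genes`, the per-condition
#' Pearson correlations, their Fisher z values, per-condition correlation-test
#' p-values (t-distribution, `n - 2` df), and the z-difference statistic with
#' its two-sided normal p-value.
#'
#' @param x gene-by-sample matrix.
#' @param phenotype phenotype tibble covering the columns of `x`.
#' @param genes gene subset; default all rows of `x`.
#' @return tibble of class `diffcorr_tbl`, one row per pair, sorted by
#'   (`gene_a`, `gene_b`), with attributes `n_a`, `n_b`.
#' @export
diffcorr_pairs <- function(x, phenotype, genes = NULL) {
  genes <- genes %||% rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) {
    abort(paste0("gene(s) not in expression matrix: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  if (length(genes) < 2L) abort("need at least 2 genes")
  cols <- condition_columns(x, phenotype)
  n_a <- length(cols$normal); n_b <- length(cols$tumor)
  if (n_a < 4L || n_b < 4L) abort("each condition needs >= 4 samples")
  xa <- x[genes, cols$normal, drop = FALSE]
  xb <- x[genes, cols$tumor, drop = FALSE]
  ca <- cor(t(xa)); cb <- cor(t(xb))
  ut <- which(upper.tri(ca), arr.ind = TRUE)
  ga <- genes[ut[, 1L]]; gb <- genes[ut[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  r_a <- clamp_r(ca[ut]); r_b <- clamp_r(cb[ut])
  p_cor <- function(r, n) {
    t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  zd <- z_difference(r_a, r_b, n_a, n_b)
  out <- tibble::tibble(
    gene_a = ga, gene_b = gb,
    r_a = r_a, r_b = r_b,
    z_a = fisher_z(r_a), z_b = fisher_z(r_b),
    n_a = n_a, n_b = n_b,
    p_a = p_cor(r_a, n_a), p_b = p_cor(r_b, n_b),
    z_diff = zd$z_diff, p_diff = zd$p_diff
  )
  out <- dplyr::arrange(out, .data$gene_a, .data$gene_b)
  structure(out, n_a = n_a, n_b = n_b,
            class = c("diffcorr_tbl", class(out)))
}

#' Local false discovery rate for z-difference statistics
#'
#' Empirical-Bayes two-component model with a theoretical standard-normal
#' null: `lfdr(z) = eta0 * phi(z) / f(z)`, where `eta0` is estimated as
#' `min(1, 2 * mean(p > 0.5))` and `f` is a Gaussian kernel density estimate
#' of the observed statistics (Silverman bandwidth). Outputs are clipped to
#' `[0, 1]`. With fewer than `min_n` statistics the density estimate is
#' unstable, and Benjamini-Hochberg adjusted two-sided p-values are returned
#' instead, with a notice.
#'
#' @param z numeric vector of z-difference statistics.
#' @param min_n minimal number of statistics for the density route,
#'   default 200.
#' @return numeric vector of lfdr values in `[0, 1]`, with attributes
#'   `eta0` and `method` (`"lfdr"` or `"BH"`).
#' @export
local_fdr <- function(z, min_n = 200L) {
  if (!length(z)) abort("no statistics given")
  if (any(!is.finite(z))) abort("non-finite z statistics")
  if (length(unique(z)) == 1L) abort("degenerate input: all statistics identical")
  p <- 2 * pnorm(-abs(z))
  if (length(z) < min_n) {
    inform(sprintf(
      "only %d statistics (< %d): falling back to Benjamini-Hochberg adjusted p-values",
      length(z), min_n))
    return(structure(p.adjust(p, method = "BH"), eta0 = NA_real_, method = "BH"))
  }
  eta0 <- min(1, 2 * mean(p > 0.5))
  bw <- bw.nrd0(z)
  d <- density(z, bw = bw, n = 2048L, from = min(z) - 3 * bw, to = max(z) + 3 * bw)
  f_hat <- approx(d$x, d$y, xout = z)$y
  lfdr <- eta0 * dnorm(z) / pmax(f_hat, .Machine$double.xmin)
  lfdr <- pmin(pmax(lfdr, 0), 1)
  structure(lfdr, eta0 = eta0, method = "lfdr")
}

#' Attach lfdr values to a pair table
#'
#' @param records a `diffcorr_tbl` from [diffcorr_pairs()].
#' @param min_n passed to [local_fdr()].
#' @return the table with an `lfdr` column and an `eta0` attribute.
#' @export
estimate_lfdr <- function(records, min_n = 200L) {
  lf <- local_fdr(records$z_diff, min_n = min_n)
  records$lfdr <- as.numeric(lf)
  attr(records, "eta0") <- attr(lf, "eta0")
  attr(records, "lfdr_method") <- attr(lf, "method")
  records
}

#' Detect switching gene pairs
#'
#' A switching pair has oppositely signed per-condition correlations
#' (positive in one condition, negative in the other), a significant
#' correlation difference (`lfdr < alpha_lfdr`), optional magnitude filters
#' on both correlations, and differential expression of its genes (both genes
#' by default; `de_rule = "either"` relaxes to one).
#'
#' @param records a `diffcorr_tbl` carrying an `lfdr` column
#'   (see [estimate_lfdr()]).
#' @param de_table differential-expression tibble from
#'   [differential_expression()] (needs columns `gene`, `adjusted_p`).
#' @param alpha_lfdr lfdr significance cutoff, default 0.05.
#' @param alpha_de adjusted-p cutoff for differential expression, default 0.05.
#' @param min_abs_r minimal `|r|` required in both conditions, default 0.
#' @param de_rule `"both"` (default) or `"either"` gene differentially
#'   expressed; set `alpha_de = 1` to disable the DE requirement.
#' @return tibble of switching pairs with a `switching` column (all `TRUE`),
#'   sorted by ascending lfdr, then descending `|z_diff|`, then pair name.
#' @export
detect_switching <- function(records, de_table, alpha_lfdr = 0.05,
                             alpha_de = 0.05, min_abs_r = 0,
                             de_rule = c("both", "either")) {
  de_rule <- match.arg(de_rule)
  if (!"lfdr" %in% colnames(records)) abort("records carry no lfdr column; run estimate_lfdr() first")
  stopifnot(all(c("gene", "adjusted_p") %in% colnames(de_table)))
  genes <- unique(c(records$gene_a, records$gene_b))
  missing <- setdiff(genes, de_table$gene)
  if (length(missing)) {
    abort(paste0("gene(s) missing from the DE table: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  de_p <- setNames(de_table$adjusted_p, de_table$gene)
  de_a <- de_p[records$gene_a] < alpha_de
  de_b <- de_p[records$gene_b] < alpha_de
  de_ok <- if (de_rule == "both") de_a & de_b else de_a | de_b
  keep <- sign(records$r_a) * sign(records$r_b) < 0 &
    records$lfdr < alpha_lfdr &
    abs(records$r_a) >= min_abs_r & abs(records$r_b) >= min_abs_r &
    de_ok
  out <- records[keep, , drop = FALSE]
  out$switching <- TRUE
  dplyr::arrange(tibble::as_tibble(out), .data$lfdr, dplyr::desc(abs(.data$z_diff)),
                 .data$gene_a, .data$gene_b)
}

#' Cluster molecules per condition by correlation distance
#'
#' Per condition, average-linkage hierarchical clustering with the signed
#' one-minus-correlation distance `d = 1 - r` (range `[0, 2]`), cut at height
#' `1 - r_cutoff` so that molecules correlated above `r_cutoff` fall into the
#' same cluster. Singleton clusters are allowed. Cluster ids are relabelled
#' by decreasing size for determinism.
#'
#' @param x gene-by-sample matrix.
#' @param phenotype phenotype tibble.
#' @param genes gene subset; default all rows.
#' @param r_cutoff correlation cutoff in (0, 1), default 0.6.
#' @return object of class `molecule_clusters`: list with `clusters` (tibble
#'   `gene`, `cluster_normal`, `cluster_tumor`) and `r_cutoff`.
#' @export
cluster_molecules <- function(x, phenotype, genes = NULL, r_cutoff = 0.6) {
  if (r_cutoff <= 0 || r_cutoff >= 1) abort("r_cutoff must be in (0, 1)")
  genes <- genes %||% rownames(x)
  cols <- condition_columns(x, phenotype)
  one <- function(sample_ids) {
    c_mat <- cor(t(x[genes, sample_ids, drop = FALSE]))
    d <- 1 - c_mat
    diag(d) <- 0
    tree <- hclust(as.dist(d), method = "average")
    cl <- cutree(tree, h = 1 - r_cutoff)
    sizes <- table(cl)
    rank <- setNames(seq_along(sizes), names(sizes)[order(-sizes, as.integer(names(sizes)))])
    unname(rank[as.character(cl)])
  }
  structure(list(
    clusters = tibble::tibble(gene = genes,
                              cluster_normal = one(cols$normal),
                              cluster_tumor = one(cols$tumor)),
    r_cutoff = r_cutoff
  ), class = "molecule_clusters")
}

# First-PC profile of a gene set within given sample columns, unit variance,
# sign-aligned to the mean standardized profile.
eigen_profile <- function(x, genes, sample_ids) {
  xm <- standardize_rows(x[genes, sample_ids, drop = FALSE])
  if (length(genes) == 1L) return(drop(xm))
  sv <- svd(xm, nu = 0, nv = 1)
  score <- drop(sv$v[, 1L])
  mean_profile <- colMeans(xm)
  if (sd(mean_profile) > 0 && cor(score, mean_profile) < 0) score <- -score
  score / sd(score)
}

#' Differential correlation between eigen-molecule modules
#'
#' For each condition's clustering, every cluster is summarized by its
#' eigen-molecule (first principal component of the cluster's genes, computed
#' separately within each condition's samples with a common sign convention),
#' and all eigen-molecule pairs get the Fisher z-difference treatment with
#' the per-condition sample sizes. Singleton clusters use the gene's
#' standardized profile.
#'
#' @param clusters a `molecule_clusters` object.
#' @param x gene-by-sample matrix.
#' @param phenotype phenotype tibble.
#' @return tibble with one row per eigen-module pair and clustering
#'   (`clustering` is the condition whose cluster memberships were used),
#'   columns `module_a`, `module_b`, `size_a`, `size_b`, `r_a`, `r_b`,
#'   `z_diff`, `p_diff`.
#' @export
eigen_module_diffcorr <- function(clusters, x, phenotype) {
  stopifnot(inherits(clusters, "molecule_clusters"))
  cols <- condition_columns(x, phenotype)
  n_a <- length(cols$normal); n_b <- length(cols$tumor)
  tab <- clusters$clusters
  one_clustering <- function(member_col, label) {
    ids <- sort(unique(tab[[member_col]]))
    if (length(ids) < 2L) {
      warn(sprintf("%s clustering has a single cluster; no eigen-module pairs", label))
      return(NULL)
    }
    ea <- sapply(ids, function(k) eigen_profile(x, tab$gene[tab[[member_col]] == k], cols$normal))
    eb <- sapply(ids, function(k) eigen_profile(x, tab$gene[tab[[member_col]] == k], cols$tumor))
    ca <- cor(ea); cb <- cor(eb)
    ut <- which(upper.tri(ca), arr.ind = TRUE)
    r_a <- clamp_r(ca[ut]); r_b <- clamp_r(cb[ut])
    zd <- z_difference(r_a, r_b, n_a, n_b)
    sizes <- table(tab[[member_col]])
    tibble::tibble(
      clustering = label,
      module_a = sprintf("%s_%02d", substr(label, 1L, 1L), ids[ut[, 1L]]),
      module_b = sprintf("%s_%02d", substr(label, 1L, 1L), ids[ut[, 2L]]),
      size_a = as.integer(sizes[as.character(ids[ut[, 1L]])]),
      size_b = as.integer(sizes[as.character(ids[ut[, 2L]])]),
      r_a = r_a, r_b = r_b, z_diff = zd$z_diff, p_diff = zd$p_diff
    )
  }
  out <- dplyr::bind_rows(one_clustering("cluster_normal", "normal"),
                          one_clustering("cluster_tumor", "tumor"))
  structure(out, n_a = n_a, n_b = n_b,
            class = c("eigen_module_diffcorr", class(out)))
}

#' Export an eigen-module network as an edge table
#'
#' @param em result of [eigen_module_diffcorr()].
#' @param clustering which clustering to export (`"normal"` or `"tumor"`).
#' @param condition correlation to use as the edge weight (`"tumor"` uses
#'   `r_b`, `"normal"` uses `r_a`).
#' @return edge tibble suitable for [write_network()].
#' @export
eigen_module_edges <- function(em, clustering = "tumor", condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  sub <- em[em$clustering == clustering, , drop = FALSE]
  r <- if (condition == "tumor") sub$r_b else sub$r_a
  network_edges(sub$module_a, sub$module_b, weight = abs(r),
                sign = ifelse(r >= 0, "+", "-"),
                annotation = sprintf("z_diff=%.4g", sub$z_diff))
}
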