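#' Pairwise Pearson correlation between genes
#'
#' @param x gene-by-sample numeric matrix with no zero-variance rows (use
#'   [filter_invariant_genes()] first).
#' @return symmetric gene-by-gene correlation matrix, diagonal exactly 1.
#' @export
pairwise_correlation <- function(x) {
  validate_expression(x)
  v <- apply(x, 1L, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance gene(s) reached pairwise_correlation: ",
                 paste(head(rownames(x)[v == 0], 5L), collapse = ", ")))
  }
  c_mat <- cor(t(x))
  c_mat <- (c_mat + t(c_mat)) / 2
  diag(c_mat) <- 1
  c_mat
}

#' Remove genes with zero variance
#'
#' Drops genes whose expression is constant in the pooled data or, when a
#' phenotype table is supplied, constant within either condition (such genes
#' break per-condition correlation tests).
#'
#' @param x gene-by-sample matrix.
#' @param phenotype optional phenotype tibble for per-condition checks.
#' @return list with `expression` (filtered matrix) and `removed` (character
#'   vector of dropped gene ids).
#' @export
filter_invariant_genes <- function(x, phenotype = NULL) {
  validate_expression(x)
  bad <- apply(x, 1L, var) == 0
  if (!is.null(phenotype)) {
    cols <- condition_columns(x, phenotype)
    for (cc in cols) {
      if (length(cc) >= 2L) bad <- bad | apply(x[, cc, drop = FALSE], 1L, var) == 0
    }
  }
  removed <- rownames(x)[bad]
  if (all(bad)) abort("all genes have zero variance; nothing left to analyze")
  if (length(removed)) {
    inform(sprintf("removed %d invariant gene(s): %s", length(removed),
                   paste(head(removed, 5L), collapse = ", ")))
  }
  list(expression = x[!bad, , drop = FALSE], removed = removed)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` off-diagonal; the diagonal is set to 0 so
#' that row sums are the network connectivities `k_i`.
#'
#' @param x gene-by-sample matrix (ignored when `cor_matrix` is given).
#' @param power soft-threshold exponent beta, at least 1.
#' @param cor_matrix optional precomputed correlation matrix.
#' @return symmetric adjacency matrix with entries in `[0, 1]` and zero
#'   diagonal.
#' @export
adjacency <- function(x, power, cor_matrix = NULL) {
  if (power < 1) abort("power must be >= 1")
  c_mat <- cor_matrix %||% pairwise_correlation(x)
  a <- abs(c_mat)^power
  diag(a) <- 0
  a
}

# Scale-free topology fit of a connectivity vector: equal-occupancy quantile
# bins of k, per-bin density = count / (n * width), linear fit of
# log10(density) on log10(mean k). The signed fit index is the regression R^2,
# forced to 0 when the slope is positive (the criterion requires connectivity
# and frequency to be negatively related).
scale_free_fit <- function(k, n_bins = 10L) {
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1L), type = 7))
  if (length(breaks) < 4L) abort("fewer than 3 usable connectivity bins")
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  widths <- diff(breaks)
  mean_k <- tapply(k, bin, mean)
  keep <- counts > 0 & widths > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3L) abort("fewer than 3 usable connectivity bins")
  dens <- counts[keep] / (length(k) * widths[keep])
  fit <- lm(log10(dens) ~ log10(mean_k[keep]))
  slope <- unname(coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  if (is.na(slope) || slope > 0) r2 <- 0
  list(r_squared = r2, slope = slope, n_bins_used = sum(keep))
}

#' Select the soft-threshold power by the scale-free criterion
#'
#' For each candidate power the unsigned adjacency is formed, connectivities
#' `k_i` are computed, and the scale-free fit index R-squared of the binned
#' log-log connectivity distribution is recorded (0 when the slope is
#' positive). The chosen power is the smallest candidate whose fit reaches
#' `r2_floor`; if none does, the candidate with the maximal fit is chosen
#' with a warning.
#'
#' @param x gene-by-sample matrix.
#' @param powers candidate powers (duplicates are dropped).
#' @param r2_floor minimal acceptable fit index, default 0.8.
#' @param n_bins connectivity bins for the fit, default 10.
#' @return object of class `soft_threshold`: a tibble with one row per power
#'   (`power`, `r_squared`, `slope`, `mean_connectivity`) and attributes
#'   `chosen_power` and `r2_floor`.
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, seq(12L, 20L, 2L)),
                                r2_floor = 0.8, n_bins = 10L) {
  powers <- sort(unique(as.integer(powers)))
  if (!length(powers)) abort("no candidate powers given")
  c_mat <- pairwise_correlation(x)
  rows <- purrr::map(powers, function(beta) {
    a <- adjacency(x, beta, cor_matrix = c_mat)
    k <- rowSums(a)
    fit <- tryCatch(scale_free_fit(k, n_bins = n_bins), error = function(e) {
      warn(sprintf("power %d: %s; fit index recorded as 0", beta, conditionMessage(e)))
      list(r_squared = 0, slope = NA_real_)
    })
    tibble::tibble(power = beta, r_squared = fit$r_squared, slope = fit$slope,
                   mean_connectivity = mean(k))
  })
  tab <- dplyr::bind_rows(rows)
  ok <- tab$power[tab$r_squared >= r2_floor]
  if (length(ok)) {
    chosen <- min(ok)
  } else {
    chosen <- tab$power[which.max(tab$r_squared)]
    warn(sprintf(
      "no candidate power reaches scale-free fit R^2 >= %.2f; using power %d (R^2 = %.3f)",
      r2_floor, chosen, max(tab$r_squared)
    ))
  }
  structure(tab, chosen_power = chosen, r2_floor = r2_floor,
            class = c("soft_threshold", class(tab)))
}

#' Chosen power of a soft-threshold report
#' @param report a `soft_threshold` object.
#' @return integer power.
#' @export
chosen_power <- function(report) attr(report, "chosen_power")

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1 by convention. A zero denominator (isolated pair) yields
#' `TOM_ij = 0`, reported once.
#'
#' @param a adjacency matrix from [adjacency()].
#' @return symmetric TOM with entries in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  k <- rowSums(a)
  l <- a %*% a  # diagonal of a is 0, so u = i and u = j terms vanish
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  zero <- denom <= 0
  if (any(zero)) {
    inform("isolated gene pair(s) with zero TOM denominator; TOM set to 0")
    tom[zero] <- 0
  }
  tom <- (tom + t(tom)) / 2
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `d = 1 - TOM` with a static cut:
#' the tree is cut at `cut_height` (default 0.995 of the maximal merge
#' height), clusters smaller than `min_module_size` are relabelled `"grey"`,
#' and surviving clusters are renamed by the size-ordered color palette
#' (largest = `"turquoise"`).
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size minimal module size, default 30.
#' @param cut_height static cut height in `(0, 1)`; `NULL` means 0.995 of the
#'   maximal merge height.
#' @return object of class `module_assignment`: list with `modules` (tibble
#'   `gene`, `module`), `tree` (hclust), `cut_height` and `sizes`.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = NULL) {
  if (min_module_size < 2L) abort("min_module_size must be >= 2")
  d <- 1 - tom
  diag(d) <- 0
  tree <- hclust(as.dist(d), method = "average")
  ch <- cut_height %||% (0.995 * max(tree$height))
  if (!is.null(cut_height) && (cut_height <= 0 || cut_height >= 1)) {
    abort("cut_height must be in (0, 1)")
  }
  cl <- cutree(tree, h = ch)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    palette <- module_colors(length(ord))
    for (i in seq_along(ord)) labels[cl == as.integer(ord[[i]])] <- palette[[i]]
  } else {
    warn("all genes unassigned (grey): no cluster reaches min_module_size")
  }
  modules <- tibble::tibble(gene = rownames(tom), module = labels)
  sizes_out <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  structure(list(modules = modules, tree = tree, cut_height = ch,
                 sizes = sizes_out),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_grey <- sum(x$modules$module == "grey")
  cat(sprintf("module assignment: %d genes, %d module(s), %d grey\n",
              nrow(x$modules), length(x$sizes), n_grey))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Module eigengenes (first principal components)
#'
#' Genes are standardized across samples; each module's eigengene is the
#' first principal-component score vector over samples, scaled to unit
#' variance and sign-aligned so that its correlation with the module's mean
#' standardized profile is non-negative.
#'
#' @param x gene-by-sample matrix.
#' @param assignment a `module_assignment` (or a tibble `gene`, `module`).
#' @param include_grey also compute an eigengene for the grey bucket
#'   (default `FALSE`).
#' @return object of class `eigengene_set`: list with `eigengenes` (samples x
#'   modules matrix, unit-variance columns) and `variance_explained`.
#' @export
module_eigengenes <- function(x, assignment, include_grey = FALSE) {
  modules <- if (inherits(assignment, "module_assignment")) assignment$modules else assignment
  stopifnot(all(c("gene", "module") %in% colnames(modules)))
  labs <- unique(modules$module)
  if (!include_grey) labs <- setdiff(labs, "grey")
  if (!length(labs)) abort("no modules to summarize")
  e <- matrix(NA_real_, nrow = ncol(x), ncol = length(labs),
              dimnames = list(colnames(x), labs))
  ve <- setNames(numeric(length(labs)), labs)
  for (m in labs) {
    rows <- modules$gene[modules$module == m]
    xm <- standardize_rows(x[rows, , drop = FALSE])
    if (length(rows) == 1L) {
      inform(sprintf("module %s has a single gene; eigengene is its standardized profile", m))
      e[, m] <- drop(xm)
      ve[[m]] <- 1
      next
    }
    sv <- svd(xm, nu = 0, nv = 1)
    score <- drop(sv$v[, 1L])
    mean_profile <- colMeans(xm)
    # sign convention; undefined when the mean profile is flat (e.g. two
    # perfectly anti-correlated genes), in which case the sign is arbitrary
    if (sd(mean_profile) > 0 && cor(score, mean_profile) < 0) score <- -score
    e[, m] <- score / sd(score)
    ve[[m]] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = e, variance_explained = ve),
            class = "eigengene_set")
}

#' Module-trait association, gene significance and module membership
#'
#' The trait is coded 0 = normal, 1 = tumor; `r_mt` is the Pearson
#' correlation of each eigengene with the trait, with the p-value from the
#' t-distribution with `n - 2` df (`t = r * sqrt((n - 2) / (1 - r^2))`).
#' When the expression matrix and assignment are supplied, per-gene Gene
#' Significance `GS = |cor(gene, trait)|` and Module Membership
#' `MM = |cor(gene, eigengene of its module)|` are computed too.
#'
#' @param eigengenes an `eigengene_set`.
#' @param phenotype phenotype tibble; condition must have both levels.
#' @param x optional gene-by-sample matrix (for GS/MM).
#' @param assignment optional module assignment (for GS/MM).
#' @return object of class `module_trait`: list with `modules` (tibble
#'   `module`, `r`, `p`, `n`) and `genes` (tibble `gene`, `module`, `gs`,
#'   `mm`; empty when `x` is not given).
#' @export
module_trait <- function(eigengenes, phenotype, x = NULL, assignment = NULL) {
  stopifnot(inherits(eigengenes, "eigengene_set"))
  e <- eigengenes$eigengenes
  ph <- phenotype[match(rownames(e), phenotype$sample_id), , drop = FALSE]
  trait <- as.numeric(ph$condition == "tumor")
  if (length(unique(trait)) < 2L) abort("trait is constant; both conditions are required")
  n <- length(trait)
  r <- unname(drop(cor(e, trait)))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  mods <- tibble::tibble(module = colnames(e), r = r, p = p, n = n)
  genes <- tibble::tibble(gene = character(), module = character(),
                          gs = numeric(), mm = numeric())
  if (!is.null(x) && !is.null(assignment)) {
    modules <- if (inherits(assignment, "module_assignment")) assignment$modules else assignment
    xs <- x[modules$gene, rownames(e), drop = FALSE]
    gs <- abs(drop(cor(t(xs), trait)))
    mm <- rep(NA_real_, nrow(modules))
    for (m in intersect(unique(modules$module), colnames(e))) {
      rows <- which(modules$module == m)
      mm[rows] <- abs(drop(cor(t(xs[rows, , drop = FALSE]), e[, m])))
    }
    genes <- tibble::tibble(gene = modules$gene, module = modules$module,
                            gs = gs, mm = mm)
  }
  structure(list(modules = mods, genes = genes), class = "module_trait")
}
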