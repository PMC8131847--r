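#' Simulation configuration
#'
#' Describes a two-condition expression study with planted structure:
#' block-correlated modules (single shared factor per module), switching gene
#' pairs whose correlation flips sign between conditions, mean-shift
#' differential expression in the tumor condition, and survival times for
#' tumor samples whose hazard depends on designated genes.
#'
#' Default sample sizes (58 normal, 468 tumor) mirror the unbalanced
#' tumor/normal design typical of TCGA cohorts.
#'
#' @param n_genes total number of genes.
#' @param n_samples_a,n_samples_b samples in condition A (normal) and B (tumor).
#' @param module_sizes integer vector of planted module sizes (may be empty).
#' @param module_loading shared-factor loading lambda in (0,1); expected
#'   within-module correlation is `lambda^2`.
#' @param n_switch_pairs number of planted switching pairs.
#' @param switch_r target |correlation| of switching pairs, in (0,1):
#'   approximately `+switch_r` in normal and `-switch_r` in tumor.
#' @param n_de_genes number of differentially expressed genes.
#' @param de_shift mean shift added in condition B, in units of residual SD.
#' @param de_gene_indices optional explicit gene indices to receive the DE
#'   shift (e.g. the genes of a planted module); default: the first
#'   `n_de_genes` genes of the unstructured block.
#' @param survival_genes optional data frame with columns `gene` (index) and
#'   `beta` (log-hazard coefficient per expression unit).
#' @param baseline_hazard baseline exponential hazard (events per day).
#' @param censor_horizon administrative censoring time (days).
#' @param seed root RNG seed; each generation stage uses its own child stream
#'   so adding a stage never perturbs earlier draws.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       n_samples_a = 58L,
                       n_samples_b = 468L,
                       module_sizes = integer(),
                       module_loading = 0.8,
                       n_switch_pairs = 0L,
                       switch_r = 0.6,
                       n_de_genes = 0L,
                       de_shift = 1,
                       de_gene_indices = NULL,
                       survival_genes = NULL,
                       baseline_hazard = 5e-4,
                       censor_horizon = 2000,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples_a = as.integer(n_samples_a),
    n_samples_b = as.integer(n_samples_b),
    module_sizes = as.integer(module_sizes), module_loading = module_loading,
    n_switch_pairs = as.integer(n_switch_pairs), switch_r = switch_r,
    n_de_genes = as.integer(n_de_genes), de_shift = de_shift,
    de_gene_indices = if (!is.null(de_gene_indices)) as.integer(de_gene_indices),
    survival_genes = if (!is.null(survival_genes)) tibble::as_tibble(survival_genes),
    baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_genes < 1L) abort("n_genes must be positive")
    if (n_samples_a < 1L || n_samples_b < 1L) abort("sample sizes must be positive")
    if (length(module_sizes) && any(module_sizes < 1L)) abort("module sizes must be positive")
    if (module_loading <= 0 || module_loading >= 1) abort("module_loading must be in (0,1)")
    if (switch_r <= 0 || switch_r >= 1) abort("switch_r must be in (0,1)")
    if (n_switch_pairs < 0L || n_de_genes < 0L) abort("counts must be non-negative")
    if (sum(module_sizes) + 2L * n_switch_pairs > n_genes) {
      abort("sum(module_sizes) + 2*n_switch_pairs exceeds n_genes")
    }
    if (baseline_hazard <= 0) abort("baseline_hazard must be positive")
    if (censor_horizon <= 0) abort("censor_horizon must be positive")
  })
  n_structured <- sum(cfg$module_sizes) + 2L * cfg$n_switch_pairs
  if (is.null(cfg$de_gene_indices)) {
    if (cfg$n_de_genes > cfg$n_genes - n_structured) {
      abort("not enough unstructured genes for n_de_genes; give de_gene_indices explicitly")
    }
    cfg$de_gene_indices <- if (cfg$n_de_genes > 0L) n_structured + seq_len(cfg$n_de_genes) else integer()
  } else {
    if (any(cfg$de_gene_indices < 1L | cfg$de_gene_indices > cfg$n_genes)) {
      abort("de_gene_indices out of range")
    }
    cfg$n_de_genes <- length(cfg$de_gene_indices)
  }
  if (!is.null(cfg$survival_genes)) {
    stopifnot(all(c("gene", "beta") %in% colnames(cfg$survival_genes)))
    if (any(cfg$survival_genes$gene < 1 | cfg$survival_genes$gene > cfg$n_genes)) {
      abort("survival gene index out of range")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-condition expression study with planted structure
#'
#' Module genes follow `x = lambda * f_m + sqrt(1 - lambda^2) * eps` with a
#' per-module shared factor `f_m` (same construction in both conditions), so
#' the expected within-module correlation is `lambda^2`. Each switching pair
#' shares one factor with loading `+sqrt(switch_r)` for both genes in the
#' normal condition and loadings of opposite sign in the tumor condition,
#' giving expected correlations `+switch_r` (normal) and `-switch_r` (tumor).
#' DE genes get a mean shift in the tumor condition; everything else is
#' independent standard-normal noise. Tumor survival times are exponential
#' with hazard `baseline_hazard * exp(sum beta_g x_g)`, administratively
#' censored at `censor_horizon`.
#'
#' @param config a [sim_config()].
#' @return list of class `simulation` with elements `expression` (matrix),
#'   `phenotype` (tibble) and `truth` (planted structure: `module_of_gene`,
#'   `switch_pairs`, `de_genes`, `survival_genes`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n_a <- config$n_samples_a
  n_b <- config$n_samples_b
  n <- n_a + n_b
  genes <- sprintf("G%05d", seq_len(g))
  samples <- c(sprintf("N%04d", seq_len(n_a)), sprintf("T%04d", seq_len(n_b)))
  is_b <- c(rep(FALSE, n_a), rep(TRUE, n_b))

  set.seed(child_seed(config$seed, "noise"))
  x <- matrix(rnorm(g * n), nrow = g, ncol = n, dimnames = list(genes, samples))

  module_of_gene <- rep(NA_character_, g)
  pos <- 0L
  if (length(config$module_sizes)) {
    set.seed(child_seed(config$seed, "module-factors"))
    lam <- config$module_loading
    for (m in seq_along(config$module_sizes)) {
      size <- config$module_sizes[[m]]
      rows <- pos + seq_len(size)
      f <- rnorm(n)
      x[rows, ] <- lam * rep(f, each = size) + sqrt(1 - lam^2) * x[rows, ]
      module_of_gene[rows] <- sprintf("M%02d", m)
      pos <- pos + size
    }
  }

  switch_pairs <- tibble::tibble(gene_a = character(), gene_b = character(),
                                 r_a_target = numeric(), r_b_target = numeric())
  if (config$n_switch_pairs > 0L) {
    set.seed(child_seed(config$seed, "switch-factors"))
    a <- sqrt(config$switch_r)
    for (p in seq_len(config$n_switch_pairs)) {
      i <- pos + 1L
      j <- pos + 2L
      s <- rnorm(n)
      load_j <- ifelse(is_b, -a, a)
      x[i, ] <- a * s + sqrt(1 - a^2) * x[i, ]
      x[j, ] <- load_j * s + sqrt(1 - a^2) * x[j, ]
      switch_pairs <- dplyr::bind_rows(switch_pairs, tibble::tibble(
        gene_a = genes[[i]], gene_b = genes[[j]],
        r_a_target = config$switch_r, r_b_target = -config$switch_r
      ))
      pos <- pos + 2L
    }
  }

  de_genes <- tibble::tibble(gene = character(), delta = numeric())
  if (length(config$de_gene_indices)) {
    x[config$de_gene_indices, is_b] <- x[config$de_gene_indices, is_b] + config$de_shift
    de_genes <- tibble::tibble(gene = genes[config$de_gene_indices],
                               delta = config$de_shift)
  }

  phenotype <- tibble::tibble(
    sample_id = samples,
    condition = factor(ifelse(is_b, "tumor", "normal"), levels = c("normal", "tumor")),
    survival_time = NA_real_, event = NA_integer_
  )
  survival_genes <- tibble::tibble(gene = character(), beta = numeric())
  if (!is.null(config$survival_genes) && nrow(config$survival_genes)) {
    set.seed(child_seed(config$seed, "survival"))
    sg <- config$survival_genes
    lp <- drop(crossprod(x[sg$gene, is_b, drop = FALSE], sg$beta))
    rate <- config$baseline_hazard * exp(lp)
    t_raw <- rexp(n_b, rate = rate)
    phenotype$survival_time[is_b] <- pmin(t_raw, config$censor_horizon)
    phenotype$event[is_b] <- as.integer(t_raw <= config$censor_horizon)
    survival_genes <- tibble::tibble(gene = genes[sg$gene], beta = sg$beta)
  }

  truth <- structure(list(
    module_of_gene = setNames(module_of_gene, genes),
    switch_pairs = switch_pairs, de_genes = de_genes,
    survival_genes = survival_genes
  ), class = "sim_truth")
  structure(list(expression = x, phenotype = phenotype, truth = truth),
            class = "simulation")
}

#' Sample null gene-pair correlations in two conditions
#'
#' Null model for calibrating the Fisher z-difference test: each pair is drawn
#' bivariate normal with the *same* correlation `rho` in both conditions, and
#' the per-condition sample correlations are returned.
#'
#' @param n_a,n_b per-condition sample sizes (both at least 4: the Fisher
#'   variance uses `n - 3` denominators).
#' @param rho common true correlation, `|rho| < 1`.
#' @param n_pairs number of pairs to draw.
#' @param seed RNG seed.
#' @return tibble with columns `r_a`, `r_b`.
#' @export
null_pair_sample <- function(n_a, n_b, rho, n_pairs, seed = 1L) {
  if (abs(rho) >= 1) abort("|rho| must be < 1")
  if (n_a < 4L || n_b < 4L) {
    abort("Fisher variance undefined: per-condition sample sizes must be >= 4 (n - 3 denominators)")
  }
  set.seed(child_seed(seed, "null-pairs"))
  draw <- function(n) {
    z1 <- matrix(rnorm(n_pairs * n), n_pairs, n)
    z2 <- matrix(rnorm(n_pairs * n), n_pairs, n)
    y <- rho * z1 + sqrt(1 - rho^2) * z2
    row_cor(z1, y)
  }
  tibble::tibble(r_a = draw(n_a), r_b = draw(n_b))
}

# Row-wise Pearson correlation between two matrices of equal shape.
row_cor <- function(x, y) {
  n <- ncol(x)
  mx <- rowMeans(x); my <- rowMeans(y)
  xc <- x - mx; yc <- y - my
  num <- rowSums(xc * yc)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  num / den
}

#' Simulate expression with a planted power-law connectivity structure
#'
#' Generates data whose weighted co-expression network is scale-free at (and
#' above) a designated generating soft-threshold power, and *not* below it.
#' Each gene loads on one shared factor, `x_i = b_i f + sqrt(1 - b_i^2) eps`,
#' with loadings laid out on the deterministic quantile grid of the density
#' `p(b) ~ b^(power - 2)` on `(0, b_max]`, so pairwise correlations are
#' `b_i b_j` and connectivity at soft power `beta` is proportional to
#' `b_i^beta`. The binned log-log connectivity distribution then has slope
#' `(power - 1 - beta) / beta`: positive below `power - 1` (so the signed
#' scale-free fit index is 0 there), flat at `power - 1`, and an exact power
#' law with negative slope from the generating power on. The mass of genes
#' sits at high loadings, mirroring the dense moderate-correlation background
#' that makes soft-threshold selection non-trivial in real expression data.
#'
#' With `exact = TRUE` (the default) the factor and per-gene residual vectors
#' are taken from a deterministic orthonormal (discrete-cosine) sample design,
#' so the sample correlations equal `b_i b_j` exactly and the planted degree
#' structure is noise-free; `n_samples` is then `n_genes + 2`. With
#' `exact = FALSE` the vectors are drawn i.i.d. normal and the structure is
#' observed through correlation sampling noise.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples (noisy mode only).
#' @param power generating soft-threshold power (>= 3).
#' @param b_max maximal factor loading, in (0, 1).
#' @param exact use the orthonormal sample design (default `TRUE`).
#' @param seed RNG seed (noisy mode only).
#' @return list with `expression` (matrix) and `loadings`.
#' @export
simulate_scale_free <- function(n_genes = 1500L, n_samples = 300L, power = 6L,
                                b_max = 0.95, exact = TRUE, seed = 1L) {
  if (power < 3L) abort("generating power must be >= 3")
  if (b_max <= 0 || b_max >= 1) abort("b_max must be in (0, 1)")
  u <- (seq_len(n_genes) - 0.5) / n_genes
  b <- b_max * u^(1 / (power - 1))
  if (exact) {
    n <- n_genes + 2L
    t_idx <- seq_len(n) - 1L
    basis <- function(j) {
      v <- cos(pi * j * (2 * t_idx + 1) / (2 * n))  # zero-mean, mutually orthogonal
      v / sqrt(sum(v^2))
    }
    f <- basis(1L)
    x <- b %o% f
    for (i in seq_len(n_genes)) {
      x[i, ] <- x[i, ] + sqrt(1 - b[[i]]^2) * basis(i + 1L)
    }
  } else {
    n <- n_samples
    set.seed(child_seed(seed, "scale-free-data"))
    f <- rnorm(n)
    x <- b %o% f + sqrt(1 - b^2) * matrix(rnorm(n_genes * n), n_genes, n)
  }
  dimnames(x) <- list(sprintf("G%05d", seq_len(n_genes)),
                      sprintf("S%04d", seq_len(n)))
  list(expression = x, loadings = setNames(b, rownames(x)))
}
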