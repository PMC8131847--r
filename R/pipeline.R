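#' Select modules most associated with the trait
#'
#' Ranks non-grey modules by `|r_mt|` descending (ties: smaller p, then
#' label) and returns the top `top_k` labels.
#'
#' @param mt a `module_trait` result.
#' @param top_k number of modules to carry forward, default 2.
#' @return character vector of module labels.
#' @export
select_trait_modules <- function(mt, top_k = 2L) {
  stopifnot(inherits(mt, "module_trait"))
  if (top_k < 1L) abort("top_k must be >= 1")
  tab <- mt$modules[mt$modules$module != "grey", , drop = FALSE]
  if (!nrow(tab)) abort("no non-grey modules to select from")
  tab <- dplyr::arrange(tab, dplyr::desc(abs(.data$r)), .data$p, .data$module)
  if (top_k > nrow(tab)) {
    warn(sprintf("top_k = %d exceeds the %d available module(s); returning all",
                 top_k, nrow(tab)))
    top_k <- nrow(tab)
  }
  tab$module[seq_len(top_k)]
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Give either paths
#' to an expression/phenotype pair or a [sim_config()] to simulate inputs.
#'
#' @param expression_path,phenotype_path input files (TSV), or `NULL` when
#'   simulating.
#' @param simulation optional [sim_config()]; used when paths are `NULL`.
#' @param gmt_path optional GMT gene-set file for enrichment.
#' @param log2_transform apply log2(x+1) on load, default `FALSE`.
#' @param scaling optional scaling method (see [scale_expression()]);
#'   `NULL` = none.
#' @param power soft-threshold power, or `"auto"` to select by the
#'   scale-free criterion.
#' @param candidate_powers candidates for auto selection.
#' @param r2_floor scale-free fit floor for auto selection.
#' @param min_module_size,cut_height module detection parameters.
#' @param top_k_modules trait-associated modules carried into the
#'   differential-correlation stage, default 2.
#' @param r_cutoff eigen-molecule clustering correlation cutoff, default 0.6.
#' @param diffcorr_scope `"selected_modules"` (default) computes pair
#'   correlations only within each selected module, as in the
#'   module-restricted design; `"all"` opts into all gene pairs (quadratic
#'   cost).
#' @param alpha_lfdr,alpha_de,min_abs_r,de_rule switching-pair parameters.
#' @param n_cutoffs survival scan cutoffs, default 90.
#' @param max_survival_genes cap on scanned genes (the switching genes are
#'   scanned, most-significant pairs first), default 20.
#' @param seed root seed for any simulation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_path = NULL, phenotype_path = NULL,
                            simulation = NULL, gmt_path = NULL,
                            log2_transform = FALSE, scaling = NULL,
                            power = "auto",
                            candidate_powers = c(1:10, seq(12L, 20L, 2L)),
                            r2_floor = 0.8, min_module_size = 30L,
                            cut_height = NULL, top_k_modules = 2L,
                            r_cutoff = 0.6, diffcorr_scope = "selected_modules",
                            alpha_lfdr = 0.05, alpha_de = 0.05,
                            min_abs_r = 0, de_rule = "both", n_cutoffs = 90L,
                            max_survival_genes = 20L, seed = 1L) {
  if (is.null(simulation) && (is.null(expression_path) || is.null(phenotype_path))) {
    abort("give expression_path + phenotype_path, or a simulation config")
  }
  if (top_k_modules < 1L) abort("top_k_modules must be >= 1")
  if (!identical(power, "auto") && (!is.numeric(power) || power < 1)) {
    abort("power must be 'auto' or a number >= 1")
  }
  de_rule <- match.arg(de_rule, c("both", "either"))
  diffcorr_scope <- match.arg(diffcorr_scope, c("selected_modules", "all"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a flat key-value pipeline configuration file (YAML dialect)
#'
#' Keys mirror the arguments of [pipeline_config()]; simulation parameters
#' are given under a nested `simulation:` block mirroring [sim_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$simulation)) {
    vals$simulation <- do.call(sim_config, vals$simulation)
  }
  do.call(pipeline_config, vals)
}

#' Run the full differential co-expression pipeline
#'
#' Stages, in order: load or simulate inputs; optional scaling; invariant-gene
#' filtering; soft-threshold selection (or fixed power); adjacency and TOM;
#' module detection; eigengenes and module-trait association; selection of
#' the `top_k_modules` trait-associated modules; differential expression
#' (all genes); per-module differential correlation of all gene pairs within
#' each selected module; switching-pair detection; eigen-molecule module
#' networks over the selected genes; optional gene-set enrichment of the
#' switching genes; optional survival cutoff scans of the switching genes.
#' Every intermediate table is written to `outdir`; identical config and seed
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the run manifest (list), invisibly written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  warnings_seen <- character()
  note <- function(stage, n_in, n_out, t0) {
    stages[[length(stages) + 1L]] <<- list(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(as.numeric(Sys.time()) - t0, 3)
    )
    inform(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  # --- load or simulate -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- run_stage("simulate", simulate_expression(config$simulation))
    x <- sim$expression; phenotype <- sim$phenotype; truth <- sim$truth
    write_expression(x, file.path(outdir, "expression.tsv"))
    write_phenotype(phenotype, file.path(outdir, "phenotype.tsv"))
    jsonlite::write_json(
      list(module_of_gene = as.list(truth$module_of_gene),
           switch_pairs = truth$switch_pairs, de_genes = truth$de_genes,
           survival_genes = truth$survival_genes),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    x <- run_stage("load", read_expression(config$expression_path,
                                           log2_transform = config$log2_transform))
    phenotype <- run_stage("load", read_phenotype(config$phenotype_path))
  }
  phenotype <- match_phenotype(x, phenotype)
  note("load", nrow(x), nrow(x), t0)

  if (!is.null(config$scaling)) {
    t0 <- as.numeric(Sys.time())
    x <- run_stage("scale", scale_expression(x, config$scaling))
    note("scale", nrow(x), nrow(x), t0)
  }

  t0 <- as.numeric(Sys.time())
  filt <- run_stage("filter", filter_invariant_genes(x, phenotype))
  x <- filt$expression
  note("filter", nrow(x) + length(filt$removed), nrow(x), t0)

  # --- network --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (identical(config$power, "auto")) {
    st <- run_stage("soft_threshold",
                    pick_soft_threshold(x, config$candidate_powers,
                                        r2_floor = config$r2_floor))
    beta <- chosen_power(st)
    write.table(as.data.frame(st), file.path(outdir, "soft_threshold.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    beta <- as.integer(config$power)
  }
  adj <- run_stage("network", adjacency(x, beta))
  tom <- run_stage("network", topological_overlap(adj))
  note("network", nrow(x), nrow(tom), t0)

  t0 <- as.numeric(Sys.time())
  mods <- run_stage("modules", detect_modules(tom, config$min_module_size,
                                              config$cut_height))
  write.table(as.data.frame(mods$modules), file.path(outdir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("modules", nrow(tom), length(mods$sizes), t0)

  t0 <- as.numeric(Sys.time())
  eig <- run_stage("eigengenes", module_eigengenes(x, mods))
  mt <- run_stage("module_trait", module_trait(eig, phenotype, x, mods))
  write.table(data.frame(sample_id = rownames(eig$eigengenes), eig$eigengenes,
                         check.names = FALSE),
              file.path(outdir, "eigengenes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(mt$modules), file.path(outdir, "module_trait.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  selected <- run_stage("select_modules",
                        select_trait_modules(mt, config$top_k_modules))
  note("module_trait", ncol(eig$eigengenes), length(selected), t0)

  # --- differential expression & correlation --------------------------------
  t0 <- as.numeric(Sys.time())
  de <- run_stage("de", differential_expression(x, phenotype))
  write.table(as.data.frame(de), file.path(outdir, "de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("de", nrow(x), sum(de$adjusted_p < config$alpha_de), t0)

  t0 <- as.numeric(Sys.time())
  records <- if (config$diffcorr_scope == "all") {
    rec <- run_stage("diffcorr", estimate_lfdr(diffcorr_pairs(x, phenotype)))
    rec$module <- "all"
    tibble::as_tibble(rec)
  } else {
    dplyr::bind_rows(lapply(selected, function(m) {
      genes <- mods$modules$gene[mods$modules$module == m]
      rec <- run_stage("diffcorr", estimate_lfdr(diffcorr_pairs(x, phenotype, genes)))
      rec$module <- m
      tibble::as_tibble(rec)
    }))
  }
  write.table(as.data.frame(records[, c("gene_a", "gene_b", "r_a", "r_b",
                                        "lfdr", "module", "z_diff", "p_diff")]),
              file.path(outdir, "diffcorr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("diffcorr", length(selected), nrow(records), t0)

  t0 <- as.numeric(Sys.time())
  switching <- run_stage("switching", detect_switching(
    records, de, alpha_lfdr = config$alpha_lfdr, alpha_de = config$alpha_de,
    min_abs_r = config$min_abs_r, de_rule = config$de_rule
  ))
  write.table(as.data.frame(switching), file.path(outdir, "switching.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(switching)) {
    sw_edges <- network_edges(
      switching$gene_a, switching$gene_b, weight = abs(switching$r_b),
      sign = ifelse(switching$r_b >= 0, "+", "-"),
      annotation = switching$module
    )
    write_network(sw_edges, file.path(outdir, "switching_network.tsv"), "tsv")
    write_network(sw_edges, file.path(outdir, "switching_network.graphml"), "graphml")
  }
  note("switching", nrow(records), nrow(switching), t0)

  t0 <- as.numeric(Sys.time())
  sel_genes <- mods$modules$gene[mods$modules$module %in% selected]
  em <- run_stage("eigen_modules", {
    cl <- cluster_molecules(x, phenotype, genes = sel_genes,
                            r_cutoff = config$r_cutoff)
    eigen_module_diffcorr(cl, x, phenotype)
  })
  if (nrow(em)) {
    write_network(eigen_module_edges(em, clustering = "tumor"),
                  file.path(outdir, "eigen_module_network.graphml"), "graphml")
    write.table(as.data.frame(em), file.path(outdir, "eigen_module_diffcorr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("eigen_modules", length(sel_genes), nrow(em), t0)

  # --- enrichment -----------------------------------------------------------
  if (!is.null(config$gmt_path) && nrow(switching)) {
    t0 <- as.numeric(Sys.time())
    sets <- run_stage("enrich", read_gmt(config$gmt_path))
    enr <- run_stage("enrich", hypergeom_enrichment(
      unique(c(switching$gene_a, switching$gene_b)), sets, rownames(x)
    ))
    write.table(as.data.frame(enr), file.path(outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("enrich", length(sets), nrow(enr), t0)
  }

  # --- survival -------------------------------------------------------------
  has_survival <- "survival_time" %in% colnames(phenotype) &&
    any(!is.na(phenotype$survival_time))
  if (has_survival && nrow(switching)) {
    t0 <- as.numeric(Sys.time())
    sw_genes <- unique(c(rbind(switching$gene_a, switching$gene_b)))
    sw_genes <- head(sw_genes, config$max_survival_genes)
    scans <- lapply(sw_genes, function(g) {
      sc <- run_stage("survival", survival_cutoff_scan(
        x[g, , drop = FALSE], phenotype, n_cutoffs = config$n_cutoffs
      ))
      tibble::tibble(gene = g, best_quantile = sc$best_quantile,
                     best_cutoff = sc$best_cutoff, min_p = sc$min_p,
                     hazard_ratio = sc$hazard_ratio,
                     significant = sc$significant)
    })
    surv_tab <- dplyr::bind_rows(scans)
    write.table(as.data.frame(surv_tab), file.path(outdir, "survival_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("survival", length(sw_genes), sum(surv_tab$significant), t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("switchcor")),
    seed = config$seed,
    power = beta,
    selected_modules = selected,
    stages = stages,
    warnings = warnings_seen,
    config = config_echo(config)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}

# JSON-friendly echo of a pipeline_config (simulation config flattened).
config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out[!vapply(out, is.function, logical(1L))]
}

#' Compare detected switching pairs with a planted truth
#'
#' Recall and empirical false discovery rate of a switching-pair table
#' against the `switch_pairs` of a [simulate_expression()] truth (pairs are
#' matched regardless of endpoint order).
#'
#' @param switching switching-pair tibble (`gene_a`, `gene_b`).
#' @param truth a `sim_truth` or its `switch_pairs` tibble.
#' @return tibble with `n_detected`, `n_true`, `recall`, `fdr`.
#' @export
evaluate_switching <- function(switching, truth) {
  pairs_true <- if (inherits(truth, "sim_truth")) truth$switch_pairs else truth
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_keys <- key(pairs_true$gene_a, pairs_true$gene_b)
  det_keys <- key(switching$gene_a, switching$gene_b)
  tp <- sum(det_keys %in% truth_keys)
  tibble::tibble(
    n_detected = length(det_keys), n_true = length(truth_keys),
    recall = if (length(truth_keys)) tp / length(truth_keys) else NA_real_,
    fdr = if (length(det_keys)) 1 - tp / length(det_keys) else 0
  )
}
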