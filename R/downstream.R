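#' Per-gene two-sample differential expression
#'
#' Student's t-test per gene between tumor and normal samples
#' (pooled-variance by default; `var_equal = FALSE` gives the Welch variant),
#' with Benjamini-Hochberg adjustment across all tested genes. Direction is
#' tumor relative to normal. Genes with zero pooled variance are flagged
#' (`degenerate`) and assigned `t = 0`, `p = 1` rather than erroring.
#'
#' @param x gene-by-sample matrix.
#' @param phenotype phenotype tibble.
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @return tibble of class `de_result`: columns `gene`, `mean_normal`,
#'   `mean_tumor`, `t_statistic`, `raw_p`, `adjusted_p`, `direction`,
#'   `degenerate`.
#' @export
differential_expression <- function(x, phenotype, var_equal = TRUE) {
  cols <- condition_columns(x, phenotype)
  n1 <- length(cols$normal); n2 <- length(cols$tumor)
  if (n1 < 2L || n2 < 2L) abort("each condition needs >= 2 samples")
  xa <- x[, cols$normal, drop = FALSE]
  xb <- x[, cols$tumor, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, 0, (m2 - m1) / se)
  raw_p <- ifelse(degenerate, 1, 2 * pt(-abs(t_stat), df = df))
  out <- tibble::tibble(
    gene = rownames(x), mean_normal = unname(m1), mean_tumor = unname(m2),
    t_statistic = unname(t_stat), raw_p = unname(raw_p),
    adjusted_p = unname(benjamini_hochberg(raw_p)),
    direction = unname(ifelse(m2 >= m1, "up", "down")),
    degenerate = unname(degenerate)
  )
  structure(out, class = c("de_result", class(out)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `p_(i) * m / i` with cumulative-minimum enforcement and
#' a cap at 1; adjusted values follow their p-values under reordering.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set, within a stated universe:
#' `p = P(X >= k)` for `X ~ Hypergeom(K, N - K, n)`, where `k` is the
#' observed overlap, `K` the set size in the universe, `n` the query size and
#' `N` the universe size. Query genes outside the universe are dropped with a
#' warning; p-values are BH-adjusted across sets and results sorted by p.
#'
#' @param query character vector of genes of interest.
#' @param sets a `gene_set_collection` (or named list of gene vectors).
#' @param universe character vector of all analyzed genes.
#' @return tibble of class `enrichment_result`: columns `set`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `adjusted_p`.
#' @export
hypergeom_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  n_univ <- length(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warn(sprintf("dropping %d query gene(s) outside the universe", length(dropped)))
  }
  query <- intersect(unique(query), universe)
  if (!length(query)) abort("empty query after intersecting with the universe")
  rows <- purrr::imap(as.list(sets), function(members, name) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(query, members))
    k_size <- length(members)
    p <- phyper(k - 1L, k_size, n_univ - k_size, length(query), lower.tail = FALSE)
    tibble::tibble(set = name, overlap = k, set_size = k_size,
                   query_size = length(query), universe_size = n_univ, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- benjamini_hochberg(out$p)
  out <- dplyr::arrange(out, .data$p, .data$set)
  structure(out, class = c("enrichment_result", class(out)))
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimator over distinct event times; times with censoring
#' only reduce the risk set without a step.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 death, 0 censored).
#' @return tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) abort("empty survival input")
  if (any(times < 0)) abort("negative survival times")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the observed minus expected
#' events in group 1 with hypergeometric variance; chi-square with 1 df.
#' Invariant to swapping the group labels. With no events at all the test is
#' undefined and `p = 1` is returned with a flag.
#'
#' @param times_1,events_1 follow-up and event indicators for group 1.
#' @param times_2,events_2 the same for group 2.
#' @return list with `chi_square`, `p`, `n_1`, `n_2`, `flag_no_events`.
#' @export
logrank_test <- function(times_1, events_1, times_2, events_2) {
  if (!length(times_1) || !length(times_2)) abort("both groups must be non-empty")
  times <- c(times_1, times_2)
  events <- c(events_1, events_2)
  group <- rep(1:2, c(length(times_1), length(times_2)))
  if (sum(events) == 0) {
    return(list(chi_square = 0, p = 1, n_1 = length(times_1),
                n_2 = length(times_2), flag_no_events = TRUE))
  }
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  chi <- unname(sd_fit$chisq)
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE),
       n_1 = length(times_1), n_2 = length(times_2), flag_no_events = FALSE)
}

#' Minimum-p expression-cutoff survival scan
#'
#' Dichotomizes a gene's expression at `n_cutoffs` evenly spaced quantile
#' levels spanning 5 to 95 percent (inclusive; linear-interpolation
#' quantiles), splits samples into low (`< cutoff`) and high (`>= cutoff`)
#' groups, runs a log-rank test at each split (skipping cutoffs that leave a
#' group empty), and selects the cutoff with the smallest p (ties: the lower
#' quantile). Kaplan-Meier curves of both groups and a descriptive univariate
#' Cox hazard ratio (high vs low, Breslow ties) are reported at the selected
#' cutoff. The reported minimum p is not corrected for scanning multiplicity,
#' so its null distribution is anti-conservative; treat `significant` as a
#' screening flag.
#'
#' @param x_gene named numeric vector of one gene's expression (names are
#'   sample ids), or a 1-row matrix.
#' @param phenotype phenotype tibble with `survival_time` and `event`.
#' @param n_cutoffs number of quantile levels, default 90.
#' @param quantile_range range of quantile levels, default `c(0.05, 0.95)`.
#' @return object of class `survival_scan`: list with `scan` (tibble
#'   `quantile`, `cutoff`, `n_low`, `n_high`, `chi_square`, `p`),
#'   `best_quantile`, `best_cutoff`, `min_p`, `hazard_ratio`, `km` (tibble
#'   with a `group` column), `significant`, `n`.
#' @export
survival_cutoff_scan <- function(x_gene, phenotype, n_cutoffs = 90L,
                                 quantile_range = c(0.05, 0.95)) {
  if (is.matrix(x_gene)) {
    stopifnot(nrow(x_gene) == 1L)
    x_gene <- setNames(drop(x_gene), colnames(x_gene))
  }
  if (!all(c("survival_time", "event") %in% colnames(phenotype))) {
    abort("phenotype carries no survival columns")
  }
  ph <- phenotype[!is.na(phenotype$survival_time) & !is.na(phenotype$event), , drop = FALSE]
  ph <- ph[ph$sample_id %in% names(x_gene), , drop = FALSE]
  if (nrow(ph) < 10L) abort("fewer than 10 samples with survival data")
  xv <- x_gene[ph$sample_id]
  grid <- seq(quantile_range[[1L]], quantile_range[[2L]], length.out = n_cutoffs)
  cuts <- quantile(xv, probs = grid, type = 7, names = FALSE)
  rows <- vector("list", n_cutoffs)
  for (i in seq_len(n_cutoffs)) {
    low <- xv < cuts[[i]]
    n_low <- sum(low); n_high <- sum(!low)
    if (n_low == 0L || n_high == 0L) next
    lr <- logrank_test(ph$survival_time[low], ph$event[low],
                       ph$survival_time[!low], ph$event[!low])
    rows[[i]] <- tibble::tibble(quantile = grid[[i]], cutoff = cuts[[i]],
                                n_low = n_low, n_high = n_high,
                                chi_square = lr$chi_square, p = lr$p)
  }
  scan <- dplyr::bind_rows(rows)
  if (nrow(scan) < 2L) abort("fewer than 2 cutoffs produce two non-empty groups")
  best <- which(scan$p == min(scan$p))[1L]  # ties -> lower quantile
  low <- xv < scan$cutoff[[best]]
  km <- dplyr::bind_rows(
    dplyr::mutate(km_curve(ph$survival_time[low], ph$event[low]), group = "low"),
    dplyr::mutate(km_curve(ph$survival_time[!low], ph$event[!low]), group = "high")
  )
  hr <- tryCatch({
    fit <- survival::coxph(
      survival::Surv(ph$survival_time, ph$event) ~ I(!low),
      ties = "breslow"
    )
    unname(exp(coef(fit)[1L]))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  structure(list(
    scan = scan, best_quantile = scan$quantile[[best]],
    best_cutoff = scan$cutoff[[best]], min_p = scan$p[[best]],
    hazard_ratio = hr, km = km, significant = scan$p[[best]] < 0.05,
    n = length(xv)
  ), class = "survival_scan")
}

#' @export
print.survival_scan <- function(x, ...) {
  cat(sprintf(
    "survival cutoff scan: n = %d, %d cutoffs; min p = %.3g at quantile %.3f (HR high vs low = %.3g)%s\n",
    x$n, nrow(x$scan), x$min_p, x$best_quantile, x$hazard_ratio,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}
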