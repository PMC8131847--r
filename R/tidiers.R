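#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a soft-threshold report
#' @param x a `soft_threshold` object.
#' @param ... unused.
#' @return tibble with one row per candidate power and a `chosen` flag.
#' @export
tidy.soft_threshold <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$chosen <- out$power == attr(x, "chosen_power")
  out
}

#' One-row summary of a soft-threshold report
#' @param x a `soft_threshold` object.
#' @param ... unused.
#' @export
glance.soft_threshold <- function(x, ...) {
  chosen <- attr(x, "chosen_power")
  row <- which(x$power == chosen)
  tibble::tibble(chosen_power = chosen, r_squared = x$r_squared[row],
                 mean_connectivity = x$mean_connectivity[row],
                 r2_floor = attr(x, "r2_floor"))
}

#' Tidy a module assignment
#' @param x a `module_assignment`.
#' @param ... unused.
#' @return tibble with `gene` and `module`.
#' @export
tidy.module_assignment <- function(x, ...) x$modules

#' One-row summary of a module assignment
#' @param x a `module_assignment`.
#' @param ... unused.
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$modules), n_modules = length(x$sizes),
    n_grey = sum(x$modules$module == "grey"),
    largest = if (length(x$sizes)) as.integer(x$sizes[[1L]]) else NA_integer_,
    cut_height = x$cut_height
  )
}

#' Tidy an eigengene set
#' @param x an `eigengene_set`.
#' @param ... unused.
#' @return long tibble with `sample_id`, `module`, `eigengene`.
#' @export
tidy.eigengene_set <- function(x, ...) {
  e <- x$eigengenes
  tidyr::pivot_longer(
    tibble::as_tibble(e, rownames = "sample_id"),
    -"sample_id", names_to = "module", values_to = "eigengene"
  )
}

#' Tidy a module-trait result
#' @param x a `module_trait`.
#' @param ... unused.
#' @return tibble with per-module `r`, `p`, `n`.
#' @export
tidy.module_trait <- function(x, ...) x$modules

#' Tidy a survival scan
#' @param x a `survival_scan`.
#' @param ... unused.
#' @return per-cutoff tibble.
#' @export
tidy.survival_scan <- function(x, ...) x$scan

#' One-row summary of a survival scan
#' @param x a `survival_scan`.
#' @param ... unused.
#' @export
glance.survival_scan <- function(x, ...) {
  tibble::tibble(n = x$n, n_cutoffs = nrow(x$scan),
                 best_quantile = x$best_quantile, best_cutoff = x$best_cutoff,
                 min_p = x$min_p, hazard_ratio = x$hazard_ratio,
                 significant = x$significant)
}
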