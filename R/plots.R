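#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_step
#'   geom_hline geom_col geom_text labs theme_minimal scale_y_continuous
#'   facet_wrap coord_flip
#' @export
ggplot2::autoplot

#' Plot a soft-threshold report
#'
#' Scale-free fit index against candidate power; the dashed line marks the
#' acceptance floor and the filled point the chosen power.
#'
#' @param object a `soft_threshold` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.soft_threshold <- function(object, ...) {
  tab <- tidy(object)
  ggplot(tab, aes(x = .data$power, y = .data$r_squared)) +
    geom_line(color = "grey50") +
    geom_point(aes(shape = .data$chosen, size = .data$chosen), show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 3)) +
    geom_hline(yintercept = attr(object, "r2_floor"), linetype = "dashed") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "soft-threshold power", y = expression("scale-free fit " * R^2)) +
    theme_minimal()
}

#' Plot module-trait correlations
#'
#' @param object a `module_trait` result.
#' @param ... unused.
#' @return a ggplot of per-module trait correlations.
#' @export
autoplot.module_trait <- function(object, ...) {
  tab <- dplyr::arrange(object$modules, .data$r)
  tab$module <- factor(tab$module, levels = tab$module)
  ggplot(tab, aes(x = .data$module, y = .data$r, fill = .data$r)) +
    geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = "eigengene-trait correlation") +
    theme_minimal()
}

#' Plot a survival cutoff scan
#'
#' Kaplan-Meier curves of the low and high expression groups at the selected
#' (minimum-p) cutoff.
#'
#' @param object a `survival_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.survival_scan <- function(object, ...) {
  km <- object$km
  ggplot(km, aes(x = .data$time, y = .data$survival, color = .data$group)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "time", y = "survival probability", color = "expression",
         subtitle = sprintf("min log-rank p = %.3g at quantile %.2f",
                            object$min_p, object$best_quantile)) +
    theme_minimal()
}

#' Volcano-style plot of differential-correlation pairs
#'
#' @param object a `diffcorr_tbl` (ideally with an `lfdr` column).
#' @param alpha_lfdr highlighting threshold, default 0.05.
#' @param ... unused.
#' @return a ggplot of per-condition correlations, switching candidates
#'   highlighted.
#' @export
autoplot.diffcorr_tbl <- function(object, alpha_lfdr = 0.05, ...) {
  tab <- tibble::as_tibble(object)
  tab$state <- if ("lfdr" %in% colnames(tab)) {
    ifelse(tab$lfdr < alpha_lfdr & sign(tab$r_a) * sign(tab$r_b) < 0,
           "switching", ifelse(tab$lfdr < alpha_lfdr, "differential", "null"))
  } else "null"
  ggplot(tab, aes(x = .data$r_a, y = .data$r_b, color = .data$state)) +
    geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "correlation (normal)", y = "correlation (tumor)", color = NULL) +
    theme_minimal()
}
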