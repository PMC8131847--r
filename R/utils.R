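#' @importFrom rlang %||% abort warn inform
#' @importFrom stats cor sd var quantile density dnorm pnorm pt pchisq phyper
#'   p.adjust rnorm rexp runif setNames approx hclust cutree as.dist prcomp
#'   complete.cases bw.nrd0 lm coef
#' @importFrom utils read.table write.table head
NULL

# Deterministic per-stage child seed from one root seed. Kept below 2^31 so
# set.seed() always accepts it; the stage string decouples the streams so that
# adding a simulation stage never perturbs the draws of earlier stages.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Validate a gene-by-sample expression matrix
#'
#' Checks the container contract used throughout the package: a numeric matrix
#' with unique, non-empty gene rownames and sample colnames and no missing
#' values.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    abort(paste0("duplicate gene identifier(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    abort(paste0("duplicate sample identifier(s): ", paste(dup_s, collapse = ", ")))
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "missing expression value at row %d (gene %s), column %d (sample %s)",
      idx[1L], rownames(x)[idx[1L]], idx[2L], colnames(x)[idx[2L]]
    ))
  }
  invisible(x)
}

# Split sample ids of `x` by condition, in the column order of `x`.
condition_columns <- function(x, phenotype) {
  ph <- match_phenotype(x, phenotype)
  split(ph$sample_id, ph$condition)[c("normal", "tumor")]
}

# Align a phenotype table to the columns of an expression matrix; every sample
# must appear exactly once.
match_phenotype <- function(x, phenotype) {
  stopifnot(is.data.frame(phenotype))
  missing <- setdiff(colnames(x), phenotype$sample_id)
  if (length(missing)) {
    abort(paste0(
      "sample(s) absent from phenotype table: ",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  dup <- unique(phenotype$sample_id[duplicated(phenotype$sample_id)])
  if (length(dup)) {
    abort(paste0("duplicate sample_id in phenotype table: ", paste(dup, collapse = ", ")))
  }
  ph <- phenotype[match(colnames(x), phenotype$sample_id), , drop = FALSE]
  ph$condition <- factor(as.character(ph$condition), levels = c("normal", "tumor"))
  if (anyNA(ph$condition)) abort("phenotype condition contains values outside {normal, tumor}")
  tibble::as_tibble(ph)
}

# Standardize rows of a matrix to mean 0, sd 1 (sd with n-1 denominator).
standardize_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  if (any(s == 0)) {
    abort(paste0(
      "zero-variance gene(s): ",
      paste(head(rownames(x)[s == 0], 5L), collapse = ", ")
    ))
  }
  (x - m) / s
}
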