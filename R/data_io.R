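#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file with gene identifiers in the first column and a
#' header row of sample identifiers. Values must be complete and numeric:
#' missing or non-numeric cells are a hard error (silent imputation would
#' corrupt downstream correlation tests), reported with their gene/sample
#' coordinates. Constant (zero-variance) genes are retained here; removing
#' them is an explicit separate step ([filter_invariant_genes()]).
#'
#' @param path path to the file.
#' @param delimiter field separator, default tab.
#' @param log2_transform apply `log2(x + 1)` after loading (default `FALSE`).
#'   The choice is logged so runs stay auditable.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, delimiter = "\t", log2_transform = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.table(
    path, header = TRUE, sep = delimiter, check.names = FALSE,
    colClasses = "character", quote = "", comment.char = ""
  )
  if (ncol(df) < 2L) abort("expression file needs a gene column plus >= 1 sample column")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    abort(paste0("duplicate sample identifier(s) in header: ", paste(dup_s, collapse = ", ")))
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) {
    abort(paste0("duplicate gene identifier(s): ", paste(dup_g, collapse = ", ")))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "non-numeric or missing value '%s' at row %d (gene %s), column %d (sample %s)",
      raw[idx[1L], idx[2L]], idx[1L], genes[idx[1L]], idx[2L], samples[idx[2L]]
    ))
  }
  dimnames(vals) <- list(genes, samples)
  if (isTRUE(log2_transform)) {
    inform("applying log2(x + 1) transform to expression values")
    vals <- log2(vals + 1)
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix to a delimited file
#'
#' @param x numeric gene-by-sample matrix.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Expects columns `sample_id` and `condition` (levels `normal` and `tumor`);
#' optional `survival_time` (non-negative, days) and `event` (0 censored,
#' 1 death) columns. If `survival_time` is present, `event` must be present
#' for the same samples. Unrecognized columns are dropped with a warning.
#'
#' @param path path to a tab-separated file with a header row.
#' @return tibble with columns `sample_id`, `condition` (factor
#'   normal/tumor) and, when available, `survival_time` and `event`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  req <- c("sample_id", "condition")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) abort(paste0("phenotype table missing column(s): ", paste(miss, collapse = ", ")))
  known <- c(req, "survival_time", "event")
  extra <- setdiff(colnames(df), known)
  if (length(extra)) {
    warn(paste0("ignoring unrecognized phenotype column(s): ", paste(extra, collapse = ", ")))
    df <- df[, intersect(known, colnames(df)), drop = FALSE]
  }
  levs <- sort(unique(as.character(df$condition)))
  if (!all(levs %in% c("normal", "tumor"))) {
    abort(paste0(
      "condition must have levels {normal, tumor}; found ", length(levs),
      " level(s): ", paste(levs, collapse = ", ")
    ))
  }
  df$condition <- factor(df$condition, levels = c("normal", "tumor"))
  has_time <- "survival_time" %in% colnames(df)
  has_event <- "event" %in% colnames(df)
  if (has_time && !has_event) abort("survival_time present but event column missing")
  if (has_event && !has_time) abort("event present but survival_time column missing")
  if (has_time) {
    bad <- !is.na(df$survival_time) & is.na(df$event)
    if (any(bad)) {
      abort(paste0("survival_time without event for sample(s): ",
                   paste(df$sample_id[bad], collapse = ", ")))
    }
    if (any(df$survival_time < 0, na.rm = TRUE)) abort("negative survival_time")
    if (!all(df$event %in% c(0, 1, NA))) abort("event must be 0 (censored) or 1 (death)")
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  tibble::as_tibble(df)
}

#' Write a phenotype table
#' @param phenotype tibble as returned by [read_phenotype()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  write.table(as.data.frame(phenotype), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name TAB description TAB member1 TAB member2 ...`. Duplicate members within
#' a set are collapsed; sets left empty are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_set_collection`: a named list of unique
#'   member vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                    i, length(fields)))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warn(sprintf("dropping empty gene set '%s' (line %d)", fields[[1L]], i))
      next
    }
    sets[[fields[[1L]]]] <- members
    descs[[fields[[1L]]]] <- fields[[2L]]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Construct a network edge table
#'
#' Undirected edges are stored once with `gene_a` lexicographically before
#' `gene_b`; endpoint order in the input is normalized and exact duplicates
#' are dropped.
#'
#' @param gene_a,gene_b endpoint gene identifiers.
#' @param weight finite numeric edge weight.
#' @param sign `"+"` or `"-"`.
#' @param annotation free-text annotation (default empty).
#' @return tibble with columns `gene_a`, `gene_b`, `weight`, `sign`,
#'   `annotation`.
#' @export
network_edges <- function(gene_a, gene_b, weight, sign = "+", annotation = "") {
  if (length(gene_a) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          weight = numeric(), sign = character(),
                          annotation = character()))
  }
  if (!all(is.finite(weight))) abort("edge weights must be finite")
  if (!all(sign %in% c("+", "-"))) abort("edge sign must be '+' or '-'")
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  if (any(a == b)) abort("self-edges are not allowed")
  out <- tibble::tibble(gene_a = a, gene_b = b, weight = as.numeric(weight),
                        sign = as.character(sign),
                        annotation = as.character(annotation))
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a network edge table
#'
#' Supported dialects: `"tsv"` (all columns verbatim; round-trips through
#' [read_network()]), `"sif"` (`gene_a TAB cc TAB gene_b`, loadable by common
#' graph viewers), and `"graphml"` (weight and sign carried as edge
#' attributes).
#'
#' @param edges tibble as produced by [network_edges()].
#' @param path output path.
#' @param dialect one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, dialect = c("tsv", "sif", "graphml")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(paste0("unknown network dialect: ",
                                                       dialect[[1L]])))
  stopifnot(all(c("gene_a", "gene_b", "weight", "sign") %in% colnames(edges)))
  if (nrow(edges) && any(edges$gene_a >= edges$gene_b)) {
    abort("edges must have gene_a < gene_b; use network_edges() to normalize")
  }
  if (dialect == "tsv") {
    write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (dialect == "sif") {
    lines <- if (nrow(edges)) paste(edges$gene_a, "cc", edges$gene_b, sep = "\t") else character()
    writeLines(lines, path)
  } else {
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    esc <- xml_escape
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
      "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
      "  <graph edgedefault=\"undirected\">",
      sprintf("    <node id=\"%s\"/>", esc(nodes)),
      if (nrow(edges)) sprintf(
        paste0("    <edge source=\"%s\" target=\"%s\">",
               "<data key=\"weight\">%.10g</data>",
               "<data key=\"sign\">%s</data></edge>"),
        esc(edges$gene_a), esc(edges$gene_b), edges$weight, esc(edges$sign)
      ),
      "  </graph>",
      "</graphml>"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a TSV network edge table written by [write_network()]
#' @param path path to the TSV file.
#' @return edge tibble.
#' @export
read_network <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "",
                   colClasses = c("character", "character", "numeric",
                                  "character", "character"))
  df$annotation[is.na(df$annotation)] <- ""
  tibble::as_tibble(df)
}
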