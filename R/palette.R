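#' Module color palette
#'
#' Fixed, ordered list of 180 color names used to label detected modules by
#' decreasing size (largest module = "turquoise"); genes not assigned to any
#' module are labelled "grey". The head of the list follows the conventional
#' co-expression ordering; the remainder extends it deterministically with
#' standard R color names so that runs are reproducible across sessions.
#'
#' @param n number of labels required.
#' @return character vector of `n` color names (excluding "grey").
#' @export
module_colors <- function(n = 180L) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
    "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
    "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
    "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
    "darkolivegreen", "darkmagenta", "mediumorchid", "darkseagreen"
  )
  pool <- grDevices::colors(distinct = TRUE)
  pool <- pool[!grepl("^gr[ae]y", pool)]
  pool <- setdiff(pool, c(base, "grey", "gray"))
  full <- c(base, sort(pool))
  if (n > length(full)) {
    # beyond the named palette, fall back to numbered labels
    full <- c(full, sprintf("module%03d", seq_len(n - length(full))))
  }
  full[seq_len(n)]
}
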