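# internal helpers shared across modules

# standard module colour sequence; modules are named by decreasing size in
# this order, with a numbered fallback once colours run out. "grey" is
# reserved for unassigned genes.
module_colour_sequence <- function() {
  c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
    "sienna3", "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2"
  )
}

module_labels_for <- function(n) {
  pal <- module_colour_sequence()
  if (n <= length(pal)) pal[seq_len(n)] else c(pal, paste0("module", seq_len(n - length(pal)) + length(pal)))
}

#' Coerce to a gene-by-sample expression matrix
#'
#' Accepts a numeric matrix (genes in rows, samples in columns) or a data
#' frame whose first column holds gene identifiers. Row and column names must
#' be unique and non-empty.
#'
#' @param x matrix or data frame of log-scale expression values.
#' @param cohort optional cohort name stored as an attribute.
#' @return numeric matrix with unique `rownames` (genes) and `colnames`
#'   (samples) and a `cohort` attribute.
#' @export
as_expression_matrix <- function(x, cohort = NULL) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[, -1, drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.matrix(x)) stop("expression input must be a matrix or data frame", call. = FALSE)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(rownames(x) == "")) {
    stop("expression matrix needs non-empty gene identifiers as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers", call. = FALSE)
  attr(x, "cohort") <- cohort %||% attr(x, "cohort") %||% "cohort"
  x
}

cohort_name <- function(m, default = "cohort") {
  attr(m, "cohort") %||% default
}

cohort_names <- function(cohorts) {
  nm <- names(cohorts)
  auto <- vapply(seq_along(cohorts), function(i) {
    cohort_name(cohorts[[i]], paste0("cohort", i))
  }, character(1))
  if (is.null(nm)) return(auto)
  ifelse(is.na(nm) | nm == "", auto, nm)
}

# named list of expression matrices, validated and aligned on names
as_cohort_list <- function(cohorts) {
  if (is.matrix(cohorts) || is.data.frame(cohorts)) cohorts <- list(cohorts)
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  out <- lapply(cohorts, as_expression_matrix)
  names(out) <- cohort_names(out)
  for (i in seq_along(out)) attr(out[[i]], "cohort") <- names(out)[i]
  out
}

upper_tri_values <- function(m) m[upper.tri(m)]

check_same_genes <- function(mats) {
  ids <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), ids)) {
      stop("matrices must share an identical, identically ordered gene list", call. = FALSE)
    }
  }
  ids
}

# correlation with pairwise-complete observations; constant columns give NA,
# which callers replace (with a warning) rather than error
safe_cor <- function(x, y = NULL) {
  suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
}
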