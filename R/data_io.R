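#' Read a gene-by-sample expression matrix
#'
#' Reads either a plain tab-separated matrix (first column = row identifiers,
#' header = sample identifiers) or the GEO series-matrix dialect, where the
#' expression block is delimited by the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` markers and cells may be quoted or `"null"`.
#' Unparseable cells become missing values.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param cohort optional cohort name attached to the result.
#' @return a numeric matrix (genes x samples) with a `cohort` attribute.
#' @export
load_expression_matrix <- function(path, format = c("tsv", "series_matrix"),
                                   cohort = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
      stop("empty or malformed series-matrix data block", call. = FALSE)
    }
    lines <- lines[(begin + 1):(end - 1)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("empty expression data block", call. = FALSE)
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  samples <- header[-1]
  if (length(samples) == 0) stop("no sample columns found", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers in header", call. = FALSE)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(cells, function(x) strip(x[[1]]), character(1))
  vals <- t(vapply(cells, function(x) {
    v <- strip(x[-1])
    v[v %in% c("", "null", "NULL", "NA", "na")] <- NA
    out <- suppressWarnings(as.numeric(v))
    length(out) <- length(samples)
    out
  }, numeric(length(samples))))
  if (length(samples) == 1) vals <- matrix(vals, ncol = 1)
  rownames(vals) <- ids
  colnames(vals) <- samples
  as_expression_matrix(vals, cohort = cohort %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a probe-to-gene map
#'
#' Two-column tab-separated file: `probe_id`, `gene_symbol`. An empty gene
#' symbol marks an unmapped probe.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character", check.names = FALSE)
  names(df)[1:2] <- c("probe_id", "gene_symbol")
  if (anyDuplicated(df$probe_id)) stop("duplicate probe identifiers in map", call. = FALSE)
  as_tibble(df[, 1:2])
}

#' Read a per-sample trait table
#'
#' Tab-separated file with columns `sample_id`, `phenotype` (1 = case,
#' 0 = control), `fvc`, `dlco`; empty cells are missing. Extra columns are
#' kept as additional numeric traits.
#'
#' @param path path to the TSV file.
#' @return tibble keyed by `sample_id`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE, na.strings = c("", "NA"))
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (col in setdiff(names(df), "sample_id")) df[[col]] <- as.numeric(df[[col]])
  validate_trait_table(as_tibble(df))
}

validate_trait_table <- function(traits, expression = NULL) {
  stopifnot(is.data.frame(traits), "sample_id" %in% names(traits))
  if ("phenotype" %in% names(traits)) {
    ph <- traits$phenotype[!is.na(traits$phenotype)]
    if (!all(ph %in% c(0, 1))) stop("phenotype must be coded 0/1", call. = FALSE)
    if (length(unique(ph)) < 2) stop("phenotype needs at least one case and one control", call. = FALSE)
  }
  if (!is.null(expression) && !all(traits$sample_id %in% colnames(expression))) {
    stop("trait table contains samples absent from the expression matrix", call. = FALSE)
  }
  as_tibble(traits)
}

#' Collapse probe-level rows to gene symbols
#'
#' When several probes map to the same gene, the probe with the highest
#' expression is retained; "highest" is the mean across samples by default
#' (missing values ignored), or the maximum single value with
#' `method = "absolute_max"`. Unmapped probes (empty gene symbol) are dropped
#' and gene symbols are upper-cased.
#'
#' @param m expression matrix keyed by probe identifiers.
#' @param map data frame with columns `probe_id`, `gene_symbol`.
#' @param method `"mean"` (default) or `"absolute_max"`.
#' @return expression matrix keyed by unique gene symbols.
#' @export
collapse_probes <- function(m, map, method = c("mean", "absolute_max")) {
  method <- match.arg(method)
  m <- as_expression_matrix(m)
  map <- as_tibble(map)
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(map)))
  map <- map[!is.na(map$gene_symbol) & map$gene_symbol != "", , drop = FALSE]
  map <- map[map$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(map) == 0) stop("no probe maps to any gene", call. = FALSE)
  score <- if (method == "mean") {
    rowMeans(m[map$probe_id, , drop = FALSE], na.rm = TRUE)
  } else {
    apply(m[map$probe_id, , drop = FALSE], 1, max, na.rm = TRUE)
  }
  sym <- toupper(map$gene_symbol)
  # per gene, keep the best-scoring probe; break ties on probe id for determinism
  ord <- order(sym, -score, map$probe_id)
  keep <- !duplicated(sym[ord])
  probes <- map$probe_id[ord][keep]
  genes <- sym[ord][keep]
  out <- m[probes, , drop = FALSE]
  rownames(out) <- genes
  out <- out[order(rownames(out)), , drop = FALSE]
  as_expression_matrix(out, cohort = cohort_name(m))
}

#' Remove genes and samples with excessive missingness or no variance
#'
#' One gene pass followed by one sample pass: genes whose missing fraction
#' exceeds `max_gene_missing` or whose variance (missing values ignored) is
#' at most `min_variance` are removed first, then samples whose missing
#' fraction exceeds `max_sample_missing`.
#'
#' @param m expression matrix.
#' @param max_gene_missing,max_sample_missing maximum tolerated missing
#'   fraction, in `[0, 1)`.
#' @param min_variance genes with variance `<=` this are dropped.
#' @return filtered matrix; the removal counts are attached as the
#'   `filter_report` attribute (a tibble).
#' @export
filter_missing <- function(m, max_gene_missing = 0.5, max_sample_missing = 0.5,
                           min_variance = 1e-10) {
  stopifnot(max_gene_missing >= 0, max_gene_missing < 1,
            max_sample_missing >= 0, max_sample_missing < 1, min_variance >= 0)
  m <- as_expression_matrix(m)
  gene_miss <- rowMeans(is.na(m))
  gene_var <- apply(m, 1, var, na.rm = TRUE)
  bad_miss <- gene_miss > max_gene_missing
  bad_var <- is.na(gene_var) | gene_var <= min_variance
  kept <- m[!(bad_miss | bad_var), , drop = FALSE]
  if (nrow(kept) == 0) {
    stop(sprintf("all %d genes removed (%d excessive missingness, %d low variance)",
                 nrow(m), sum(bad_miss), sum(bad_var)), call. = FALSE)
  }
  sample_miss <- colMeans(is.na(kept))
  bad_sample <- sample_miss > max_sample_missing
  kept <- kept[, !bad_sample, drop = FALSE]
  report <- tibble(
    step = c("genes_missing", "genes_low_variance", "samples_missing"),
    removed = c(sum(bad_miss & !bad_var), sum(bad_var), sum(bad_sample))
  )
  out <- as_expression_matrix(kept, cohort = cohort_name(m))
  attr(out, "filter_report") <- report
  out
}

#' Restrict cohorts to their common genes
#'
#' Gene symbols are upper-cased, intersected across all cohorts, and every
#' matrix is returned with the shared genes in identical order.
#'
#' @param cohorts list of gene-keyed expression matrices.
#' @return list of matrices over the common gene set, same order everywhere.
#' @export
align_cohorts <- function(cohorts) {
  cohorts <- as_cohort_list(cohorts)
  if (length(cohorts) < 2) stop("need at least two cohorts to align", call. = FALSE)
  cohorts <- lapply(cohorts, function(m) {
    rownames(m) <- toupper(rownames(m))
    if (anyDuplicated(rownames(m))) stop("duplicate gene symbols after case normalisation", call. = FALSE)
    m
  })
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(common) == 0) stop("no genes shared by all cohorts", call. = FALSE)
  common <- sort(common)
  out <- lapply(cohorts, function(m) {
    as_expression_matrix(m[common, , drop = FALSE], cohort = cohort_name(m))
  })
  names(out) <- names(cohorts)
  out
}

#' Write an expression matrix as TSV
#'
#' @param m expression matrix.
#' @param path output path; first column `gene_id`, header = sample ids.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  m <- as_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
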