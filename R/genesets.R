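#' Construct a curated gene set
#'
#' Gene symbols are upper-cased and de-duplicated.
#'
#' @param name set name.
#' @param genes character vector of gene symbols (non-empty).
#' @param category free-text category (e.g. secretome, known-disease, GWA,
#'   cell-marker, DE).
#' @param provenance optional character vector recording parent sets.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, category = "custom", provenance = NULL) {
  genes <- unique(toupper(genes[!is.na(genes) & genes != ""]))
  if (length(genes) == 0) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, genes = genes, category = category,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "' (", x$category, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @param category category assigned to every set.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path, category = "custom") {
  sets <- fgsea::gmtPathways(path)
  lapply(setNames(names(sets), names(sets)), function(nm) {
    gene_set(nm, sets[[nm]], category = category)
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$category, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain one-symbol-per-line gene list
#'
#' @param path file path.
#' @param name set name (default: file stem).
#' @param category category label.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL, category = "custom") {
  genes <- trimws(readLines(path, warn = FALSE))
  gene_set(name %||% sub("\\.[^.]*$", "", basename(path)), genes,
           category = category)
}

#' Set algebra on gene sets
#'
#' @param a,b [gene_set()] objects (or character vectors).
#' @param mode `"intersection"` or `"difference"` (a minus b).
#' @return a [gene_set()] carrying both parents in its provenance; may be
#'   empty (then it has zero genes and `print` reports so).
#' @export
intersect_gene_sets <- function(a, b, mode = c("intersection", "difference")) {
  mode <- match.arg(mode)
  if (is.character(a)) a <- gene_set("query", a)
  if (is.character(b)) b <- gene_set("target", b)
  genes <- switch(mode,
                  intersection = intersect(a$genes, b$genes),
                  difference = setdiff(a$genes, b$genes))
  op <- if (mode == "intersection") "&" else "-"
  structure(list(name = paste(a$name, op, b$name),
                 genes = genes,
                 category = paste(a$category, b$category, sep = "/"),
                 provenance = c(a$name, b$name)),
            class = "gene_set")
}

#' Hypergeometric over-representation of gene sets
#'
#' For each target set, with universe size `N`, `K` target genes in the
#' universe, `n` query genes and `k` overlapping genes, the one-sided
#' enrichment p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`;
#' p-values are Benjamini-Hochberg adjusted across targets. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query a [gene_set()] or character vector.
#' @param targets list of [gene_set()] objects.
#' @param universe a [gene_set()] or character vector of background genes.
#' @return tibble: `query`, `target`, `universe_size`, `target_size`,
#'   `query_size`, `overlap_size`, `p_value`, `adj_p`, `overlap_genes`
#'   (semicolon-joined).
#' @export
hypergeometric_enrichment <- function(query, targets, universe) {
  if (is.character(query)) query <- gene_set("query", query)
  if (is.character(universe)) universe <- gene_set("universe", universe)
  if (inherits(targets, "gene_set")) targets <- list(targets)
  uni <- universe$genes
  if (length(uni) == 0) stop("empty universe", call. = FALSE)
  q <- intersect(query$genes, uni)
  if (length(q) < length(query$genes)) {
    warning(length(query$genes) - length(q), " query gene(s) outside the universe dropped")
  }
  out <- purrr::map_dfr(targets, function(tg) {
    tgt <- intersect(tg$genes, uni)
    ov <- intersect(q, tgt)
    k <- length(ov)
    p <- phyper(k - 1, length(tgt), length(uni) - length(tgt), length(q),
                lower.tail = FALSE)
    tibble(query = query$name, target = tg$name,
           universe_size = length(uni), target_size = length(tgt),
           query_size = length(q), overlap_size = k,
           p_value = p, overlap_genes = paste(sort(ov), collapse = ";"))
  })
  out$adj_p <- bh_adjust(out$p_value)
  out[, c("query", "target", "universe_size", "target_size", "query_size",
          "overlap_size", "p_value", "adj_p", "overlap_genes")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Filter a single-cell marker table into per-cell-type gene sets
#'
#' Rows passing `fdr <= fdr_max` and `|logfc| >= logfc_min` are kept. When
#' the table contains both signs of fold change, up- and down-regulated
#' markers become separate sets (`<cell_type>_up` / `<cell_type>_down`).
#'
#' @param markers data frame with columns `cell_type`, `gene`, `fdr`,
#'   `logfc`.
#' @param fdr_max,logfc_min retention thresholds (defaults 0.05 and 0.5).
#' @return named list of [gene_set()] objects (empty, with a warning, when
#'   nothing passes).
#' @export
filter_marker_sets <- function(markers, fdr_max = 0.05, logfc_min = 0.5) {
  markers <- as_tibble(markers)
  stopifnot(all(c("cell_type", "gene", "fdr", "logfc") %in% names(markers)))
  kept <- markers |>
    filter(.data$fdr <= fdr_max, abs(.data$logfc) >= logfc_min)
  if (nrow(kept) == 0) {
    warning("no marker rows pass the thresholds")
    return(list())
  }
  split_signs <- any(kept$logfc < 0) && any(kept$logfc > 0)
  kept <- kept |>
    mutate(set_name = if (split_signs) {
      paste0(.data$cell_type, ifelse(.data$logfc >= 0, "_up", "_down"))
    } else .data$cell_type)
  sets <- split(kept$gene, kept$set_name)
  lapply(setNames(names(sets), names(sets)), function(nm) {
    gene_set(nm, sets[[nm]], category = "cell-marker")
  })
}
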