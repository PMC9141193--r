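#' Compute module eigengenes per cohort
#'
#' Per cohort and module, member genes are standardised (mean 0, sd 1;
#' residual missing values imputed at 0 after centering) and the first right
#' singular vector of the member x sample matrix is taken. The sign is
#' oriented so the eigengene correlates non-negatively with the module's mean
#' standardised expression, and the vector is rescaled to unit variance.
#' `var_explained` is the first squared singular value over the total.
#'
#' @param assignment tibble with columns `gene_id`, `module` ("grey" =
#'   unassigned, skipped).
#' @param cohorts list of expression matrices containing the assigned genes.
#' @return object of class `module_eigengenes`: `eigengenes` is a named list
#'   (per cohort) of sample x module matrices; `var_explained` a tibble.
#' @export
compute_eigengenes <- function(assignment, cohorts) {
  assignment <- as_tibble(assignment)
  stopifnot(all(c("gene_id", "module") %in% names(assignment)))
  cohorts <- as_cohort_list(cohorts)
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0) stop("no assigned modules", call. = FALSE)
  ve <- list()
  eg <- lapply(names(cohorts), function(cn) {
    m <- cohorts[[cn]]
    out <- sapply(mods, function(mod) {
      genes <- intersect(assignment$gene_id[assignment$module == mod], rownames(m))
      if (length(genes) == 0) stop("module ", mod, " has no genes in cohort ", cn, call. = FALSE)
      e <- module_eigengene(m[genes, , drop = FALSE])
      ve[[paste(cn, mod)]] <<- tibble(cohort = cn, module = mod,
                                      var_explained = attr(e, "var_explained"))
      e
    })
    rownames(out) <- colnames(m)
    out
  })
  names(eg) <- names(cohorts)
  structure(list(eigengenes = eg, var_explained = bind_rows(ve)),
            class = "module_eigengenes")
}

# first right singular vector of the standardised member x sample matrix
module_eigengene <- function(x) {
  z <- standardise_rows(x)
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  avg <- colMeans(z)
  if (sum(e * avg) < 0) e <- -e
  s <- sd(e)
  if (s > 0) e <- e / s
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  e
}

standardise_rows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  z <- (x - mu) / s
  z[is.na(z)] <- 0
  z
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat("Module eigengenes:", ncol(x$eigengenes[[1]]), "modules x",
      length(x$eigengenes), "cohorts\n")
  print(x$var_explained)
  invisible(x)
}

#' Detect consensus modules from a consensus TOM
#'
#' Average-linkage hierarchical clustering of `1 - consensusTOM`, static cut
#' at `cut_height_fraction` of the maximum merge height; branches of at least
#' `min_module_size` genes become modules, labelled by decreasing size along
#' the conventional colour sequence. Module membership is then validated by
#' consensus kME (minimum across cohorts of the correlation with a module's
#' eigengene): branch members whose kME to their own module does not exceed
#' `kme_rescue_threshold` are demoted, and every unassigned gene (demoted or
#' off-branch) is rescued into the module of its maximal consensus kME when
#' that exceeds the threshold; otherwise it stays "grey". The symmetric kME
#' step keeps weakly attached bystander genes out of modules while bringing
#' in genuine members that fell off the static branches.
#'
#' @param ct a [consensus_tom()] object or a plain consensus TOM matrix.
#' @param cohorts list of aligned expression matrices (for kME rescue).
#' @param min_module_size minimum branch size, >= 3.
#' @param cut_height_fraction static cut as a fraction of the maximum merge
#'   height, in `(0, 1]`.
#' @param kme_rescue_threshold consensus kME needed to rescue a gene.
#' @return object of class `module_detection` with `dendrogram` (hclust),
#'   `assignment` (tibble `gene_id`, `module`), `cut_height`.
#' @export
detect_modules <- function(ct, cohorts, min_module_size = 30,
                           cut_height_fraction = 0.99,
                           kme_rescue_threshold = 0.3) {
  stopifnot(min_module_size >= 3, cut_height_fraction > 0, cut_height_fraction <= 1)
  cons <- consensus_matrix(ct)
  if (nrow(cons) == 0) stop("empty consensus TOM", call. = FALSE)
  cohorts <- as_cohort_list(cohorts)
  genes <- rownames(cons)
  stopifnot(!is.null(genes), all(genes %in% rownames(cohorts[[1]])))
  hc <- hclust(as.dist(1 - cons), method = "average")
  h_cut <- cut_height_fraction * max(hc$height)
  cl <- cutree(hc, h = h_cut)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  assignment <- tibble(gene_id = genes, module = "grey")
  if (length(big) > 0) {
    # label by decreasing size; ties broken by the first gene id in the branch
    first_gene <- vapply(big, function(b) min(genes[cl == b]), character(1))
    ord <- big[order(-sizes[big], first_gene)]
    labels <- module_labels_for(length(ord))
    for (i in seq_along(ord)) {
      assignment$module[cl == as.integer(ord[i])] <- labels[i]
    }
    me <- compute_eigengenes(assignment, cohorts)
    kme <- consensus_kme_matrix(assignment$gene_id, me, cohorts)
    # demote branch members that are not coherent with their own module
    in_module <- assignment$module != "grey"
    own <- kme[cbind(which(in_module),
                     match(assignment$module[in_module], colnames(kme)))]
    assignment$module[in_module][own <= kme_rescue_threshold] <- "grey"
    # rescue unassigned genes by their best consensus kME
    unassigned <- which(assignment$module == "grey")
    best <- max.col(kme[unassigned, , drop = FALSE], ties.method = "first")
    best_val <- kme[cbind(unassigned, best)]
    rescue <- best_val > kme_rescue_threshold
    assignment$module[unassigned[rescue]] <- colnames(kme)[best[rescue]]
  }
  structure(
    list(dendrogram = hc, assignment = assignment, cut_height = h_cut,
         min_module_size = min_module_size,
         kme_rescue_threshold = kme_rescue_threshold),
    class = "module_detection"
  )
}

# consensus (min across cohorts) signed correlation of each gene with each
# module eigengene; genes x modules
consensus_kme_matrix <- function(genes, me, cohorts) {
  per <- lapply(names(cohorts), function(cn) {
    safe_cor(t(cohorts[[cn]][genes, , drop = FALSE]), me$eigengenes[[cn]])
  })
  out <- Reduce(pmin, per)
  out[is.na(out)] <- 0
  rownames(out) <- genes
  out
}

#' @export
print.module_detection <- function(x, ...) {
  tab <- sort(table(x$assignment$module), decreasing = TRUE)
  cat("Detected", sum(names(tab) != "grey"), "modules (cut height",
      signif(x$cut_height, 4), "):\n")
  print(tab)
  invisible(x)
}

#' @export
tidy.module_detection <- function(x, ...) x$assignment

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair whose consensus eigengene correlation
#' (minimum across cohorts) is highest, while it exceeds `merge_cor`;
#' eigengenes are recomputed after every merge. Final labels are reassigned
#' by decreasing module size, so the result is a fixed point of the
#' operation.
#'
#' @param assignment tibble `gene_id`, `module`, or a `module_detection`.
#' @param cohorts list of aligned expression matrices.
#' @param merge_cor merge threshold in `(0, 1)`.
#' @return tibble `gene_id`, `module`.
#' @export
merge_modules <- function(assignment, cohorts, merge_cor = 0.75) {
  stopifnot(merge_cor > 0, merge_cor < 1)
  if (inherits(assignment, "module_detection")) assignment <- assignment$assignment
  assignment <- as_tibble(assignment)
  cohorts <- as_cohort_list(cohorts)
  repeat {
    mods <- setdiff(unique(assignment$module), "grey")
    if (length(mods) < 2) break
    me <- compute_eigengenes(assignment, cohorts)
    cons <- Reduce(pmin, lapply(me$eigengenes, function(e) safe_cor(e[, mods, drop = FALSE])))
    diag(cons) <- -Inf
    top <- which(cons == max(cons), arr.ind = TRUE)[1, ]
    if (cons[top[1], top[2]] <= merge_cor) break
    a <- mods[top[1]]; b <- mods[top[2]]
    sizes <- table(assignment$module)
    keep <- if (sizes[a] >= sizes[b]) a else b
    drop <- setdiff(c(a, b), keep)
    assignment$module[assignment$module == drop] <- keep
  }
  relabel_by_size(assignment)
}

relabel_by_size <- function(assignment) {
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0) return(assignment)
  sizes <- table(factor(assignment$module, levels = mods))
  first_gene <- vapply(mods, function(m) min(assignment$gene_id[assignment$module == m]), character(1))
  ord <- mods[order(-as.integer(sizes[mods]), first_gene)]
  labels <- setNames(module_labels_for(length(ord)), ord)
  assignment$module <- ifelse(assignment$module == "grey", "grey",
                              labels[assignment$module])
  assignment
}
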