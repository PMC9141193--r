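#' Permutation Zsummary module preservation
#'
#' For every reference module, density statistics (mean intramodular
#' adjacency, mean intramodular correlation, eigengene variance explained,
#' mean |kME|) are computed in the test cohort, and connectivity statistics
#' (correlation between reference and test of intramodular connectivity kIM,
#' of kME, and of the gene-gene correlation pattern) compare the module's
#' wiring across cohorts. A null distribution is built from `n_permutations`
#' random gene sets of the same size drawn from the test-cohort gene universe
#' excluding the module; each statistic is standardised against its null,
#' `Zdensity` and `Zconnectivity` are the medians of their groups and
#' `Zsummary` their mean. Conventional classes: `< 2` none, `2-10` moderate,
#' `>= 10` strong.
#'
#' @param reference reference-cohort expression matrix.
#' @param assignment tibble `gene_id`, `module` for the reference network
#'   (or a `module_detection` object).
#' @param test test-cohort expression matrix.
#' @param n_permutations number of null gene sets, >= 20.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param mode,power network type used for the adjacency-based statistics.
#' @param min_prop_present skip (with a warning) modules with a smaller
#'   fraction of their genes present in the test cohort.
#' @return tibble, one row per module: observed statistics, per-group Z
#'   scores, `zsummary`, `preservation` class, `n_genes`, `n_permutations`,
#'   `seed`.
#' @export
module_preservation <- function(reference, assignment, test,
                                n_permutations = 100, seed = 42,
                                mode = "signed", power = 6,
                                min_prop_present = 0.5) {
  stopifnot(n_permutations >= 20)
  if (inherits(assignment, "module_detection")) assignment <- assignment$assignment
  assignment <- as_tibble(assignment)
  reference <- as_expression_matrix(reference)
  test <- as_expression_matrix(test)
  universe <- intersect(rownames(reference), rownames(test))
  mods <- setdiff(unique(assignment$module), "grey")
  withr::with_seed(seed, {
    purrr::map_dfr(sort(mods), function(mod) {
      genes_all <- assignment$gene_id[assignment$module == mod]
      genes <- intersect(genes_all, universe)
      if (length(genes) < max(3, min_prop_present * length(genes_all))) {
        warning("module ", mod, " insufficiently present in the test cohort; skipped")
        return(NULL)
      }
      obs <- preservation_stats(reference, test, genes, mode, power)
      pool <- setdiff(universe, genes)
      null <- vapply(seq_len(n_permutations), function(i) {
        preservation_stats(reference, test, sample(pool, length(genes)), mode, power)
      }, numeric(length(obs)))
      mu <- rowMeans(null)
      sdv <- apply(null, 1, sd)
      z <- (obs - mu) / sdv
      z_density <- median(z[1:4])
      z_connectivity <- median(z[5:7])
      zsummary <- mean(c(z_density, z_connectivity))
      tibble(
        module = mod, n_genes = length(genes),
        mean_adjacency = obs[["mean_adjacency"]],
        mean_correlation = obs[["mean_correlation"]],
        var_explained = obs[["var_explained"]],
        mean_kme = obs[["mean_kme"]],
        cor_kim = obs[["cor_kim"]], cor_kme = obs[["cor_kme"]],
        cor_cor = obs[["cor_cor"]],
        z_density = z_density, z_connectivity = z_connectivity,
        zsummary = zsummary,
        preservation = classify_preservation(zsummary),
        n_permutations = n_permutations, seed = seed
      )
    })
  })
}

# the 7 preservation statistics for one gene set; order matters (4 density
# then 3 connectivity)
preservation_stats <- function(reference, test, genes, mode, power) {
  ref <- reference[genes, , drop = FALSE]
  tst <- test[genes, , drop = FALSE]
  c_ref <- cor_for_network(ref)
  c_tst <- cor_for_network(tst)
  a_ref <- adjacency_from_cor(c_ref, mode = mode, power = power)
  a_tst <- adjacency_from_cor(c_tst, mode = mode, power = power)
  e_tst <- module_eigengene(tst)
  kme_tst <- as.vector(safe_cor(t(tst), e_tst))
  e_ref <- module_eigengene(ref)
  kme_ref <- as.vector(safe_cor(t(ref), e_ref))
  kim_ref <- rowSums(a_ref)
  kim_tst <- rowSums(a_tst)
  c(
    mean_adjacency = mean(upper_tri_values(a_tst)),
    mean_correlation = mean(upper_tri_values(c_tst)),
    var_explained = attr(e_tst, "var_explained"),
    mean_kme = mean(abs(kme_tst), na.rm = TRUE),
    cor_kim = zero_safe_cor(kim_ref, kim_tst),
    cor_kme = zero_safe_cor(kme_ref, kme_tst),
    cor_cor = zero_safe_cor(upper_tri_values(c_ref), upper_tri_values(c_tst))
  )
}

zero_safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Classify a Zsummary preservation score
#'
#' `z < 2` = "none", `2 <= z < 10` = "moderate", `z >= 10` = "strong".
#'
#' @param z numeric vector of Zsummary values (finite).
#' @return character vector of classes.
#' @export
classify_preservation <- function(z) {
  if (any(!is.finite(z))) stop("non-finite Zsummary", call. = FALSE)
  dplyr::case_when(z < 2 ~ "none", z < 10 ~ "moderate", TRUE ~ "strong")
}
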