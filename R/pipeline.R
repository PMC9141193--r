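#' Assemble a pipeline configuration
#'
#' Bundles the tunable parameters of the full consensus analysis with their
#' defaults: signed network, automatic soft power (candidates 1-10, target
#' fit 0.8), TOM calibration quantile 0.95, static tree cut at 0.99 of the
#' maximum merge height with minimum module size 30 and kME rescue at 0.3,
#' eigengene merge correlation 0.75, candidate thresholds |r| >= 0.5 and
#' adjusted p <= 0.05, hub percentile 0.95, 100 preservation permutations,
#' elastic-net alpha 0.35 with 5-fold CV and 100 label permutations.
#'
#' @param ... overrides for any default listed above.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "signed", power = "auto", powers = 1:10, target_r2 = 0.8,
    cor_method = "pearson", calibration_quantile = 0.95,
    max_gene_missing = 0.5, max_sample_missing = 0.5, min_variance = 1e-10,
    min_module_size = 30, cut_height_fraction = 0.99,
    kme_rescue_threshold = 0.3, merge_cor = 0.75,
    cor_threshold = 0.5, p_threshold = 0.05, module_p_method = "fisher",
    hub_quantile = 0.95, hub_score_method = "product",
    preservation_permutations = 100,
    alpha = 0.35, cv_folds = 5, classifier_permutations = 100
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full consensus co-expression pipeline
#'
#' Stages, in order: `preprocess` (missingness filter and common-gene
#' alignment), `network` (per-cohort adjacency and TOM, quantile calibration,
#' consensus TOM), `modules` (detection, eigengene merging, eigengenes),
#' `traits` (candidate-module selection, gene significance, kME, HubScore,
#' hub selection), `preservation` (Zsummary of every module in each test
#' cohort, when test cohorts are supplied), `genesets` (hub triage against
#' curated sets: novel = hubs minus known-disease, secreted = hubs
#' intersected with secretome, plus hypergeometric enrichment of hubs in
#' every supplied set), and `classify` (elastic-net panel on the hub genes
#' of the first cohort with permutation PRAUC significance). All artifacts
#' are written as TSV under `out_dir` together with a `manifest.tsv` of md5
#' digests and the full parameter set as JSON, so a rerun with the same
#' inputs and seed reproduces identical digests.
#'
#' @param cohorts named list of gene x sample expression matrices (training
#'   cohorts).
#' @param traits list of trait tibbles aligned to `cohorts`.
#' @param test_cohorts optional named list of expression matrices for module
#'   preservation.
#' @param gene_sets optional named list of [gene_set()] objects; names
#'   `known_disease` and `secretome` get the dedicated triage treatment.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param seed single integer seed driving every stochastic stage.
#' @param config a [pipeline_config()] list.
#' @param stop_after optional stage name; later stages are skipped.
#' @return object of class `conexus_pipeline`: a list with one element per
#'   executed stage plus `manifest`.
#' @export
run_pipeline <- function(cohorts, traits, test_cohorts = NULL,
                         gene_sets = NULL, out_dir = NULL, seed = 42,
                         config = pipeline_config(), stop_after = NULL) {
  stages <- c("preprocess", "network", "modules", "traits", "preservation",
              "genesets", "classify")
  if (!is.null(stop_after)) stop_after <- match.arg(stop_after, stages)
  res <- list(config = config, seed = seed)
  artifacts <- list()
  reached <- function(stage) {
    is.null(stop_after) || match(stage, stages) <= match(stop_after, stages)
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("[conexus:%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  # preprocess
  run_stage("preprocess", function() {
    cohorts <- as_cohort_list(cohorts)
    cohorts <- lapply(cohorts, filter_missing,
                      max_gene_missing = config$max_gene_missing,
                      max_sample_missing = config$max_sample_missing,
                      min_variance = config$min_variance)
    cohorts <- align_cohorts(cohorts)
    for (nm in names(cohorts)) {
      validate_trait_table(traits[[nm]] %||% traits[[match(nm, names(cohorts))]],
                           cohorts[[nm]])
    }
    res$cohorts <<- cohorts
    artifacts$genes_aligned <<- tibble(gene_id = rownames(cohorts[[1]]))
  })
  if (reached("network")) {
    run_stage("network", function() {
      ct <- build_consensus_tom(res$cohorts, mode = config$mode,
                                power = config$power, powers = config$powers,
                                target_r2 = config$target_r2,
                                cor_method = config$cor_method,
                                q = config$calibration_quantile)
      res$consensus <<- ct
      artifacts$network_summary <<- tibble(
        cohort = names(ct$per_cohort), power = attr(ct, "power"),
        mode = attr(ct, "mode"),
        calibration_exponent = unname(ct$calibration_exponents))
    })
  }
  if (reached("modules")) {
    run_stage("modules", function() {
      det <- detect_modules(res$consensus, res$cohorts,
                            min_module_size = config$min_module_size,
                            cut_height_fraction = config$cut_height_fraction,
                            kme_rescue_threshold = config$kme_rescue_threshold)
      assignment <- merge_modules(det, res$cohorts, merge_cor = config$merge_cor)
      res$detection <<- det
      res$assignment <<- assignment
      res$eigengenes <<- compute_eigengenes(assignment, res$cohorts)
      artifacts$module_assignment <<- assignment
      artifacts$var_explained <<- res$eigengenes$var_explained
    })
  }
  if (reached("traits") && !is.null(res$assignment)) {
    run_stage("traits", function() {
      report <- select_candidate_modules(res$eigengenes, traits,
                                         cor_threshold = config$cor_threshold,
                                         p_threshold = config$p_threshold,
                                         method = config$module_p_method)
      gs <- gene_significance(res$cohorts, traits)
      mm <- module_membership(res$assignment, res$eigengenes, res$cohorts)
      hubs <- hub_score(mm, gs, method = config$hub_score_method) |>
        select_hubs(q = config$hub_quantile)
      res$candidates <<- report
      res$gene_significance <<- gs
      res$membership <<- mm
      res$hubs <<- hubs
      artifacts$module_trait_tests <<- report$tests
      artifacts$hub_table <<- hubs
    })
  }
  if (reached("preservation") && !is.null(res$assignment) && length(test_cohorts %||% list()) > 0) {
    run_stage("preservation", function() {
      test_cohorts <- as_cohort_list(test_cohorts)
      res$preservation <<- purrr::map_dfr(names(test_cohorts), function(tn) {
        module_preservation(res$cohorts[[1]], res$assignment, test_cohorts[[tn]],
                            n_permutations = config$preservation_permutations,
                            seed = seed, mode = config$mode,
                            power = attr(res$consensus, "power")) |>
          mutate(test_cohort = tn)
      })
      artifacts$preservation <<- res$preservation
    })
  }
  if (reached("genesets") && !is.null(res$hubs) && length(gene_sets %||% list()) > 0) {
    run_stage("genesets", function() {
      cand <- if (length(res$candidates$selected) > 0) res$candidates$selected
              else unique(res$hubs$module)
      hub_genes <- res$hubs$gene_id[res$hubs$is_hub & res$hubs$module %in% cand]
      hub_set <- gene_set("consensus_hubs", hub_genes, category = "hubs")
      universe <- gene_set("aligned_genes", rownames(res$cohorts[[1]]))
      triage <- list()
      if (!is.null(gene_sets$known_disease)) {
        triage$novel_candidates <-
          intersect_gene_sets(hub_set, gene_sets$known_disease, "difference")
      }
      if (!is.null(gene_sets$secretome)) {
        triage$secreted_hubs <-
          intersect_gene_sets(hub_set, gene_sets$secretome, "intersection")
      }
      res$hub_set <<- hub_set
      res$triage <<- triage
      res$enrichment <<- hypergeometric_enrichment(hub_set, gene_sets, universe)
      artifacts$enrichment <<- res$enrichment
    })
  }
  if (reached("classify") && !is.null(res$hubs)) {
    run_stage("classify", function() {
      cand <- if (length(res$candidates$selected) > 0) res$candidates$selected
              else unique(res$hubs$module)
      hub_genes <- res$hubs$gene_id[res$hubs$is_hub & res$hubs$module %in% cand]
      if (length(hub_genes) < 2) stop("fewer than two hub genes available as predictors")
      m <- res$cohorts[[1]]
      tt <- as_tibble(traits[[1]])
      tt <- tt[match(colnames(m), tt$sample_id), ]
      res$classifier <<- permutation_significance(
        t(m[hub_genes, , drop = FALSE]), tt$phenotype, alpha = config$alpha,
        n_permutations = config$classifier_permutations, seed = seed,
        cv_folds = config$cv_folds)
      artifacts$classifier <<- glance(res$classifier)
    })
  }

  res$manifest <- if (!is.null(out_dir)) {
    write_artifacts(artifacts, out_dir, config, seed)
  } else NULL
  structure(res, class = "conexus_pipeline")
}

write_artifacts <- function(artifacts, out_dir, config, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(artifacts)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(artifacts[[nm]], path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  params_path <- file.path(out_dir, "parameters.json")
  jsonlite::write_json(c(config, list(seed = seed)), params_path,
                       auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, params_path)
  manifest <- tibble(file = basename(paths),
                     md5 = unname(tools::md5sum(paths)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}

#' @export
print.conexus_pipeline <- function(x, ...) {
  cat("conexus pipeline run (seed", x$seed, ")\n")
  if (!is.null(x$cohorts)) {
    cat(" cohorts:", paste(names(x$cohorts), collapse = ", "), "-",
        nrow(x$cohorts[[1]]), "aligned genes\n")
  }
  if (!is.null(x$assignment)) {
    mods <- setdiff(unique(x$assignment$module), "grey")
    cat(" modules:", length(mods), "consensus modules\n")
  }
  if (!is.null(x$candidates)) {
    cat(" candidates:", paste(x$candidates$selected, collapse = ", "), "\n")
  }
  if (!is.null(x$hubs)) cat(" hubs:", sum(x$hubs$is_hub), "intramodular hub genes\n")
  if (!is.null(x$classifier)) {
    cat(" classifier: PRAUC", round(x$classifier$prauc, 3), ", permutation p",
        signif(x$classifier$permutation_p, 3), "\n")
  }
  invisible(x)
}
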