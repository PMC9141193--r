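#' Correlation with asymptotic p-value
#'
#' Pearson correlation over complete pairs with either Student's asymptotic
#' test (`t = r sqrt((n-2)/(1-r^2))`, df = n-2) or Fisher's z test
#' (`z = atanh(r) sqrt(n-3)`), both two-sided.
#'
#' @param x,y numeric vectors.
#' @param method `"student"` or `"fisher"`.
#' @return one-row tibble: `estimate`, `n`, `statistic`, `p_value`, `method`.
#' @export
correlation_test <- function(x, y, method = c("student", "fisher")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < ifelse(method == "student", 3, 4)) {
    stop("need at least ", ifelse(method == "student", 3, 4),
         " complete pairs", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  r <- cor(x, y)
  if (method == "student") {
    stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(stat), df = n - 2)
  } else {
    if (abs(r) >= 1 - 1e-12) {
      warning("|r| = 1: Fisher p-value is 0")
      stat <- sign(r) * Inf
      p <- 0
    } else {
      stat <- atanh(r) * sqrt(n - 3)
      p <- 2 * pnorm(-abs(stat))
    }
  }
  tibble(estimate = r, n = n, statistic = stat, p_value = p, method = method)
}

# long tibble of eigengene-trait correlations, one row per module x trait x cohort
module_trait_tests <- function(eigengenes, traits, method = "fisher") {
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  cohorts <- names(eigengenes$eigengenes)
  stopifnot(length(traits) == length(cohorts))
  if (is.null(names(traits))) names(traits) <- cohorts
  purrr::map_dfr(cohorts, function(cn) {
    me <- eigengenes$eigengenes[[cn]]
    tt <- as_tibble(traits[[cn]])
    tt <- tt[match(rownames(me), tt$sample_id), , drop = FALSE]
    trait_cols <- setdiff(names(tt), "sample_id")
    purrr::map_dfr(trait_cols, function(trait) {
      v <- tt[[trait]]
      if (sum(complete.cases(v)) < 4 || length(unique(v[!is.na(v)])) < 2) return(NULL)
      purrr::map_dfr(colnames(me), function(mod) {
        res <- correlation_test(me[, mod], v, method = method)
        tibble(module = mod, trait = trait, cohort = cn,
               r = res$estimate, n = res$n, p_value = res$p_value)
      })
    })
  })
}

#' Select candidate modules by trait correlation
#'
#' Correlates every module eigengene with the binary phenotype in each cohort
#' and with the continuous lung-function traits (`fvc`, `dlco`) in cohorts
#' where they exist. P-values (Fisher's asymptotic test by default) are
#' Benjamini-Hochberg adjusted per trait-cohort family across modules. A
#' module is selected when it passes `|r| >= cor_threshold` and adjusted
#' `p <= p_threshold` for the phenotype in every cohort and for every
#' available lung-function trait.
#'
#' @param eigengenes a [compute_eigengenes()] result.
#' @param traits list of trait tibbles, one per cohort, aligned by
#'   `sample_id` to the eigengene rows.
#' @param cor_threshold,p_threshold selection thresholds (defaults 0.5, 0.05).
#' @param method p-value method, `"fisher"` (default) or `"student"`.
#' @return object of class `candidate_module_report` with `tests` (tibble
#'   incl. `adj_p`, `pass`) and `selected` (character vector of modules).
#' @export
select_candidate_modules <- function(eigengenes, traits, cor_threshold = 0.5,
                                     p_threshold = 0.05,
                                     method = c("fisher", "student")) {
  method <- match.arg(method)
  tests <- module_trait_tests(eigengenes, traits, method = method)
  known <- c("phenotype", "fvc", "dlco")
  missing_traits <- setdiff(known, unique(tests$trait))
  if (length(missing_traits) > 0) {
    warning("trait(s) absent in all cohorts, skipped: ",
            paste(missing_traits, collapse = ", "))
  }
  tests <- tests |>
    group_by(.data$trait, .data$cohort) |>
    mutate(adj_p = bh_adjust(.data$p_value)) |>
    ungroup() |>
    mutate(pass = abs(.data$r) >= cor_threshold & .data$adj_p <= p_threshold)
  required <- tests |>
    filter(.data$trait %in% known) |>
    dplyr::distinct(.data$trait, .data$cohort)
  selected <- tests |>
    filter(.data$trait %in% known) |>
    group_by(.data$module) |>
    summarise(all_pass = all(.data$pass) && n() == nrow(required)) |>
    filter(.data$all_pass)
  structure(
    list(tests = tests, selected = sort(selected$module),
         cor_threshold = cor_threshold, p_threshold = p_threshold,
         method = method),
    class = "candidate_module_report"
  )
}

#' @export
print.candidate_module_report <- function(x, ...) {
  cat("Candidate modules (|r| >=", x$cor_threshold, ", adj p <=",
      x$p_threshold, "):",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @export
tidy.candidate_module_report <- function(x, ...) x$tests

#' @export
glance.candidate_module_report <- function(x, ...) {
  tibble(n_modules = length(unique(x$tests$module)),
         n_selected = length(x$selected),
         cor_threshold = x$cor_threshold, p_threshold = x$p_threshold,
         method = x$method)
}

#' Trait-based gene significance
#'
#' GS = Pearson correlation of each gene's expression with each trait
#' (binary phenotype as 0/1, i.e. point-biserial), per cohort, over pairwise
#' complete observations, with Student's asymptotic p-value. Traits missing
#' in a cohort contribute no rows; genes with < 3 complete pairs get NA.
#'
#' @param cohorts list of expression matrices.
#' @param traits list of trait tibbles aligned to the cohorts.
#' @return tibble: `gene_id`, `cohort`, `trait`, `gs`, `n`, `p_value`.
#' @export
gene_significance <- function(cohorts, traits) {
  cohorts <- as_cohort_list(cohorts)
  stopifnot(length(traits) == length(cohorts))
  if (is.null(names(traits))) names(traits) <- names(cohorts)
  purrr::map_dfr(names(cohorts), function(cn) {
    m <- cohorts[[cn]]
    tt <- as_tibble(traits[[cn]])
    tt <- tt[match(colnames(m), tt$sample_id), , drop = FALSE]
    trait_cols <- setdiff(names(tt), "sample_id")
    purrr::map_dfr(trait_cols, function(trait) {
      v <- tt[[trait]]
      n_ok <- colSums(!is.na(v) & !is.na(t(m)))
      if (max(n_ok) < 3 || length(unique(v[!is.na(v)])) < 2) return(NULL)
      gs <- as.vector(safe_cor(t(m), v))
      gs[n_ok < 3] <- NA_real_
      stat <- gs * sqrt((n_ok - 2) / pmax(1 - gs^2, .Machine$double.eps))
      tibble(gene_id = rownames(m), cohort = cn, trait = trait, gs = gs,
             n = as.integer(n_ok), p_value = 2 * pt(-abs(stat), df = pmax(n_ok - 2, 1)))
    })
  })
}

#' Module membership (kME)
#'
#' Per cohort, kME is the correlation of a gene with its own module's
#' eigengene. The consensus kME is the entry of smallest magnitude across
#' cohorts when all cohorts agree in sign, and 0 otherwise.
#'
#' @param assignment tibble `gene_id`, `module` (or `module_detection`).
#' @param eigengenes a [compute_eigengenes()] result.
#' @param cohorts list of expression matrices.
#' @return tibble: `gene_id`, `module`, one `kme_<cohort>` column per cohort,
#'   `consensus_kme`. Grey genes are omitted.
#' @export
module_membership <- function(assignment, eigengenes, cohorts) {
  if (inherits(assignment, "module_detection")) assignment <- assignment$assignment
  assignment <- as_tibble(assignment)
  cohorts <- as_cohort_list(cohorts)
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  assigned <- assignment |> filter(.data$module != "grey")
  kme_cols <- lapply(names(cohorts), function(cn) {
    m <- cohorts[[cn]]
    me <- eigengenes$eigengenes[[cn]]
    vapply(seq_len(nrow(assigned)), function(i) {
      safe_cor(m[assigned$gene_id[i], ], me[, assigned$module[i]])
    }, numeric(1))
  })
  names(kme_cols) <- paste0("kme_", names(cohorts))
  out <- bind_rows(assigned)
  for (nm in names(kme_cols)) out[[nm]] <- kme_cols[[nm]]
  kmat <- as.matrix(out[names(kme_cols)])
  out$consensus_kme <- apply(kmat, 1, consensus_signed_min)
  out
}

# value of smallest magnitude when all signs agree, else 0
consensus_signed_min <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  if (length(unique(sign(v[v != 0]))) > 1 || any(v == 0)) return(0)
  v[which.min(abs(v))]
}

#' HubScore: combined connectivity- and trait-based gene importance
#'
#' The default score is the product of the absolute consensus kME and the
#' mean absolute gene significance over all available trait measurements
#' (phenotype per cohort plus each lung-function trait where recorded), so it
#' lies in `[0, 1]`. Alternatives: `"mean"` averages the two components;
#' `"rank"` averages their within-module percentile ranks.
#'
#' @param membership a [module_membership()] table.
#' @param significance a [gene_significance()] table.
#' @param method `"product"` (default), `"mean"` or `"rank"`.
#' @return tibble: `gene_id`, `module`, `consensus_kme`, `mean_abs_gs`,
#'   `hub_score`. Genes without any GS value are dropped with a warning.
#' @export
hub_score <- function(membership, significance, method = c("product", "mean", "rank")) {
  method <- match.arg(method)
  gs_summary <- significance |>
    filter(!is.na(.data$gs)) |>
    group_by(.data$gene_id) |>
    summarise(mean_abs_gs = mean(abs(.data$gs)), n_traits = n())
  out <- membership |>
    select("gene_id", "module", "consensus_kme") |>
    left_join(gs_summary, by = "gene_id")
  if (anyNA(out$mean_abs_gs)) {
    warning(sum(is.na(out$mean_abs_gs)),
            " gene(s) without gene significance excluded from hub ranking")
    out <- out |> filter(!is.na(.data$mean_abs_gs))
  }
  out <- switch(method,
    product = out |> mutate(hub_score = abs(.data$consensus_kme) * .data$mean_abs_gs),
    mean = out |> mutate(hub_score = (abs(.data$consensus_kme) + .data$mean_abs_gs) / 2),
    rank = out |>
      group_by(.data$module) |>
      mutate(hub_score = (rank(abs(.data$consensus_kme)) + rank(.data$mean_abs_gs)) /
               (2 * n())) |>
      ungroup()
  )
  out
}

#' Flag intramodular hubs at a score percentile
#'
#' Within each module, genes whose HubScore is at least the
#' linear-interpolation `q`-quantile of that module's scores are flagged as
#' hubs; ties at the threshold are all included, and small modules always
#' yield at least their top-scoring gene.
#'
#' @param hubs a [hub_score()] table.
#' @param q percentile threshold in `(0, 1)` (default 0.95, i.e. top 5%).
#' @return the input with logical `is_hub` and `hub_quantile` columns.
#' @export
select_hubs <- function(hubs, q = 0.95) {
  stopifnot(q > 0, q < 1)
  hubs |>
    group_by(.data$module) |>
    mutate(is_hub = .data$hub_score >= quantile(.data$hub_score, q),
           hub_quantile = q) |>
    ungroup()
}
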