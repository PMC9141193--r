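#' Define the ground truth for a synthetic multi-cohort study
#'
#' The generator follows a gene-level factor model: each planted module m has
#' a latent eigengene score per sample, and member gene g is
#' `x_g = rho_g * ME_m + sqrt(1 - rho_g^2) * noise`, so two members have
#' expected correlation `rho_i * rho_j`. Background genes are pure noise.
#' Shared modules appear in every cohort; cohort-specific modules appear only
#' in their cohort (their genes are background elsewhere). Trait-coupled
#' modules additionally load on a single latent disease-severity factor
#' (`latent_loading`), which anti-correlates the up- and down-regulated
#' programmes the way disease severity couples them in real cohorts, while
#' keeping each eigengene marginally standard normal. The binary phenotype is
#' `Bernoulli(plogis(sum_m w_m^pheno * ME_m))`; each continuous lung-function
#' trait is `sum_m w_m^trait * ME_m + noise_sd * noise`, emitted only for
#' cohorts listed in `lung_trait_cohorts` (mirroring a study where only one
#' cohort has FVC/DLCO).
#'
#' @param n_genes total genes per cohort.
#' @param n_samples integer vector, samples per cohort.
#' @param shared_module_sizes sizes of modules planted in every cohort.
#' @param specific_module_sizes named integer vector: cohort-specific module
#'   sizes, names = cohort index they appear in (e.g. `c("2" = 80)`).
#' @param loading_range range of per-gene loadings `rho_g` (uniform draw).
#' @param pheno_weights,fvc_weights,dlco_weights per-shared-module trait
#'   coupling weights (recycled with zeros to the number of shared modules).
#' @param latent_loadings per-shared-module loading on the common
#'   disease-severity factor, in `(-1, 1)`.
#' @param noise_sd standard deviation of the continuous-trait noise.
#' @param lung_trait_cohorts integer indices of cohorts with FVC/DLCO.
#' @param seed integer seed; all draws are reproducible from it.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_genes = 2000,
                            n_samples = c(120, 120),
                            shared_module_sizes = c(350, 250, 180, 120, 100),
                            specific_module_sizes = c("2" = 80),
                            loading_range = c(0.3, 0.9),
                            pheno_weights = c(4, -4),
                            fvc_weights = c(1, -1),
                            dlco_weights = c(0.9, -0.9),
                            latent_loadings = c(0.8, -0.8),
                            noise_sd = 0.6,
                            lung_trait_cohorts = 1,
                            seed = 42) {
  stopifnot(n_genes >= sum(shared_module_sizes) + sum(specific_module_sizes),
            all(shared_module_sizes >= 3), all(n_samples >= 3),
            loading_range[1] > 0, loading_range[2] < 1,
            all(abs(latent_loadings) < 1))
  n_shared <- length(shared_module_sizes)
  pad <- function(w) {
    out <- rep(0, n_shared)
    w <- w[seq_len(min(length(w), n_shared))]
    out[seq_along(w)] <- w
    out
  }
  modules <- tibble(
    module = c(paste0("M", seq_len(n_shared)),
               if (length(specific_module_sizes)) paste0("S", seq_along(specific_module_sizes))),
    size = c(shared_module_sizes, unname(specific_module_sizes)),
    cohort = c(rep(NA_integer_, n_shared),
               as.integer(names(specific_module_sizes) %||% integer(0))),
    pheno_weight = c(pad(pheno_weights), rep(0, length(specific_module_sizes))),
    fvc_weight = c(pad(fvc_weights), rep(0, length(specific_module_sizes))),
    dlco_weight = c(pad(dlco_weights), rep(0, length(specific_module_sizes))),
    latent_loading = c(pad(latent_loadings), rep(0, length(specific_module_sizes)))
  )
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  truth <- withr::with_seed(seed, {
    slots <- sample(n_genes) # scatter module genes through the gene list
    assign <- rep("background", n_genes)
    offset <- 0
    for (i in seq_len(nrow(modules))) {
      assign[slots[offset + seq_len(modules$size[i])]] <- modules$module[i]
      offset <- offset + modules$size[i]
    }
    loading <- ifelse(assign == "background", NA_real_,
                      runif(n_genes, loading_range[1], loading_range[2]))
    list(assign = assign, loading = loading)
  })
  structure(
    list(
      gene_ids = gene_ids,
      module_map = setNames(truth$assign, gene_ids),
      loadings = setNames(truth$loading, gene_ids),
      modules = modules,
      n_samples = n_samples,
      noise_sd = noise_sd,
      lung_trait_cohorts = lung_trait_cohorts,
      seed = seed
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic multi-cohort truth:", length(x$gene_ids), "genes,",
      length(x$n_samples), "cohorts (", paste(x$n_samples, collapse = ", "),
      "samples), seed", x$seed, "\n")
  print(x$modules)
  invisible(x)
}

#' Simulate multi-cohort expression and trait data from a planted truth
#'
#' @param truth a [synthetic_truth()] object.
#' @return list with `expression` (named list of gene x sample matrices, one
#'   per cohort, identical gene lists), `traits` (named list of tibbles with
#'   `sample_id`, `phenotype`, `fvc`, `dlco`), `eigengenes` (the latent
#'   per-module sample scores actually used, for test harnesses) and `truth`.
#' @export
simulate_consensus_cohorts <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  withr::with_seed(truth$seed, {
    n_genes <- length(truth$gene_ids)
    expression <- list()
    traits <- list()
    latents <- list()
    for (ci in seq_along(truth$n_samples)) {
      ns <- truth$n_samples[ci]
      severity <- rnorm(ns)
      me <- sapply(seq_len(nrow(truth$modules)), function(i) {
        g <- truth$modules$latent_loading[i]
        g * severity + sqrt(1 - g^2) * rnorm(ns)
      })
      colnames(me) <- truth$modules$module
      x <- matrix(rnorm(n_genes * ns), nrow = n_genes)
      active <- is.na(truth$modules$cohort) | truth$modules$cohort == ci
      for (i in which(active)) {
        idx <- which(truth$module_map == truth$modules$module[i])
        rho <- truth$loadings[idx]
        x[idx, ] <- rho %o% me[, i] + sqrt(1 - rho^2) * x[idx, , drop = FALSE]
      }
      rownames(x) <- truth$gene_ids
      colnames(x) <- sprintf("C%d_S%03d", ci, seq_len(ns))
      pheno <- rbinom(ns, 1, plogis(as.vector(me %*% truth$modules$pheno_weight)))
      has_lung <- ci %in% truth$lung_trait_cohorts
      fvc <- if (has_lung) {
        as.vector(me %*% truth$modules$fvc_weight) + truth$noise_sd * rnorm(ns)
      } else rep(NA_real_, ns)
      dlco <- if (has_lung) {
        as.vector(me %*% truth$modules$dlco_weight) + truth$noise_sd * rnorm(ns)
      } else rep(NA_real_, ns)
      nm <- paste0("cohort", ci)
      expression[[nm]] <- as_expression_matrix(x, cohort = nm)
      traits[[nm]] <- tibble(sample_id = colnames(x), phenotype = pheno,
                             fvc = fvc, dlco = dlco)
      latents[[nm]] <- me
    }
    list(expression = expression, traits = traits, eigengenes = latents,
         truth = truth)
  })
}

#' Simulate curated gene-set annotations with controlled hub overlap
#'
#' Emits mock secretome, known-disease, lung-function GWA and per-cell-type
#' marker gene sets whose overlap with the planted "hub pool" (top-loading
#' genes of the trait-coupled modules) is controlled per category, plus a
#' single-cell marker table (`cell_type`, `gene`, `fdr`, `logfc`) for the
#' marker-filtering step.
#'
#' @param truth a [synthetic_truth()] object.
#' @param overlap_with_hubs named fractions in `[0, 1]` for categories
#'   `secretome`, `known_disease`, `gwa`.
#' @param set_sizes named sizes for the three curated sets.
#' @param n_cell_types number of mock cell-type marker sets.
#' @param seed integer seed (defaults to `truth$seed + 1`).
#' @return list with `gene_sets` (list of [gene_set()] objects), `markers`
#'   (tibble) and `hub_pool` (character vector of planted top genes).
#' @export
simulate_gene_annotations <- function(truth,
                                      overlap_with_hubs = c(secretome = 0.3,
                                                            known_disease = 0.5,
                                                            gwa = 0.3),
                                      set_sizes = c(secretome = 200,
                                                    known_disease = 400,
                                                    gwa = 300),
                                      n_cell_types = 4,
                                      seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(overlap_with_hubs >= 0), all(overlap_with_hubs <= 1))
  seed <- seed %||% (truth$seed + 1)
  trait_modules <- truth$modules$module[truth$modules$pheno_weight != 0]
  in_trait <- truth$module_map %in% trait_modules
  lo <- truth$loadings
  cut90 <- quantile(lo[in_trait], 0.9, na.rm = TRUE)
  hub_pool <- names(lo)[in_trait & !is.na(lo) & lo >= cut90]
  others <- setdiff(truth$gene_ids, hub_pool)
  withr::with_seed(seed, {
    gene_sets <- lapply(names(set_sizes), function(cat) {
      size <- set_sizes[[cat]]
      # the fraction applies to the smaller of the category set and the hub
      # pool, so overlap = 1 means the smaller set is fully contained
      k <- round(overlap_with_hubs[[cat]] * min(size, length(hub_pool)))
      genes <- c(sample(hub_pool, k), sample(others, size - k))
      gene_set(cat, genes, category = cat)
    })
    names(gene_sets) <- names(set_sizes)
    # marker table: each cell type marks one planted module's top genes plus
    # decoys; decoys carry failing fdr/logfc so filtering is exercised
    mods <- truth$modules$module
    markers <- purrr::map_dfr(seq_len(n_cell_types), function(i) {
      mod <- mods[(i - 1) %% length(mods) + 1]
      member <- names(truth$module_map)[truth$module_map == mod]
      top <- member[order(-truth$loadings[member])][seq_len(min(30, length(member)))]
      decoy <- sample(setdiff(truth$gene_ids, top), 15)
      tibble(
        cell_type = paste0("cell_type_", i),
        gene = c(top, decoy),
        fdr = c(runif(length(top), 0, 0.04), runif(length(decoy), 0.1, 0.9)),
        logfc = c(runif(length(top), 0.6, 2.5), runif(length(decoy), 0, 0.4))
      )
    })
    list(gene_sets = gene_sets, markers = markers, hub_pool = hub_pool)
  })
}
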