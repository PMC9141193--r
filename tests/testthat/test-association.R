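test_that("correlation_test reproduces closed-form Student and Fisher results", {
  # r = 0 gives p = 1 under both methods
  x <- c(1, 0, -1, 0, 1, 0, -1, 0)
  e <- c(0, 1, 0, -1, 0, 1, 0, -1)
  expect_equal(correlation_test(x, e, "student")$p_value, 1)
  expect_equal(correlation_test(x, e, "fisher")$p_value, 1)
  # r = 0.6, n = 27: t = 3.75, df = 25
  withr::with_seed(2, {
    repeat { # rejection-sample a vector pair with sample correlation 0.6
      a <- rnorm(27); b <- rnorm(27)
      b <- residuals(lm(b ~ a)); b <- b / sd(b)
      y <- 0.6 * scale(a)[, 1] + sqrt(1 - 0.36) * b
      if (abs(cor(a, y) - 0.6) < 1e-10) break
    }
  })
  res <- correlation_test(a, y, "student")
  expect_equal(res$estimate, 0.6, tolerance = 1e-9)
  expect_equal(res$statistic, 0.6 * sqrt(25 / (1 - 0.36)), tolerance = 1e-8)
  expect_equal(res$p_value, 2 * pt(-3.75, 25), tolerance = 1e-6)
  expect_equal(res$p_value, 9.4e-4, tolerance = 0.01)
  # degenerate inputs
  expect_error(correlation_test(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_warning(res1 <- correlation_test(1:5, 2 * (1:5) + 3, "fisher"), "Fisher")
  expect_equal(res1$p_value, 0)
})

test_that("fisher and student p-values agree asymptotically", {
  withr::with_seed(9, {
    res <- t(replicate(60, {
      n <- 100
      x <- rnorm(n)
      y <- 0.15 * x + rnorm(n)
      c(ps = correlation_test(x, y, "student")$p_value,
        pf = correlation_test(x, y, "fisher")$p_value)
    }))
  })
  # outside the extreme tail the two references agree within 10%
  moderate <- res[res[, "ps"] >= 0.01, , drop = FALSE]
  expect_gt(nrow(moderate), 30)
  expect_gte(mean(abs(moderate[, "pf"] / moderate[, "ps"] - 1) < 0.1), 0.9)
})

test_that("candidate selection demands every required trait in every cohort", {
  # hand-built eigengenes: module A coupled to all traits, B only in cohort 1
  withr::with_seed(10, {
    n <- 100
    z <- rnorm(n)
    me1 <- cbind(A = 0.9 * z + 0.44 * rnorm(n), B = rnorm(n))
    z2 <- rnorm(n)
    me2 <- cbind(A = 0.9 * z2 + 0.44 * rnorm(n), B = rnorm(n))
    rownames(me1) <- paste0("s", 1:n); rownames(me2) <- paste0("t", 1:n)
    tr1 <- tibble::tibble(sample_id = rownames(me1),
                          phenotype = as.integer(plogis(3 * z) > runif(n)),
                          fvc = z + 0.3 * rnorm(n), dlco = z + 0.3 * rnorm(n))
    tr2 <- tibble::tibble(sample_id = rownames(me2),
                          phenotype = as.integer(plogis(3 * z2) > runif(n)),
                          fvc = NA_real_, dlco = NA_real_)
  })
  me <- structure(list(eigengenes = list(c1 = me1, c2 = me2),
                       var_explained = tibble::tibble()),
                  class = "module_eigengenes")
  rep <- select_candidate_modules(me, list(c1 = tr1, c2 = tr2))
  expect_equal(rep$selected, "A")
  expect_true(all(c("phenotype", "fvc", "dlco") %in% rep$tests$trait))
  # a module passing in one cohort but not the other is rejected
  me_b <- structure(list(eigengenes = list(
    c1 = cbind(A = me1[, "A"]), c2 = cbind(A = me2[, "B"])),
    var_explained = tibble::tibble()), class = "module_eigengenes")
  rep_b <- select_candidate_modules(me_b, list(c1 = tr1, c2 = tr2))
  expect_length(rep_b$selected, 0)
})

test_that("gene significance matches direct correlations and handles binary traits", {
  sim <- small_sim(seed = 51, n_genes = 50, sizes = c(15), specific = NULL,
                   pheno_weights = 3, fvc_weights = 1, dlco_weights = 1,
                   latent_loadings = 0)
  gs <- gene_significance(sim$expression, sim$traits)
  # a gene identical to the fvc vector has GS 1
  m <- sim$expression$cohort1
  m <- rbind(m, FVCGENE = sim$traits$cohort1$fvc)
  gs2 <- gene_significance(list(cohort1 = m), sim$traits["cohort1"])
  expect_equal(gs2$gs[gs2$gene_id == "FVCGENE" & gs2$trait == "fvc"], 1, tolerance = 1e-12)
  # point-biserial phenotype GS equals cor() against the 0/1 coding
  g <- rownames(sim$expression$cohort1)[1]
  expect_equal(gs$gs[gs$gene_id == g & gs$trait == "phenotype" & gs$cohort == "cohort1"],
               cor(sim$expression$cohort1[g, ], sim$traits$cohort1$phenotype))
  # no fvc/dlco rows for the cohort that lacks them
  expect_false(any(gs$cohort == "cohort2" & gs$trait %in% c("fvc", "dlco")))
})

test_that("null gene significance concentrates near zero", {
  withr::with_seed(52, {
    m <- matrix(rnorm(100 * 200), 100, 200,
                dimnames = list(sprintf("G%03d", 1:100), paste0("s", 1:200)))
    tr <- tibble::tibble(sample_id = colnames(m),
                         phenotype = rep(c(0L, 1L), 100),
                         fvc = rnorm(200), dlco = rnorm(200))
  })
  gs <- gene_significance(list(c1 = m), list(c1 = tr))
  expect_gte(mean(abs(gs$gs) < 0.2), 0.95)
})

test_that("trait-coupled module genes carry the planted GS sign", {
  sim <- small_sim(seed = 53, n_samples = c(200, 200))
  gs <- gene_significance(sim$expression["cohort1"], sim$traits["cohort1"])
  truth <- sim$truth$module_map
  up <- gs$gs[gs$trait == "phenotype" & gs$gene_id %in% names(truth)[truth == "M1"]]
  dn <- gs$gs[gs$trait == "phenotype" & gs$gene_id %in% names(truth)[truth == "M2"]]
  expect_gt(mean(up > 0), 0.95)
  expect_gt(mean(dn < 0), 0.95)
})

test_that("consensus kME takes the minimal-magnitude common-sign value", {
  expect_equal(conexus:::consensus_signed_min(c(0.8, 0.6)), 0.6)
  expect_equal(conexus:::consensus_signed_min(c(-0.8, -0.4)), -0.4)
  expect_equal(conexus:::consensus_signed_min(c(0.8, -0.4)), 0)
  expect_equal(conexus:::consensus_signed_min(c(0.8, 0)), 0)
  # a gene equal to its module eigengene has kME 1 in that cohort
  sim <- small_sim(seed = 54, n_genes = 40, sizes = c(12), specific = NULL,
                   pheno_weights = 2, fvc_weights = 1, dlco_weights = 1,
                   latent_loadings = 0)
  genes <- names(sim$truth$module_map)[sim$truth$module_map == "M1"]
  assign <- tibble::tibble(gene_id = genes, module = "turquoise")
  me <- compute_eigengenes(assign, sim$expression)
  m1 <- sim$expression$cohort1
  m1[genes[1], ] <- me$eigengenes$cohort1[, "turquoise"]
  mm <- module_membership(assign, me, list(cohort1 = m1, cohort2 = sim$expression$cohort2))
  expect_equal(mm$kme_cohort1[mm$gene_id == genes[1]], 1, tolerance = 1e-12)
})

test_that("HubScore is the product of |consensus kME| and mean |GS|", {
  membership <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                               module = "blue",
                               consensus_kme = c(1, 0.7, 0.7))
  significance <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 4),
    cohort = rep(c("c1", "c2", "c1", "c1"), 3),
    trait = rep(c("phenotype", "phenotype", "fvc", "dlco"), 3),
    gs = c(1, 1, 1, 1, 0, 0, 0, 0, 0.5, 0.7, -0.6, 0.6),
    n = 100, p_value = 0.5)
  hs <- hub_score(membership, significance)
  expect_equal(hs$hub_score[hs$gene_id == "g1"], 1)
  expect_equal(hs$hub_score[hs$gene_id == "g2"], 0)
  expect_equal(hs$hub_score[hs$gene_id == "g3"], 0.7 * 0.6, tolerance = 1e-12)
  # kME (0.8, 0.6) with |GS| = (.5,.7,.6,.6): consensus 0.6 x mean 0.6 = 0.36
  membership2 <- tibble::tibble(gene_id = "g4", module = "blue",
                                consensus_kme = conexus:::consensus_signed_min(c(0.8, 0.6)))
  significance2 <- significance[9:12, ]
  significance2$gene_id <- "g4"
  significance2$gs <- c(0.5, 0.7, -0.6, 0.6)
  expect_equal(hub_score(membership2, significance2)$hub_score, 0.36, tolerance = 1e-12)
  # genes without GS are excluded with a warning
  expect_warning(hs3 <- hub_score(membership, significance[1:8, ]), "excluded")
  expect_false("g3" %in% hs3$gene_id)
})

test_that("hub selection keeps the top of each module with tie inclusion", {
  hubs <- tibble::tibble(gene_id = paste0("g", 1:100), module = "blue",
                         consensus_kme = 1, mean_abs_gs = 1,
                         hub_score = seq(0.01, 1, length.out = 100))
  sel <- select_hubs(hubs, q = 0.95)
  expect_equal(sum(sel$is_hub), 5) # exactly the top 5% of 100 distinct scores
  small <- hubs[1:20, ]
  expect_equal(sum(select_hubs(small, q = 0.95)$is_hub), 1)
  # ties at the threshold are all included
  tied <- tibble::tibble(gene_id = paste0("g", 1:40), module = "m",
                         consensus_kme = 1, mean_abs_gs = 1,
                         hub_score = c(rep(0.2, 36), rep(0.9, 4)))
  expect_equal(sum(select_hubs(tied, q = 0.95)$is_hub), 4)
  # hub counts bounded per module
  sim_scores <- tibble::tibble(gene_id = paste0("g", 1:73), module = "m",
                               consensus_kme = 1, mean_abs_gs = 1,
                               hub_score = withr::with_seed(3, runif(73)))
  n_hub <- sum(select_hubs(sim_scores, 0.95)$is_hub)
  expect_gte(n_hub, 1)
  expect_lte(n_hub, ceiling(0.05 * 73) + 1)
})

test_that("BH adjustment preserves the raw p-value ordering", {
  withr::with_seed(60, p <- runif(50)^2)
  adj <- bh_adjust(p)
  expect_equal(order(adj[order(p)]), seq_along(p)) # monotone in sorted order
})
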