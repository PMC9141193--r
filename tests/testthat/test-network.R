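test_that("adjacency transforms follow the signed/unsigned definitions", {
  # r = 1: signed adjacency 1 at any power
  m <- two_gene_matrix(1)
  a <- adjacency_matrix(m, mode = "signed", power = 6)
  expect_equal(a["g1", "g2"], 1)
  # r = -1: signed adjacency 0
  a <- adjacency_matrix(two_gene_matrix(-1), mode = "signed", power = 3)
  expect_equal(a["g1", "g2"], 0)
  # r = 0.5 unsigned at power 2 -> 0.25
  a <- adjacency_matrix(two_gene_matrix(0.5), mode = "unsigned", power = 2)
  expect_equal(a["g1", "g2"], 0.25, tolerance = 1e-12)
  # diagonal stored as zero for connectivity
  expect_equal(unname(diag(a)), c(0, 0))
})

test_that("constant genes warn and correlate at zero instead of failing", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(a <- adjacency_matrix(m, power = 1), "constant")
  expect_equal(a["g1", "g2"], 0.5) # signed((1+0)/2)^1
  expect_error(adjacency_matrix(m[, 1:2, drop = FALSE]), "3 samples")
})

test_that("unsigned adjacency strictly decreases with power when |r| < 1", {
  withr::with_seed(3, m <- matrix(rnorm(200), 10, 20,
                                  dimnames = list(paste0("g", 1:10), paste0("s", 1:20))))
  a2 <- adjacency_matrix(m, mode = "unsigned", power = 2)
  a4 <- adjacency_matrix(m, mode = "unsigned", power = 4)
  off <- upper.tri(a2)
  expect_true(all(a4[off] < a2[off]))
})

test_that("TOM matches its defining formula on a hand-built 3-gene network", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.5
  a[2, 3] <- a[3, 2] <- 0.4
  tom <- tom_similarity(a)
  # l_12 = 0.5 * 0.4; min(k) = 1.2; TOM_12 = (0.2 + 0.8) / (1.2 + 1 - 0.8)
  expect_equal(tom[1, 2], 1.0 / 1.4, tolerance = 1e-9)
  expect_equal(unname(diag(tom)), rep(1, 3))
})

test_that("TOM equals the O(n^3) triple-loop oracle and isolates null genes", {
  a <- random_adjacency(30, seed = 8)
  expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
  a0 <- random_adjacency(10, seed = 9)
  a0[1, ] <- a0[, 1] <- 0 # isolated gene
  tom <- tom_similarity(a0)
  expect_equal(unname(tom[1, -1]), rep(0, 9))
})

test_that("quantile calibration matches reference quantiles and preserves order", {
  sim <- small_sim(seed = 21, n_genes = 80, sizes = c(20, 20), specific = NULL)
  toms <- lapply(sim$expression, function(m) tom_similarity(adjacency_matrix(m, power = 6)))
  cal <- calibrate_toms(toms, q = 0.95)
  q1 <- quantile(cal$toms[[1]][upper.tri(cal$toms[[1]])], 0.95)
  q2 <- quantile(cal$toms[[2]][upper.tri(cal$toms[[2]])], 0.95)
  expect_equal(unname(q1), unname(q2), tolerance = 1e-8)
  expect_equal(unname(cal$exponents[1]), 1)
  # power map is monotone: within-cohort ordering unchanged
  o <- order(toms[[2]][upper.tri(toms[[2]])])
  expect_equal(o, order(cal$toms[[2]][upper.tri(cal$toms[[2]])]))
  # identical TOMs calibrate to exponent 1, unchanged
  cal2 <- calibrate_toms(list(toms[[1]], toms[[1]]))
  expect_equal(unname(cal2$exponents), c(1, 1))
  expect_equal(cal2$toms[[2]], toms[[1]])
  # stated exponent arithmetic: Q_ref = 0.2, Q_2 = 0.4 -> e = log(.2)/log(.4)
  expect_equal(0.4^(log(0.2) / log(0.4)), 0.2, tolerance = 1e-12)
})

test_that("consensus TOM is the element-wise minimum of calibrated TOMs", {
  sim <- small_sim(seed = 22, n_genes = 60, sizes = c(20), specific = NULL,
                   pheno_weights = 2, fvc_weights = 1, dlco_weights = 1,
                   latent_loadings = 0)
  toms <- lapply(sim$expression, function(m) tom_similarity(adjacency_matrix(m, power = 6)))
  ct <- consensus_tom(toms, calibrate = TRUE)
  for (t in ct$per_cohort) {
    expect_true(all(ct$consensus <= t + 1e-12))
  }
  expect_equal(ct$consensus, Reduce(pmin, ct$per_cohort), ignore_attr = TRUE)
  # single cohort: identity
  single <- consensus_tom(toms[1])
  expect_equal(single$consensus, toms[[1]])
  # mismatched gene lists rejected
  t2 <- toms[[2]][-1, -1]
  expect_error(consensus_tom(list(toms[[1]], t2)), "identical")
})

test_that("soft-threshold choice takes the smallest qualifying power with fallback", {
  expect_equal(conexus:::choose_power(c(0.2, 0.5, 0.85, 0.9), c(2, 4, 6, 8), 0.8)$power, 6)
  expect_warning(res <- conexus:::choose_power(c(0.2, 0.5, 0.6), c(2, 4, 6), 0.8),
                 "no candidate power")
  expect_equal(res$power, 6)
  expect_false(res$reached_target)
})

test_that("soft-threshold report is deterministic and well-formed", {
  sim <- small_sim(seed = 23, n_genes = 200, sizes = c(50, 40, 30), specific = NULL,
                   pheno_weights = c(2, -2, 0), fvc_weights = c(1, -1, 0),
                   dlco_weights = c(1, -1, 0), latent_loadings = c(0.8, -0.8, 0))
  st1 <- pick_soft_threshold(sim$expression$cohort1, powers = 1:8)
  st2 <- pick_soft_threshold(sim$expression$cohort1, powers = 1:8)
  expect_identical(st1$power, st2$power)
  expect_true(st1$power %in% 1:8)
  expect_true(all(st1$report$fit_r2 >= -1 & st1$report$fit_r2 <= 1, na.rm = TRUE))
  expect_true(all(diff(st1$report$mean_connectivity) < 0)) # connectivity falls with power
})

test_that("TOM Q-Q divergence separates same-generator from disjoint structure", {
  tomify <- function(m) tom_similarity(adjacency_matrix(m, power = 6))
  shared <- small_sim(seed = 31, n_genes = 120, sizes = c(40, 30), specific = NULL)
  t1 <- tomify(shared$expression$cohort1)
  t2 <- tomify(shared$expression$cohort2)
  expect_equal(tom_qq_divergence(t1, t1), 0)
  expect_gt(tom_qq_divergence(t1, t1^2), 0) # strict monotone shrinkage
  # disjoint module structure: one cohort with modules, one pure noise
  noise <- simulate_consensus_cohorts(synthetic_truth(
    n_genes = 120, n_samples = c(60, 60), shared_module_sizes = c(3),
    specific_module_sizes = NULL, pheno_weights = 0.1, fvc_weights = 0,
    dlco_weights = 0, latent_loadings = 0, seed = 32))
  t3 <- tomify(noise$expression$cohort1)
  expect_gt(tom_qq_divergence(t1, t3), tom_qq_divergence(t1, t2))
})
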