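# shared fixtures and independent oracles

# small two-cohort simulation for unit tests
small_sim <- function(seed = 11, n_genes = 300, n_samples = c(60, 60),
                      sizes = c(60, 50), specific = c("2" = 30),
                      pheno_weights = c(4, -4), fvc_weights = c(1, -1),
                      dlco_weights = c(0.9, -0.9),
                      latent_loadings = c(0.8, -0.8), ...) {
  simulate_consensus_cohorts(synthetic_truth(
    n_genes = n_genes, n_samples = n_samples, shared_module_sizes = sizes,
    specific_module_sizes = specific,
    pheno_weights = pheno_weights, fvc_weights = fvc_weights,
    dlco_weights = dlco_weights, latent_loadings = latent_loadings,
    seed = seed, ...))
}

# the default full-scale synthetic study, computed once and cached for the
# end-to-end checks (2 cohorts x 2000 genes x 120 samples, seed 42)
.run_cache <- new.env(parent = emptyenv())
default_synthetic_run <- function() {
  if (!is.null(.run_cache$run)) return(.run_cache$run)
  truth <- synthetic_truth()
  sim <- simulate_consensus_cohorts(truth)
  ct <- build_consensus_tom(sim$expression)
  assignment <- merge_modules(detect_modules(ct, sim$expression), sim$expression)
  me <- compute_eigengenes(assignment, sim$expression)
  .run_cache$run <- list(truth = truth, sim = sim, ct = ct,
                         assignment = assignment, eigengenes = me)
  .run_cache$run
}

# expression matrix with an exact correlation r between two genes
two_gene_matrix <- function(r) {
  x <- c(1, 0, -1, 0, 1, 0, -1, 0)
  e <- c(0, 1, 0, -1, 0, 1, 0, -1) # orthogonal to x, same sd
  y <- r * x + sqrt(1 - r^2) * e
  m <- rbind(g1 = x, g2 = y)
  colnames(m) <- paste0("s", seq_along(x))
  m
}

# O(n^3) TOM oracle: explicit triple loop over shared neighbours
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- tom[j, i] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

random_adjacency <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    a
  })
}

# hypergeometric upper-tail by exhaustive enumeration of all draws
hyper_tail_oracle <- function(N, K, n, k) {
  count <- 0
  total <- choose(N, n)
  for (x in 0:min(K, n)) {
    if (x >= k) count <- count + choose(K, x) * choose(N - K, n - x)
  }
  count / total
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# FISTA proximal-gradient solver for the elastic-net logistic objective
#   (1/n) sum log(1 + exp(-(2y-1) * (b0 + X b))) +
#   lambda * ((1-alpha)/2 ||b||^2 + alpha ||b||_1)
enet_objective <- function(X, y, b0, b, lambda, alpha) {
  eta <- b0 + as.vector(X %*% b)
  mean(log1p(exp(-(2 * y - 1) * eta))) +
    lambda * ((1 - alpha) / 2 * sum(b^2) + alpha * sum(abs(b)))
}

enet_fista_oracle <- function(X, y, lambda, alpha, maxit = 20000, tol = 1e-11) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p); b0 <- 0
  zb <- b; zb0 <- b0; tk <- 1
  L <- (max(eigen(crossprod(cbind(1, X)), symmetric = TRUE, only.values = TRUE)$values) /
          (4 * n)) + lambda * (1 - alpha)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- zb0 + as.vector(X %*% zb)
    g <- (plogis(eta) - y) / n
    gb0 <- sum(g)
    gb <- as.vector(crossprod(X, g)) + lambda * (1 - alpha) * zb
    b0_new <- zb0 - gb0 / L
    b_new <- soft(zb - gb / L, lambda * alpha / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb0 <- b0_new + (tk - 1) / tk_new * (b0_new - b0)
    zb <- b_new + (tk - 1) / tk_new * (b_new - b)
    b0 <- b0_new; b <- b_new; tk <- tk_new
    if (it %% 100 == 0) {
      obj <- enet_objective(X, y, b0, b, lambda, alpha)
      if (abs(obj_old - obj) < tol) break
      obj_old <- obj
    }
  }
  list(b0 = b0, b = b, objective = enet_objective(X, y, b0, b, lambda, alpha))
}
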