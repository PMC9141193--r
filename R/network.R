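#' Biweight midcorrelation matrix
#'
#' Robust correlation based on median/MAD biweights. Columns whose MAD is
#' zero fall back to mean/SD weights for that column.
#'
#' @param x samples x variables numeric matrix (complete observations).
#' @return variables x variables correlation matrix.
#' @export
bicor_matrix <- function(x) {
  x <- as.matrix(x)
  w <- apply(x, 2, function(v) {
    med <- median(v, na.rm = TRUE)
    s <- mad(v, constant = 1, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      mu <- mean(v, na.rm = TRUE)
      sdv <- sd(v, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) return(rep(0, length(v)))
      return((v - mu) / sdv)
    }
    u <- (v - med) / (9 * s)
    wt <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * wt
  })
  denom <- sqrt(colSums(w^2, na.rm = TRUE))
  denom[denom == 0] <- 1
  w <- sweep(w, 2, denom, "/")
  w[is.na(w)] <- 0
  out <- crossprod(w)
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

cor_for_network <- function(m, cor_method = c("pearson", "bicor")) {
  cor_method <- match.arg(cor_method)
  r <- if (cor_method == "pearson") safe_cor(t(m)) else bicor_matrix(t(m))
  const <- apply(m, 1, function(v) {
    s <- sd(v, na.rm = TRUE)
    !is.finite(s) || s == 0
  })
  if (any(const) || anyNA(r)) {
    if (any(const)) {
      warning(sum(const), " constant gene(s); their correlations set to 0")
    }
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency matrix
#'
#' Pairwise correlations (pairwise-complete Pearson by default, biweight
#' midcorrelation optionally) raised to the soft-thresholding power:
#' unsigned `|r|^power`, signed `((1 + r)/2)^power`. The diagonal is stored
#' as zero so that row sums give the network connectivity `k_i`.
#'
#' @param m expression matrix (genes x samples, >= 3 samples).
#' @param mode `"signed"` (default) or `"unsigned"`.
#' @param power soft-thresholding exponent, >= 1.
#' @param cor_method `"pearson"` or `"bicor"`.
#' @return symmetric adjacency matrix in `[0, 1]` with zero diagonal and
#'   attributes `mode` and `power`.
#' @export
adjacency_matrix <- function(m, mode = c("signed", "unsigned"), power = 6,
                             cor_method = c("pearson", "bicor")) {
  mode <- match.arg(mode)
  m <- as_expression_matrix(m)
  stopifnot(power >= 1)
  if (ncol(m) < 3) stop("need at least 3 samples", call. = FALSE)
  r <- cor_for_network(m, cor_method)
  adjacency_from_cor(r, mode = mode, power = power)
}

# transform an existing correlation matrix; shared by preservation stats
adjacency_from_cor <- function(r, mode = c("signed", "unsigned"), power = 6) {
  mode <- match.arg(mode)
  a <- if (mode == "signed") ((1 + r) / 2)^power else abs(r)^power
  a[a > 1] <- 1
  a[a < 0] <- 0
  diag(a) <- 0
  attr(a, "mode") <- mode
  attr(a, "power") <- power
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins || diff(range(k)) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tabulate(bin, nbins = n_bins) / length(k)
  ok <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  -sign(coef(fit)[2]) * summary(fit)$r.squared
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For every candidate power the connectivities are binned (10 equal-width
#' bins), log10 bin frequency is regressed on log10 mean bin connectivity,
#' and the signed fit statistic `-sign(slope) * R^2` is reported. The chosen
#' power is the smallest one reaching `target_r2`; if none does, the power
#' maximising the fit is returned with `reached_target = FALSE`.
#'
#' @param m expression matrix (>= 3 samples).
#' @param powers candidate integer powers.
#' @param target_r2 target signed scale-free fit.
#' @param mode,cor_method passed to [adjacency_matrix()].
#' @return object of class `soft_threshold` with a per-power `report`
#'   tibble, the chosen `power` and `reached_target`.
#' @export
pick_soft_threshold <- function(m, powers = 1:10, target_r2 = 0.8,
                                mode = c("signed", "unsigned"),
                                cor_method = c("pearson", "bicor")) {
  mode <- match.arg(mode)
  m <- as_expression_matrix(m)
  stopifnot(length(powers) > 0)
  if (ncol(m) < 3) stop("need at least 3 samples", call. = FALSE)
  r <- cor_for_network(m, cor_method)
  report <- purrr::map_dfr(powers, function(p) {
    a <- adjacency_from_cor(r, mode = mode, power = p)
    k <- rowSums(a)
    tibble(power = p, fit_r2 = scale_free_fit(k),
           mean_connectivity = mean(k), max_connectivity = max(k))
  })
  chosen <- choose_power(report$fit_r2, powers, target_r2)
  structure(
    list(report = report, power = chosen$power,
         reached_target = chosen$reached_target, target_r2 = target_r2,
         mode = mode, cohort = cohort_name(m)),
    class = "soft_threshold"
  )
}

choose_power <- function(fit_r2, powers, target_r2) {
  ok <- which(!is.na(fit_r2) & fit_r2 >= target_r2)
  if (length(ok) > 0) {
    list(power = powers[min(ok)], reached_target = TRUE)
  } else {
    if (all(is.na(fit_r2))) {
      warning("scale-free fit undefined for all powers; using the largest candidate")
      return(list(power = max(powers), reached_target = FALSE))
    }
    warning("no candidate power reaches the target scale-free fit; using the best fit")
    list(power = powers[which.max(fit_r2)], reached_target = FALSE)
  }
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("Soft threshold for", x$cohort, "(", x$mode, "network ): power =",
      x$power, if (!x$reached_target) "(target fit not reached)", "\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.soft_threshold <- function(x, ...) x$report

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (the diagonal of `a` is zero, so terms `u = i, j`
#' vanish) and `k_i = sum_u a_iu`. The diagonal is 1.
#'
#' @param a adjacency matrix (symmetric, values in `[0, 1]`, zero diagonal;
#'   any symmetric matrix is accepted and its diagonal zeroed).
#' @return symmetric TOM with unit diagonal, values in `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric", call. = FALSE)
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1) stop("adjacency values must lie in [0, 1]", call. = FALSE)
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  tom
}

#' Calibrate TOMs across cohorts by quantile matching
#'
#' The first cohort is the reference. For cohort s with off-diagonal
#' `q`-quantile `Q_s`, the calibration exponent is
#' `e_s = log(Q_ref) / log(Q_s)` and the calibrated TOM is `TOM_s^{e_s}`,
#' so all cohorts share the reference `q`-quantile afterwards.
#'
#' @param toms list of TOMs on identical gene lists.
#' @param q calibration quantile in `(0, 1)` (default 0.95).
#' @return list with `toms` (calibrated) and `exponents`.
#' @export
calibrate_toms <- function(toms, q = 0.95) {
  stopifnot(is.list(toms), length(toms) >= 1, q > 0, q < 1)
  check_same_genes(toms)
  qs <- vapply(toms, function(t) unname(quantile(upper_tri_values(t), q)), numeric(1))
  if (any(qs <= 0) || any(qs >= 1)) {
    stop("calibration quantile is 0 or 1 in some cohort; power scaling undefined", call. = FALSE)
  }
  exponents <- log(qs[1]) / log(qs)
  out <- purrr::map2(toms, exponents, function(t, e) {
    ct <- t^e
    diag(ct) <- 1
    ct
  })
  names(exponents) <- names(toms)
  list(toms = out, exponents = exponents)
}

#' Consensus TOM across cohorts
#'
#' Optionally quantile-calibrates the per-cohort TOMs, then takes the
#' element-wise minimum.
#'
#' @param toms list of TOMs on identical gene lists.
#' @param calibrate calibrate before taking the minimum (default TRUE).
#' @param q calibration quantile.
#' @return object of class `consensus_tom` with fields `consensus`,
#'   `per_cohort` (calibrated TOMs), `calibration_exponents` and
#'   `calibration_quantile`.
#' @export
consensus_tom <- function(toms, calibrate = TRUE, q = 0.95) {
  stopifnot(is.list(toms), length(toms) >= 1)
  check_same_genes(toms)
  exponents <- setNames(rep(1, length(toms)), names(toms))
  if (calibrate && length(toms) > 1) {
    cal <- calibrate_toms(toms, q = q)
    toms <- cal$toms
    exponents <- cal$exponents
  }
  cons <- Reduce(pmin, toms)
  diag(cons) <- 1
  structure(
    list(consensus = cons, per_cohort = toms,
         calibration_exponents = exponents, calibration_quantile = q),
    class = "consensus_tom"
  )
}

#' @export
print.consensus_tom <- function(x, ...) {
  cat("Consensus TOM over", length(x$per_cohort), "cohorts,",
      nrow(x$consensus), "genes; calibration quantile",
      x$calibration_quantile, "\n")
  invisible(x)
}

consensus_matrix <- function(ct) {
  if (inherits(ct, "consensus_tom")) ct$consensus else as.matrix(ct)
}

#' Build the consensus TOM from expression cohorts
#'
#' Convenience wrapper: per-cohort adjacency at a common power (chosen as the
#' maximum of per-cohort automatic picks when `power = "auto"`), TOM,
#' quantile calibration, element-wise minimum.
#'
#' With `power = "auto"` the soft power is picked per cohort by scale-free
#' fit and the consensus power is the maximum across cohorts, floored at the
#' mode's conventional working power (8 for signed, 4 for unsigned): a signed
#' adjacency retains a baseline similarity of `0.5^power` between unrelated
#' genes, so the smallest power passing the scale-free criterion can leave
#' too little topological contrast for stable branch cutting.
#'
#' @param cohorts list of aligned expression matrices.
#' @param mode,cor_method network type, see [adjacency_matrix()].
#' @param power integer power or `"auto"`.
#' @param powers,target_r2 candidates and target for the automatic pick.
#' @param min_auto_power floor applied to the automatic pick; default 8 for
#'   signed, 4 for unsigned networks.
#' @param q calibration quantile.
#' @return `consensus_tom` object; the power used is attached as attribute
#'   `power`.
#' @export
build_consensus_tom <- function(cohorts, mode = c("signed", "unsigned"),
                                power = "auto", powers = 1:10, target_r2 = 0.8,
                                min_auto_power = NULL,
                                cor_method = c("pearson", "bicor"), q = 0.95) {
  mode <- match.arg(mode)
  cor_method <- match.arg(cor_method)
  cohorts <- as_cohort_list(cohorts)
  check_same_genes(cohorts)
  if (identical(power, "auto")) {
    picks <- lapply(cohorts, pick_soft_threshold, powers = powers,
                    target_r2 = target_r2, mode = mode, cor_method = cor_method)
    min_auto_power <- min_auto_power %||% if (mode == "signed") 8 else 4
    power <- max(vapply(picks, `[[`, numeric(1), "power"), min_auto_power)
  }
  toms <- lapply(cohorts, function(m) {
    tom_similarity(adjacency_matrix(m, mode = mode, power = power,
                                    cor_method = cor_method))
  })
  out <- consensus_tom(toms, calibrate = TRUE, q = q)
  attr(out, "power") <- power
  attr(out, "mode") <- mode
  out
}

#' Kolmogorov-style divergence between two TOM value distributions
#'
#' Maximum absolute difference between the off-diagonal TOM value
#' distributions of two cohorts, evaluated as quantile functions on an even
#' probability grid. Used as a dataset-compatibility screen before consensus
#' analysis.
#'
#' @param t1,t2 TOM matrices (need not share genes).
#' @param n_quantiles grid size, >= 10.
#' @return non-negative scalar; 0 iff the distributions agree on the grid.
#' @export
tom_qq_divergence <- function(t1, t2, n_quantiles = 101) {
  stopifnot(n_quantiles >= 10)
  probs <- seq(0, 1, length.out = n_quantiles)
  q1 <- quantile(upper_tri_values(as.matrix(t1)), probs)
  q2 <- quantile(upper_tri_values(as.matrix(t2)), probs)
  max(abs(q1 - q2))
}
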