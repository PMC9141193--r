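#' Precision-recall area under the curve (average precision)
#'
#' Average-precision estimator: positives are taken in decreasing-score
#' order and the precision at each positive's rank is averaged. Tied scores
#' are handled as blocks — every positive in a tied block receives the
#' precision evaluated at the end of the block — so constant scores give the
#' class prevalence.
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param y binary labels (0/1, logical, or two-level factor).
#' @return scalar average precision in `[0, 1]`.
#' @export
evaluate_prauc <- function(scores, y) {
  y <- as_binary(y)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  block_end <- cumsum(rle(s)$lengths)
  tp_end <- cumsum(y)[block_end]
  tp_block <- diff(c(0, tp_end))
  precision_end <- tp_end / block_end
  sum(tp_block * precision_end) / sum(y)
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  as.integer(y)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit an elastic-net logistic marker panel
#'
#' Minimises the penalised logistic deviance
#' `logloss + lambda * ((1 - alpha)/2 * ||b||_2^2 + alpha * ||b||_1)` on
#' internally standardised predictors, over a log-spaced lambda path from
#' `lambda_max` down by `lambda_min_ratio`. `lambda` is chosen by stratified
#' cross-validation maximising the precision-recall AUC; ties prefer the
#' larger (sparser) lambda. Coefficients are reported on the original
#' predictor scale.
#'
#' @param x samples x genes numeric matrix (or data frame).
#' @param y binary labels with at least two samples per class.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param cv_folds number of stratified folds.
#' @param seed integer seed making fold assignment deterministic.
#' @param nlambda,lambda_min_ratio lambda path (50 points down to 1e-3 of
#'   `lambda_max` by default).
#' @return object of class `elastic_net_fit`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.35, cv_folds = 5, seed = 42,
                            nlambda = 50, lambda_min_ratio = 1e-3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  y <- as_binary(y)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least two samples per class", call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha <= 1, cv_folds >= 2)
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                         nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                         standardize = TRUE)
  lambda_path <- full$lambda
  cv <- withr::with_seed(seed, {
    fold <- stratified_folds(y, cv_folds)
    per_fold <- lapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = alpha, lambda = lambda_path,
                            standardize = TRUE)
      prob <- predict(fit, x[!tr, , drop = FALSE], type = "response")
      apply(prob, 2, function(p) {
        if (length(unique(y[!tr])) < 2) return(NA_real_)
        evaluate_prauc(p, y[!tr])
      })
    })
    rowMeans(do.call(cbind, per_fold), na.rm = TRUE)
  })
  best <- which(cv == max(cv, na.rm = TRUE))[1] # path is decreasing: first = largest lambda
  lambda <- lambda_path[best]
  beta <- as.vector(coef(full, s = lambda, exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(x))
  structure(
    list(
      fit = full, alpha = alpha, lambda = lambda, lambda_path = lambda_path,
      cv_prauc = tibble(lambda = lambda_path, mean_prauc = cv),
      coefficients = beta,
      selected_predictors = colnames(x)[beta[-1] != 0],
      standardization = list(mean = colMeans(x),
                             sd = apply(x, 2, sd) * sqrt((nrow(x) - 1) / nrow(x))),
      cv_folds = cv_folds, seed = seed, n = nrow(x)
    ),
    class = "elastic_net_fit"
  )
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat("Elastic-net logistic model: alpha =", x$alpha,
      ", lambda =", signif(x$lambda, 4), "(CV over PRAUC),",
      length(x$selected_predictors), "of", length(x$coefficients) - 1,
      "predictors selected\n")
  invisible(x)
}

#' @export
coef.elastic_net_fit <- function(object, ...) object$coefficients

#' @export
predict.elastic_net_fit <- function(object, newdata,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  eta <- as.vector(predict(object$fit, newdata, s = object$lambda,
                           type = "link", exact = FALSE))
  if (type == "link") eta else plogis(eta)
}

#' @export
tidy.elastic_net_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients)) |>
    filter(.data$term == "(Intercept)" | .data$estimate != 0)
}

#' @export
glance.elastic_net_fit <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda,
         n_selected = length(x$selected_predictors),
         cv_prauc = max(x$cv_prauc$mean_prauc, na.rm = TRUE),
         n = x$n, cv_folds = x$cv_folds)
}

#' Label-permutation significance of a marker panel's PRAUC
#'
#' Fits the elastic-net model, records its in-sample PRAUC, then refits on
#' `n_permutations` label permutations. The permutation p-value is
#' `(1 + #\{perm PRAUC >= observed\}) / (1 + n_permutations)`, so with 19
#' permutations all below the observed score the floor is 0.05. When several
#' panels are compared, adjust the returned p-values together with
#' [bh_adjust()].
#'
#' @param x,y,alpha,cv_folds,seed as in [fit_elastic_net()].
#' @param n_permutations number of label permutations, >= 19.
#' @param ... passed on to [fit_elastic_net()].
#' @return object of class `classifier_report`: `prauc`, `permutation_p`,
#'   `perm_praucs`, `selected_predictors`, `fit`.
#' @export
permutation_significance <- function(x, y, alpha = 0.35, n_permutations = 100,
                                     seed = 42, cv_folds = 5, ...) {
  stopifnot(n_permutations >= 19)
  y <- as_binary(y)
  fit <- fit_elastic_net(x, y, alpha = alpha, cv_folds = cv_folds, seed = seed, ...)
  observed <- evaluate_prauc(predict(fit, x), y)
  perm <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_permutations), function(i) {
      yp <- sample(y)
      fp <- fit_elastic_net(x, yp, alpha = alpha, cv_folds = cv_folds,
                            seed = seed, ...)
      evaluate_prauc(predict(fp, x), yp)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= observed)) / (1 + n_permutations)
  structure(
    list(prauc = observed, permutation_p = p, perm_praucs = perm,
         n_permutations = n_permutations,
         selected_predictors = fit$selected_predictors, fit = fit),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("PRAUC =", round(x$prauc, 3), "; permutation p =",
      signif(x$permutation_p, 3), "(", x$n_permutations, "permutations ),",
      length(x$selected_predictors), "predictors selected\n")
  invisible(x)
}

#' @export
glance.classifier_report <- function(x, ...) {
  tibble(prauc = x$prauc, permutation_p = x$permutation_p,
         n_permutations = x$n_permutations,
         n_selected = length(x$selected_predictors))
}
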