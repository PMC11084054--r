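# Stratified k-fold assignment: samples of each class are spread evenly
# across folds so every training split contains both classes.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Nested cross-validated elastic-net risk model
#'
#' Elastic-net logistic regression with nested cross-validation: on each
#' outer training set, an inner k-fold grid search over the mixing
#' parameter alpha (and glmnet's lambda path) picks the
#' deviance-minimizing penalty; the outer held-out folds then supply
#' honest out-of-sample predicted probabilities, pooled into a
#' cross-validated AUC. The reported feature set comes from refitting on
#' all data at the consensus hyperparameters (modal alpha, median
#' lambda across outer folds).
#'
#' @param features numeric matrix (samples x predictors); standardized
#'   internally (glmnet's own standardization).
#' @param outcome binary vector (0/1).
#' @param outer,inner fold counts for the nested loops (default 10 x 10).
#' @param repeats number of repeats of the whole outer loop (out-of-fold
#'   probabilities averaged across repeats); default 1.
#' @param alphas grid of elastic-net mixing values searched in the inner
#'   loop.
#' @param seed integer; fixes fold assignment and glmnet's internal
#'   randomness so reruns are identical.
#' @return list with `selected_features`, `coefficients` (named, no
#'   intercept), `intercept`, `shap` (samples x selected features),
#'   `cv_predictions` (honest out-of-fold probabilities),
#'   `insample_predictions`, `auc_cv`, `auc_insample`, `alpha`, `lambda`,
#'   `cv_spec`.
#' @export
nested_cv_enr <- function(features, outcome, outer = 10, inner = 10,
                          repeats = 1, alphas = seq(0.1, 0.9, by = 0.2),
                          seed = 1L) {
  features <- as.matrix(features)
  outcome <- as.integer(outcome)
  stopifnot(nrow(features) == length(outcome), all(outcome %in% 0:1))
  if (all(apply(features, 2, stats::sd) == 0))
    stop("all-constant feature matrix")
  if (min(table(outcome)) < outer) stop("degenerate folds: too few events")
  n <- nrow(features)
  with_seed(seed, {
    pred_sum <- numeric(n)
    picked_alpha <- c(); picked_lambda <- c()
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(outcome, outer)
      for (f in seq_len(outer)) {
        tr <- fold != f
        Xtr <- features[tr, , drop = FALSE]; ytr <- outcome[tr]
        inner_id <- .stratified_folds(ytr, inner)
        best <- NULL
        for (a in alphas) {
          cvf <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial",
                                   alpha = a, foldid = inner_id,
                                   type.measure = "deviance")
          cvm <- min(cvf$cvm)
          if (is.null(best) || cvm < best$cvm)
            best <- list(cvm = cvm, alpha = a, lambda = cvf$lambda.min)
        }
        fit <- glmnet::glmnet(Xtr, ytr, family = "binomial",
                              alpha = best$alpha, lambda = best$lambda)
        pred_sum[fold == f] <- pred_sum[fold == f] +
          as.numeric(stats::predict(fit, features[fold == f, , drop = FALSE],
                                    type = "response"))
        picked_alpha <- c(picked_alpha, best$alpha)
        picked_lambda <- c(picked_lambda, best$lambda)
      }
    }
    cv_pred <- pred_sum / repeats
    alpha_hat <- as.numeric(names(sort(table(picked_alpha),
                                       decreasing = TRUE))[1])
    lambda_hat <- stats::median(picked_lambda)
    final <- glmnet::glmnet(features, outcome, family = "binomial",
                            alpha = alpha_hat, lambda = lambda_hat)
    beta <- as.numeric(final$beta)
    names(beta) <- rownames(final$beta)
    sel <- names(beta)[beta != 0]
    ins_pred <- as.numeric(stats::predict(final, features,
                                          type = "response"))
    shap <- shap_linear(beta[sel], features[, sel, drop = FALSE])
    list(selected_features = sel,
         coefficients = beta[sel],
         intercept = as.numeric(final$a0),
         shap = shap,
         cv_predictions = cv_pred,
         insample_predictions = ins_pred,
         auc_cv = roc_auc(cv_pred, outcome),
         auc_insample = roc_auc(ins_pred, outcome),
         alpha = alpha_hat, lambda = lambda_hat,
         cv_spec = list(outer = outer, inner = inner, repeats = repeats,
                        seed = seed))
  })
}

#' Exact SHAP attributions for a linear model
#'
#' For an additive model under feature independence the Shapley value of
#' feature j for sample i is `phi_ij = coef_j * (x_ij - mean_j)` exactly,
#' so each row of attributions sums to the linear predictor minus its
#' mean (the efficiency property). Feature importance is the mean
#' absolute attribution per feature.
#'
#' @param coefficients named numeric vector (no intercept).
#' @param features numeric matrix with matching columns.
#' @return samples x features matrix of attributions, with an attribute
#'   `importance` (named mean absolute attribution).
#' @export
shap_linear <- function(coefficients, features) {
  features <- as.matrix(features)
  if (length(coefficients) != ncol(features))
    stop("feature/model dimension mismatch")
  centered <- sweep(features, 2, colMeans(features))
  phi <- sweep(centered, 2, coefficients, `*`)
  attr(phi, "importance") <- sort(colMeans(abs(phi)), decreasing = TRUE)
  phi
}

#' Area under the ROC curve via the Mann-Whitney identity
#'
#' Concordance probability between predictions of cases and non-cases,
#' with the average-rank tie correction (ties count 1/2).
#'
#' @param predictions numeric vector of scores or probabilities.
#' @param outcome binary vector (0/1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predictions, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(predictions)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a percentile bootstrap confidence interval
#'
#' Resamples (prediction, label) pairs with replacement; iterations in
#' which a class vanishes are redrawn. The 95% interval is the 2.5/97.5
#' percentile of the bootstrap AUC distribution.
#'
#' @param predictions numeric vector.
#' @param outcome binary vector (0/1).
#' @param n_boot bootstrap iterations (default 10,000).
#' @param seed integer seed for the resampling.
#' @return list with `auc` and `ci95` (length-2 vector).
#' @export
roc_auc_ci <- function(predictions, outcome, n_boot = 10000, seed = 1L) {
  outcome <- as.integer(outcome)
  auc <- roc_auc(predictions, outcome)
  n <- length(outcome)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(outcome[idx])) == 2) break
      }
      roc_auc(predictions[idx], outcome[idx])
    }, numeric(1))
  })
  list(auc = auc,
       ci95 = unname(stats::quantile(boot, c(0.025, 0.975))))
}

#' DeLong test for the difference of two correlated AUCs
#'
#' Compares two prediction vectors evaluated on the same samples and
#' labels via the DeLong test for paired ROC curves (two-sided).
#'
#' @param pred_a,pred_b numeric prediction vectors on the same samples.
#' @param outcome binary vector (0/1).
#' @return two-sided p-value for the AUC difference.
#' @export
compare_auc <- function(pred_a, pred_b, outcome) {
  if (length(pred_a) != length(pred_b) ||
      length(pred_a) != length(outcome))
    stop("prediction vectors and labels must have equal length")
  if (isTRUE(all.equal(pred_a, pred_b))) return(1)
  r1 <- pROC::roc(outcome, pred_a, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(outcome, pred_b, quiet = TRUE, direction = "<")
  as.numeric(pROC::roc.test(r1, r2, method = "delong",
                            paired = TRUE)$p.value)
}
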