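#' @keywords internal
.assoc_row <- function(feature, exposure, beta, se, p, n, effect_measure,
                       model_id = NA_integer_, converged = TRUE) {
  exp_scale <- effect_measure %in% c("OR", "RR")
  data.frame(feature = feature, exposure = exposure,
             beta = beta, se = se, p = p, q = NA_real_, n = n,
             effect_measure = effect_measure,
             effect = if (exp_scale) exp(beta) else beta,
             ci_lo = if (exp_scale) exp(beta - 1.96 * se) else beta - 1.96 * se,
             ci_hi = if (exp_scale) exp(beta + 1.96 * se) else beta + 1.96 * se,
             model_id = model_id, converged = converged,
             stringsAsFactors = FALSE)
}

#' Logistic regression of a binary outcome on one exposure
#'
#' Maximum-likelihood logistic fit of `outcome ~ exposure + covariates`;
#' the exposure coefficient is reported as a log odds ratio with a Wald
#' 95% CI. Fits flagged as non-converged (including separation) are
#' marked unusable via `converged = FALSE` rather than silently returned.
#'
#' @param outcome binary vector (0/1).
#' @param exposure numeric vector (e.g. a species CLR value or a
#'   standardized metabolite).
#' @param covariates optional numeric design block (samples x k).
#' @param feature,exposure_id identifiers carried into the result.
#' @param model_id adjustment-model tag (1, 2 or 3).
#' @return one-row data.frame (an association result).
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         feature = "feature", exposure_id = "exposure",
                         model_id = NA_integer_) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome must contain both classes")
  dat <- data.frame(.y = outcome, .x = exposure)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- stats::complete.cases(dat) & (if (is.null(X)) TRUE else
    stats::complete.cases(X))
  dat <- dat[ok, , drop = FALSE]
  form <- if (is.null(X)) .y ~ .x else .y ~ .x + X[ok, , drop = FALSE]
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  conv <- fit$converged && co[".x", "Std. Error"] < 100
  .assoc_row(feature, exposure_id, co[".x", 1], co[".x", 2], co[".x", 4],
             nrow(dat), "OR", model_id, converged = conv)
}

#' Linear metabolome-wide association of one metabolite with one exposure
#'
#' Ordinary least squares of an INT-transformed metabolite on a species
#' CLR exposure plus covariates; the slope is per CLR unit.
#'
#' @param metabolite numeric vector of INT-transformed levels.
#' @param exposure numeric vector (species CLR).
#' @param covariates optional numeric design block.
#' @param feature,exposure_id,model_id identifiers carried into the result.
#' @return one-row data.frame (an association result).
#' @export
fit_linear_mwaa <- function(metabolite, exposure, covariates = NULL,
                            feature = "metabolite",
                            exposure_id = "exposure",
                            model_id = NA_integer_) {
  X <- cbind(`(Intercept)` = 1, exposure = exposure, covariates)
  ok <- stats::complete.cases(X) & !is.na(metabolite)
  X <- X[ok, , drop = FALSE]
  y <- metabolite[ok]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design")
  cf <- qr.coef(qrX, y)
  res <- y - X %*% cf
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * chol2inv(qr.R(qrX))[2, 2])
  p <- 2 * stats::pt(-abs(cf[2] / se), df)
  .assoc_row(feature, exposure_id, unname(cf[2]), se, p, length(y),
             "linear", model_id)
}

#' Metabolome-wide association analysis for one exposure
#'
#' Runs [fit_linear_mwaa()] across every metabolite column against a
#' single exposure, sharing one design projection across metabolites
#' (identical values, vectorized), and applies BH correction across the
#' metabolome — one FDR family per exposure.
#'
#' @param metabolites samples x metabolites numeric matrix
#'   (INT-transformed) or `feature_table` of kind `int_transformed`.
#' @param exposure numeric vector.
#' @param covariates optional numeric design block.
#' @param exposure_id,model_id identifiers carried into the result.
#' @return data.frame with one row per metabolite, BH `q` filled in.
#' @export
mwaa <- function(metabolites, exposure, covariates = NULL,
                 exposure_id = "exposure", model_id = NA_integer_) {
  if (inherits(metabolites, "feature_table")) metabolites <- metabolites$values
  X <- cbind(`(Intercept)` = 1, exposure = exposure, covariates)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  Y <- metabolites[ok, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design")
  XtXinv <- chol2inv(qr.R(qrX))
  coefs <- XtXinv %*% crossprod(X, Y)
  R <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  s2 <- colSums(R^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  beta <- coefs[2, ]
  p <- 2 * stats::pt(-abs(beta / se), df)
  out <- .assoc_row(colnames(Y), exposure_id, unname(beta), unname(se),
                    unname(p), nrow(X), "linear", model_id)
  out$q <- bh_fdr(out$p)
  out
}

#' Modified Poisson regression for relative risk of a common binary outcome
#'
#' Poisson GLM with log link applied to a binary outcome, with standard
#' errors from the robust HC0 sandwich estimator; the exponentiated
#' exposure coefficient estimates the relative risk. This is the standard
#' approach for prospective analyses where the outcome is common enough
#' that odds ratios overstate risk ratios.
#'
#' @param outcome binary vector (0/1), e.g. incident disease among
#'   baseline-negative subjects.
#' @param exposure numeric vector.
#' @param covariates optional numeric design block.
#' @param feature,exposure_id,model_id identifiers carried into the result.
#' @param hc one of `"HC0"` (default, no small-sample correction) or
#'   `"HC1"`.
#' @return one-row data.frame (an association result, `effect_measure =
#'   "RR"`).
#' @export
modified_poisson <- function(outcome, exposure, covariates = NULL,
                             feature = "feature", exposure_id = "exposure",
                             model_id = NA_integer_, hc = c("HC0", "HC1")) {
  hc <- match.arg(hc)
  outcome <- as.integer(outcome)
  if (all(outcome == 0, na.rm = TRUE)) stop("no events in outcome")
  dat <- data.frame(.y = outcome, .x = exposure)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- stats::complete.cases(dat) & (if (is.null(X)) TRUE else
    stats::complete.cases(X))
  dat <- dat[ok, , drop = FALSE]
  form <- if (is.null(X)) .y ~ .x else .y ~ .x + X[ok, , drop = FALSE]
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::poisson()))
  if (!fit$converged) stop("modified Poisson fit did not converge")
  vc <- sandwich::vcovHC(fit, type = hc)
  beta <- stats::coef(fit)[".x"]
  se <- sqrt(vc[".x", ".x"])
  p <- 2 * stats::pnorm(-abs(beta / se))
  .assoc_row(feature, exposure_id, unname(beta), se, unname(p),
             nrow(dat), "RR", model_id)
}

#' DerSimonian-Laird random-effects meta-analysis of two or more estimates
#'
#' Pools per-set coefficients with inverse-variance weights
#' `1 / (SE^2 + tau^2)`, where the between-set variance `tau^2` is the
#' non-iterative DerSimonian-Laird moment estimator floored at zero.
#' The retention rule applied downstream keeps a feature when the pooled
#' p-value is below 0.05 *and* the set-level coefficients agree in sign
#' (directional concordance across discovery and validation).
#'
#' @param beta,se numeric vectors of per-set estimates and standard
#'   errors (same length, >= 2; the first two sets drive the concordance
#'   flag).
#' @param feature identifier carried into the result.
#' @return one-row data.frame with `beta_pooled`, `se_pooled`, `tau2`,
#'   `p_pooled`, per-set directions, `concordant` and `retained`.
#' @export
random_effects_meta <- function(beta, se, feature = "feature") {
  stopifnot(length(beta) == length(se), length(beta) >= 2)
  if (any(se <= 0) || any(!is.finite(se))) stop("all SEs must be positive and finite")
  w <- 1 / se^2
  beta_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_fe)^2)
  k <- length(beta)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / denom)
  w_re <- 1 / (se^2 + tau2)
  bp <- sum(w_re * beta) / sum(w_re)
  sp <- sqrt(1 / sum(w_re))
  p <- 2 * stats::pnorm(-abs(bp / sp))
  concordant <- sign(beta[1]) == sign(beta[2]) && all(beta[1:2] != 0)
  data.frame(feature = feature, beta_pooled = bp, se_pooled = sp,
             tau2 = tau2, p_pooled = p,
             direction_discovery = sign(beta[1]),
             direction_validation = sign(beta[2]),
             concordant = concordant,
             retained = concordant && p < 0.05,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values with monotonicity enforced (as implemented in
#' `stats::p.adjust`).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Linear trend of species abundance across ordinal disease grades
#'
#' Regresses CLR abundance on the grade coded as an integer score
#' (0, 1, 2, 3) plus covariates, reporting the slope and trend p-value.
#'
#' @param species_clr numeric vector of CLR abundances.
#' @param grade integer vector of grades 0-3.
#' @param covariates optional numeric design block.
#' @param feature identifier carried into the result.
#' @return one-row data.frame (an association result, linear).
#' @export
grade_trend <- function(species_clr, grade, covariates = NULL,
                        feature = "species") {
  grade <- as.numeric(grade)
  if (length(unique(grade[!is.na(grade)])) < 2)
    stop("at least 2 distinct grades are required")
  fit_linear_mwaa(species_clr, grade, covariates, feature = feature,
                  exposure_id = "lvdd_grade")
}

#' Covariate-adjusted partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariates; the p-value uses a t reference distribution
#' with `n - k - 2` degrees of freedom (k = number of covariate columns).
#' With no covariates this reduces to the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric design block.
#' @return list with `r` and `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  X <- cbind(`(Intercept)` = rep(1, length(x)), covariates)
  ok <- stats::complete.cases(X) & !is.na(x) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  n <- sum(ok)
  k <- ncol(X) - 1
  if (n <= k + 3) stop("too few samples for the requested adjustment")
  rx <- stats::lm.fit(X, x[ok])$residuals
  ry <- stats::lm.fit(X, y[ok])$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance")
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df))
}
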