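#' Prevalence filter for taxa and KO tables
#'
#' Retains features observed (nonzero, non-missing) in strictly more than
#' `threshold` of samples — e.g. at the default species setting, a
#' feature present in 21 of 100 samples passes a 20% filter, one present
#' in exactly 20 does not.
#'
#' @param table a `feature_table` of kind counts/relabund/ko_relabund.
#' @param threshold prevalence fraction in (0,1).
#' @return list with `table` (filtered `feature_table`) and `report`
#'   (a transform report: counts, rule, per-feature pass flags).
#' @export
filter_by_prevalence <- function(table, threshold = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$kind %in% c("counts", "relabund", "ko_relabund", "intensity"))
    stop("prevalence filtering applies to abundance-like tables")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  v <- table$values
  n <- nrow(v)
  prev <- colSums(v > 0 & !is.na(v)) / n
  pass <- prev > threshold
  out <- ft_subset(table, features = colnames(v)[pass])
  report <- list(features_in = ncol(v), features_out = sum(pass),
                 rule = sprintf("present in > %.0f%% of %d samples",
                                100 * threshold, n),
                 pass = pass, prevalence = prev)
  list(table = out, report = report)
}

#' Filter KO gene families on prevalence with a relative-abundance floor
#'
#' A sample counts toward a KO's prevalence only where its relative
#' abundance is at least `relabund_floor`; KOs pass when such samples
#' exceed `prev_threshold` of all samples. The defaults (20% prevalence,
#' 0.001% = 1e-5 floor) match the functional-analysis inclusion rule.
#'
#' @param table a `feature_table` of kind `ko_relabund`.
#' @param prev_threshold prevalence fraction in (0,1).
#' @param relabund_floor minimum relative abundance (fraction) to count.
#' @return list with `table` and `report`, as [filter_by_prevalence()].
#' @export
filter_kos <- function(table, prev_threshold = 0.20, relabund_floor = 1e-5) {
  stopifnot(inherits(table, "feature_table"))
  if (table$kind != "ko_relabund") stop("filter_kos expects a ko_relabund table")
  if (relabund_floor <= 0) stop("relabund_floor must be positive")
  if (prev_threshold <= 0 || prev_threshold >= 1)
    stop("prev_threshold must be in (0,1)")
  v <- table$values
  n <- nrow(v)
  prev <- colSums(v >= relabund_floor & !is.na(v)) / n
  pass <- prev > prev_threshold
  out <- ft_subset(table, features = colnames(v)[pass])
  report <- list(features_in = ncol(v), features_out = sum(pass),
                 rule = sprintf(
                   "relative abundance >= %g in > %.0f%% of %d samples",
                   relabund_floor, 100 * prev_threshold, n),
                 pass = pass, prevalence = prev)
  list(table = out, report = report)
}

#' Centered log-ratio transform
#'
#' Per sample, each value becomes `log(x + pseudocount)` minus the mean of
#' those logs across the retained features, so every transformed sample
#' sums to zero. The pseudocount handles sampling zeros; with no zeros it
#' may be 0, in which case the transform is invariant to per-sample
#' rescaling of the composition.
#'
#' @param table a `feature_table` of kind counts or relabund.
#' @param pseudocount nonnegative offset; must be positive when zeros are
#'   present.
#' @return a `feature_table` of kind `clr`.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$kind %in% c("counts", "relabund"))
    stop("clr_transform expects counts or relative abundances")
  v <- table$values
  if (any(rowSums(v, na.rm = TRUE) == 0)) stop("all-zero sample(s) present")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(v == 0, na.rm = TRUE))
    stop("zeros present: a positive pseudocount is required")
  lg <- log(v + pseudocount)
  clr <- lg - rowMeans(lg)
  out <- table
  out$values <- clr
  out$kind <- "clr"
  out
}

#' Rank-based inverse normal transform with half-minimum imputation
#'
#' Values flagged below the detection limit (NA entries) are replaced by
#' half the minimum detected value, then ranks (average ranks for ties)
#' are mapped through the standard normal quantile function with the Blom
#' offset: `qnorm((rank - 3/8) / (n + 1/4))`.
#'
#' @param values numeric vector; NA marks a below-detection measurement.
#' @return numeric vector of the same length; an attribute
#'   `half_minimum` records the imputation value used (NA when nothing
#'   was imputed).
#' @export
inverse_normal_transform <- function(values) {
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("all values are below detection")
  if (length(values) < 3) stop("at least 3 values are required")
  hm <- NA_real_
  if (anyNA(values)) {
    hm <- min(obs) / 2
    values[is.na(values)] <- hm
  }
  r <- rank(values, ties.method = "average")
  n <- length(values)
  out <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  attr(out, "half_minimum") <- hm
  out
}

#' Inverse normal transform of a whole intensity table
#'
#' Applies [inverse_normal_transform()] to each metabolite column.
#'
#' @param table a `feature_table` of kind `intensity` (NA = below
#'   detection).
#' @return list with `table` (kind `int_transformed`) and `report`
#'   carrying the per-metabolite half-minimum imputation values.
#' @export
int_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$kind != "intensity") stop("int_transform expects an intensity table")
  v <- table$values
  hm <- numeric(ncol(v))
  out <- v
  for (j in seq_len(ncol(v))) {
    tj <- inverse_normal_transform(v[, j])
    hm[j] <- attr(tj, "half_minimum")
    out[, j] <- tj
  }
  names(hm) <- colnames(v)
  res <- table
  res$values <- out
  res$kind <- "int_transformed"
  list(table = res,
       report = list(features_in = ncol(v), features_out = ncol(v),
                     rule = "half-minimum imputation + Blom INT",
                     half_minimum = hm))
}

#' Detection-rate filter for metabolite intensity tables
#'
#' Retains metabolites detected (non-missing) in strictly more than
#' `threshold` of samples; the default mirrors the 75% detection rule.
#'
#' @param table a `feature_table` of kind `intensity`.
#' @param threshold detection fraction in (0,1).
#' @return list with `table` and `report`.
#' @export
filter_by_detection <- function(table, threshold = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  if (table$kind != "intensity")
    stop("filter_by_detection expects an intensity table")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  v <- table$values
  det <- colSums(!is.na(v)) / nrow(v)
  pass <- det > threshold
  out <- ft_subset(table, features = colnames(v)[pass])
  list(table = out,
       report = list(features_in = ncol(v), features_out = sum(pass),
                     rule = sprintf("detected in > %.0f%% of samples",
                                    100 * threshold),
                     pass = pass, detection = det))
}
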