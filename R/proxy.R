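#' Standardize association results to Z-scores
#'
#' Z = beta / SE for each feature, order-aligned with the input's feature
#' ids.
#'
#' @param results data.frame of association results (columns `feature`,
#'   `beta`, `se`).
#' @return named numeric vector of Z-scores.
#' @export
to_zscores <- function(results) {
  stopifnot(all(c("feature", "beta", "se") %in% names(results)))
  if (any(!is.finite(results$beta)) || any(results$se <= 0) ||
      any(!is.finite(results$se)))
    stop("Z-scores require finite beta and positive finite SE")
  stats::setNames(results$beta / results$se, results$feature)
}

#' Metabolite-mediated proxy association of a species with incident disease
#'
#' Correlates, over a shared panel of metabolites, the Z-scores from
#' metabolite-species associations with the Z-scores from
#' metabolite-incident-disease associations (Spearman, average ranks for
#' ties). A significant correlation (p < 0.05) is read as an indirect
#' (proxy) association of the species with incident disease: negative
#' when the species' metabolite signature opposes the risk signature.
#' Only metabolites significantly associated with the incident outcome
#' should enter the panel; all such metabolites enter every species'
#' test.
#'
#' The p-value is exact (enumeration over permutations, via
#' `stats::cor.test`) for panels of at most `exact_max` metabolites
#' without ties, and uses the t approximation otherwise.
#'
#' @param z_species named Z-score vector from metabolite-species models.
#' @param z_outcome named Z-score vector from metabolite-outcome models,
#'   over the same metabolites (matched by name when both are named).
#' @param species_id identifier carried into the result.
#' @param exact_max largest panel size for which the exact permutation
#'   p-value is used (default 9).
#' @return one-row data.frame with `species`, `R`, `p`, `k`,
#'   `significant`, and the metabolite ids as an attribute
#'   `metabolites`.
#' @export
proxy_association <- function(z_species, z_outcome, species_id = "species",
                              exact_max = 9) {
  if (!is.null(names(z_species)) && !is.null(names(z_outcome))) {
    if (!setequal(names(z_species), names(z_outcome)))
      stop("the two Z vectors must cover the same metabolites")
    z_outcome <- z_outcome[names(z_species)]
  } else if (length(z_species) != length(z_outcome)) {
    stop("Z vectors must have equal length")
  }
  k <- length(z_species)
  if (k < 3) stop("at least 3 metabolites are required")
  if (stats::sd(z_species) == 0 || stats::sd(z_outcome) == 0)
    stop("constant Z vector")
  ties <- anyDuplicated(z_species) || anyDuplicated(z_outcome)
  exact <- k <= exact_max && !ties
  ct <- suppressWarnings(
    stats::cor.test(z_species, z_outcome, method = "spearman",
                    exact = exact))
  out <- data.frame(species = species_id, R = unname(ct$estimate),
                    p = ct$p.value, k = k,
                    significant = ct$p.value < 0.05,
                    exact = exact, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "metabolites") <- names(z_species)
  out
}
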