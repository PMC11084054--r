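#' Covariate sets for the three adjustment models
#'
#' Model 1 adjusts for sociodemographic and lifestyle covariates; Model 2
#' adds body-mass index and systolic blood pressure; Model 3 further adds
#' the three medication-use indicators. The nesting is enforced by
#' construction from this single registry. The species discovery stage
#' (ANCOM-II) uses its own reduced set, and the metabolite-outcome models
#' drop the antibiotic/probiotic indicator because metabolome sampling is
#' not concurrent with stool collection.
#'
#' @param model 1, 2 or 3, or one of the named sets `"ancom"` /
#'   `"metabolite"`.
#' @return character vector of metadata column names.
#' @export
model_covariates <- function(model = 1) {
  base1 <- c("age", "sex", "center", "education", "income", "smoking",
             "alcohol", "physical_activity", "ahei2010",
             "abx_probiotic_use")
  if (identical(model, "ancom"))
    return(c("age", "sex", "center", "abx_probiotic_use"))
  if (identical(model, "metabolite"))
    return(setdiff(base1, "abx_probiotic_use"))
  model <- as.integer(model)
  if (!model %in% 1:3) stop("model must be 1, 2, 3, 'ancom' or 'metabolite'")
  out <- base1
  if (model >= 2) out <- c(out, "bmi", "sbp")
  if (model >= 3) out <- c(out, "med_antidiabetic", "med_antihypertensive",
                           "med_lipidlowering")
  out
}

# Columns treated as unordered factors when building design matrices.
.factor_covariates <- c("center", "education", "income", "smoking", "alcohol")

#' Build a covariate design-matrix block from sample metadata
#'
#' Categorical covariates are dummy-coded; the intercept column is not
#' included. Errors if any requested covariate is missing for an included
#' sample, per the analysis contract that covariates must be complete.
#'
#' @param meta sample metadata data.frame.
#' @param covariates character vector of column names.
#' @return numeric matrix with one row per sample.
#' @export
covariate_matrix <- function(meta, covariates) {
  if (!length(covariates)) return(matrix(nrow = nrow(meta), ncol = 0))
  missing <- setdiff(covariates, names(meta))
  if (length(missing))
    stop("metadata lacks covariate column(s): ",
         paste(missing, collapse = ", "))
  sub <- meta[, covariates, drop = FALSE]
  if (anyNA(sub))
    stop("missing covariate values among included samples: ",
         paste(covariates[vapply(sub, anyNA, logical(1))], collapse = ", "))
  for (v in intersect(covariates, .factor_covariates))
    sub[[v]] <- factor(sub[[v]])
  mm <- stats::model.matrix(~ ., data = sub)
  mm[, -1, drop = FALSE]
}

#' Validate a sample-metadata table
#'
#' Checks the internal consistency rules tying the LVDD labels together:
#' a positive grade (1-3) iff prevalent disease, and incident status
#' defined only among prevalent-negative subjects.
#'
#' @param meta data.frame with at least `sample_id`, `prevalent_lvdd`,
#'   `lvdd_grade` and (optionally) `incident_lvdd` columns.
#' @return `meta`, invisibly, after validation.
#' @export
validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (all(c("prevalent_lvdd", "lvdd_grade") %in% names(meta))) {
    ok <- !is.na(meta$prevalent_lvdd) & !is.na(meta$lvdd_grade)
    if (any((meta$lvdd_grade[ok] > 0) != (meta$prevalent_lvdd[ok] == 1)))
      stop("lvdd_grade > 0 must coincide with prevalent_lvdd == 1")
  }
  if (all(c("prevalent_lvdd", "incident_lvdd") %in% names(meta))) {
    bad <- !is.na(meta$incident_lvdd) & meta$prevalent_lvdd == 1
    if (any(bad, na.rm = TRUE))
      stop("incident_lvdd must be defined only where prevalent_lvdd == 0")
  }
  invisible(meta)
}

#' Run configuration
#'
#' Holds every threshold and stochastic setting of the pipeline so a run
#' is fully described by one object. Defaults mirror the analysis
#' settings: 20% species prevalence, 75% metabolite detection, KO floor
#' 0.001% relative abundance at 20% prevalence, FDR 0.1, 10 x 10-fold
#' nested cross-validation, 10,000 bootstrap iterations.
#'
#' @param species_prevalence,metabolite_detection,ko_prevalence fractions
#'   in (0,1).
#' @param ko_floor minimum relative abundance (fraction, 1e-5 = 0.001%)
#'   for a sample to count toward KO prevalence.
#' @param pseudocount added to counts before log-ratio work.
#' @param fdr_level BH false-discovery-rate level.
#' @param model_id covariate model for the final quantification (1, 2, 3).
#' @param cv_outer,cv_inner,cv_repeats nested-CV geometry.
#' @param n_boot bootstrap iterations for AUC confidence intervals.
#' @param ancom_alpha,ancom_cutoff,structural_threshold ANCOM-II settings.
#' @param seed integer seed owned by the run; all stochastic steps derive
#'   from it.
#' @return a list with class `run_config`.
#' @export
run_config <- function(species_prevalence = 0.20,
                       metabolite_detection = 0.75,
                       ko_prevalence = 0.20,
                       ko_floor = 1e-5,
                       pseudocount = 0.5,
                       fdr_level = 0.1,
                       model_id = 1,
                       cv_outer = 10, cv_inner = 10, cv_repeats = 1,
                       n_boot = 10000,
                       ancom_alpha = 0.05, ancom_cutoff = 0.7,
                       structural_threshold = 0.99,
                       seed = 1L) {
  for (th in c(species_prevalence, metabolite_detection, ko_prevalence,
               fdr_level, ancom_cutoff, structural_threshold))
    if (!is.numeric(th) || th <= 0 || th >= 1)
      stop("thresholds must lie strictly in (0, 1)")
  if (ko_floor <= 0) stop("ko_floor must be positive")
  structure(list(species_prevalence = species_prevalence,
                 metabolite_detection = metabolite_detection,
                 ko_prevalence = ko_prevalence, ko_floor = ko_floor,
                 pseudocount = pseudocount, fdr_level = fdr_level,
                 model_id = model_id, cv_outer = cv_outer,
                 cv_inner = cv_inner, cv_repeats = cv_repeats,
                 n_boot = n_boot, ancom_alpha = ancom_alpha,
                 ancom_cutoff = ancom_cutoff,
                 structural_threshold = structural_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stage-tagged logging to stderr; level gate via option gutlvdd.log_level
# (one of "debug", "info", "warn", "quiet").
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

log_msg <- function(stage, ..., level = "info") {
  gate <- getOption("gutlvdd.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[gate]]) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations route through
# this so a run_config seed gives byte-identical outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
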