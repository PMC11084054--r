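test_that("identical seeds give identical cohorts", {
  cfg <- small_cohort_config()
  a <- generate_cohort(cfg, seed = 99)
  b <- generate_cohort(cfg, seed = 99)
  expect_identical(a$species$values, b$species$values)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(a$kos$values, b$kos$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$da_species, b$truth$da_species)
  c <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$species$values, c$species$values))
})

test_that("generated cohorts satisfy the metadata and table invariants", {
  co <- generate_cohort(small_cohort_config(), seed = 5)
  expect_silent(validate_metadata(co$meta))
  expect_true(all((co$meta$lvdd_grade > 0) == (co$meta$prevalent_lvdd == 1)))
  expect_true(all(is.na(co$meta$incident_lvdd[co$meta$prevalent_lvdd == 1])))
  expect_true(all(co$meta$set_discovery != co$meta$set_validation))
  expect_lt(max(abs(rowSums(co$kos$values) - 1)), 1e-8)
  expect_true(all(co$species$values >= 0))
  # censored intensities are explicit missing, never zero
  expect_true(anyNA(co$metabolites$values))
  expect_true(all(co$metabolites$values > 0, na.rm = TRUE))
  # every planted edge references an existing feature
  edges <- co$truth$species_metabolite_edges
  expect_true(all(edges$species %in% feature_ids(co$species)))
  expect_true(all(edges$metabolite %in% feature_ids(co$metabolites)))
  expect_true(all(edges$effect != 0))
})

test_that("full-scale defaults reproduce the target marginal rates", {
  co <- generate_cohort(default_paper_scale(), seed = 202)
  prev <- mean(co$meta$prevalent_lvdd)
  expect_gt(prev, 0.459 - 0.03)
  expect_lt(prev, 0.459 + 0.03)
  fu <- !is.na(co$meta$incident_lvdd)
  inc <- mean(co$meta$incident_lvdd[fu])
  expect_gt(inc, 212 / 594 - 0.05)
  expect_lt(inc, 212 / 594 + 0.05)
  filt <- filter_by_prevalence(co$species, 0.20)
  expect_gte(filt$report$features_out, 0.8 * filt$report$features_in)
})

test_that("a zero-effect cohort carries no species-outcome signal", {
  co <- generate_cohort(cohort_config(n = 400, n_species = 200,
                                      n_metabolites = 10, n_kos = 5,
                                      n_assoc_metabolites = 5,
                                      n_prevalent_metabolites = 3,
                                      n_incident_metabolites = 3,
                                      n_structural = 0, n_ko_per_proxy = 0,
                                      effect_multiplier = 0), seed = 31)
  clr <- clr_transform(co$species, 0.5)$values
  p <- vapply(seq_len(ncol(clr)), function(j) {
    summary(stats::glm(co$meta$prevalent_lvdd ~ clr[, j],
                       family = stats::binomial()))$coefficients[2, 4]
  }, numeric(1))
  frac <- mean(p < 0.05)
  # binomial band around the nominal level over 200 features
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_identical(length(co$truth$da_species), 0L)
})

test_that("a planted unit log-odds species effect is recovered by logistic fit", {
  cfg <- cohort_config(n = 1000, n_species = 40, n_metabolites = 10,
                       n_kos = 5, n_assoc_metabolites = 5,
                       n_prevalent_metabolites = 3,
                       n_incident_metabolites = 3, n_structural = 0,
                       n_da_species = 1, species_effect = 1.0,
                       metab_prevalent_effect = 0, n_ko_per_proxy = 0)
  co <- generate_cohort(cfg, seed = 77)
  sp <- names(co$truth$da_species)
  expect_equal(unname(co$truth$da_species[sp]), 1.0)
  clr <- clr_transform(co$species, 0.5)$values
  x <- as.numeric(scale(clr[, sp]))
  # adjust for the covariates that truly enter the risk model
  covs <- cbind(scale(co$meta$age), co$meta$sex, scale(co$meta$bmi),
                scale(co$meta$sbp), co$meta$diabetes)
  fit <- fit_logistic(co$meta$prevalent_lvdd, x, covs, feature = sp)
  expect_lt(abs(fit$beta - 1.0), 3 * fit$se)
})

test_that("structural-zero species are hard-zeroed in the prevalent stratum", {
  co <- generate_cohort(small_cohort_config(), seed = 12)
  sz <- co$truth$structural_species
  expect_gte(length(sz), 1)
  cases <- co$meta$prevalent_lvdd == 1
  expect_true(all(co$species$values[cases, sz] == 0))
  expect_gt(mean(co$species$values[!cases, sz[1]] > 0), 0.5)
})

test_that("doubling a planted effect does not reduce recovery", {
  recover_freq <- function(effect, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- cohort_config(n = 300, n_species = 30, n_metabolites = 10,
                           n_kos = 5, n_assoc_metabolites = 5,
                           n_prevalent_metabolites = 3,
                           n_incident_metabolites = 3, n_structural = 0,
                           n_da_species = 1, species_effect = effect,
                           metab_prevalent_effect = 0, n_ko_per_proxy = 0)
      co <- generate_cohort(cfg, seed = s)
      sp <- names(co$truth$da_species)
      clr <- clr_transform(co$species, 0.5)$values
      fit <- fit_logistic(co$meta$prevalent_lvdd,
                          as.numeric(scale(clr[, sp])))
      fit$p < 0.05
    }, logical(1)))
  }
  seeds <- 1:12
  expect_gte(recover_freq(1.0, seeds), recover_freq(0.5, seeds))
})

test_that("write_cohort emits the TSV outputs plus ground truth JSON", {
  co <- generate_cohort(cohort_config(n = 60, n_species = 24,
                                      n_metabolites = 10, n_kos = 5,
                                      n_da_species = 3,
                                      n_assoc_metabolites = 4,
                                      n_prevalent_metabolites = 2,
                                      n_incident_metabolites = 2,
                                      n_structural = 0,
                                      n_ko_per_proxy = 1), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("species_counts.tsv", "metabolite_intensities.tsv",
                    "ko_relabund.tsv", "sample_metadata.tsv",
                    "ground_truth.json"))
  back <- read_feature_table(file.path(dir, "species_counts.tsv"), "counts")
  expect_equal(back$values, co$species$values, tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_named(gt$da_species, names(co$truth$da_species))
})
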