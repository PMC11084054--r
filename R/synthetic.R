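#' Settings for the synthetic cohort generator
#'
#' Defaults describe the full-scale study conditions the pipeline is
#' validated against: ~2,000 subjects; ~550 species before the 20%
#' prevalence filter; ~700 metabolites before the 75% detection filter,
#' left-censored at the 10th percentile; ~2,000 KO gene families; a
#' prevalent outcome rate of 45.9%; an incident rate of 35.7% among
#' baseline-negative subjects under follow-up; 7 planted differential
#' species (3 protective, 4 risk) of which three ("proxy species") carry
#' coherent metabolite signatures; 220 species-associated metabolites
#' containing nested subsets of 46 prevalent-associated and 21
#' incident-associated metabolites.
#'
#' @param n number of subjects (>= 50).
#' @param n_species species count before filtering (>= 10).
#' @param n_metabolites metabolite count before filtering.
#' @param n_kos KO gene-family count.
#' @param seq_depth mean sequencing depth per sample.
#' @param species_log_sd between-species SD of mean log abundance.
#' @param sample_log_sd within-species, between-sample SD of log
#'   abundance.
#' @param n_da_species planted differential species (first 3 protective
#'   when >= 3, remainder risk).
#' @param species_effect log-odds of prevalent disease per SD of CLR
#'   abundance for planted species.
#' @param n_structural species hard-zeroed in the prevalent stratum
#'   (structural zeros).
#' @param n_assoc_metabolites,n_prevalent_metabolites,n_incident_metabolites
#'   nested planted metabolite sets (species-associated > prevalent >
#'   incident).
#' @param metabolite_edge_range magnitude range of standardized
#'   species-to-metabolite slopes outside the incident panel.
#' @param metab_prevalent_effect log-odds of prevalent disease per SD of
#'   a prevalent-associated metabolite.
#' @param incident_logrr_range magnitude range of planted log relative
#'   risks per SD for incident-associated metabolites.
#' @param censor_quantile left-censoring quantile for metabolite
#'   intensities (below-detection entries become missing).
#' @param lowdetect_frac fraction of metabolites censored heavily (30%)
#'   so that the detection filter has something to remove.
#' @param n_ko_per_proxy planted KOs coupled to each proxy species.
#' @param ko_effect_range magnitude range of standardized species-to-KO
#'   slopes.
#' @param prevalent_rate,incident_rate target marginal outcome rates.
#' @param discovery_frac,concurrent_frac,baseline_v1_frac,followup_frac
#'   analysis-set membership fractions (discovery/validation partition;
#'   concurrent microbiome+metabolome subset; baseline-visit metabolome
#'   subset; follow-up among baseline-negative subjects).
#' @param effect_multiplier scales every planted effect; 0 produces a
#'   null cohort in which covariates still shape the outcomes.
#' @return a list with class `cohort_config`.
#' @export
cohort_config <- function(n = 2000,
                          n_species = 550,
                          n_metabolites = 700,
                          n_kos = 2042,
                          seq_depth = 25000,
                          species_log_sd = 2.0,
                          sample_log_sd = 1.0,
                          n_da_species = 7,
                          species_effect = 0.5,
                          n_structural = 2,
                          n_assoc_metabolites = 220,
                          n_prevalent_metabolites = 46,
                          n_incident_metabolites = 21,
                          metabolite_edge_range = c(0.12, 0.30),
                          metab_prevalent_effect = 0.25,
                          incident_logrr_range = c(0.10, 0.22),
                          censor_quantile = 0.10,
                          lowdetect_frac = 0.045,
                          n_ko_per_proxy = 40,
                          ko_effect_range = c(0.4, 0.7),
                          prevalent_rate = 0.459,
                          incident_rate = 212 / 594,
                          discovery_frac = 1508 / 1996,
                          concurrent_frac = 804 / 1996,
                          baseline_v1_frac = 1405 / 1996,
                          followup_frac = 0.55,
                          effect_multiplier = 1) {
  if (n < 50) stop("n must be at least 50")
  if (n_species < 10) stop("n_species must be at least 10")
  if (n_incident_metabolites > n_prevalent_metabolites ||
      n_prevalent_metabolites > n_assoc_metabolites ||
      n_assoc_metabolites > n_metabolites)
    stop("planted metabolite sets must be nested within the metabolome")
  if (n_da_species + n_structural > floor(n_species / 2))
    stop("infeasible config: planted + structural species must fit in ",
         "the abundant half of the species pool")
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_paper_scale <- function() cohort_config()

.super_pathways <- c("Lipid", "Amino Acid", "Xenobiotics", "Nucleotide",
                     "Carbohydrate", "Peptide", "Cofactors and Vitamins",
                     "Energy", "Partially Characterized Molecules")

# Calibrate an intercept so mean(link_inv(b0 + lp)) hits `target`.
.calibrate_intercept <- function(lp, target, inv) {
  f <- function(b0) mean(inv(b0 + lp)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Simulates, in order: covariates from simple parametric families;
#' compositional species counts from log-normal latent abundances pushed
#' through per-sample multinomials; metabolite latents as linear
#' combinations of planted species CLR values plus covariate effects and
#' Gaussian noise, exponentiated to intensities and left-censored; a
#' prevalent outcome from a logistic model on covariates, planted species
#' CLR values and planted metabolites (intercept calibrated to the target
#' rate); disease grades 1-3 among cases, monotone in the underlying risk
#' score; an incident outcome among baseline-negative subjects under
#' follow-up from a log-link Bernoulli model (so the true relative risk
#' is the exponent of the planted coefficient), capped at 0.95; KO
#' relative abundances coupled to their parent proxy species; and finally
#' hard structural zeroing of selected species within the prevalent
#' stratum.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with `species` (counts `feature_table`), `metabolites`
#'   (intensity `feature_table`, NA = below detection), `kos`
#'   (`ko_relabund` `feature_table`), `meta` (sample metadata
#'   data.frame) and `truth` (planted ground-truth record).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(seed, {
    n <- cfg$n
    ids <- sprintf("S%04d", seq_len(n))

    ## ---- covariates -------------------------------------------------
    age <- pmin(pmax(stats::rnorm(n, 59.4, 8), 45), 75)
    sex <- stats::rbinom(n, 1, 0.671)
    center <- sample(c("Bronx", "Chicago", "Miami", "SanDiego"), n, TRUE)
    education <- sample(c("lt_hs", "hs", "gt_hs"), n, TRUE,
                        prob = c(0.35, 0.3, 0.35))
    income <- sample(c("lt20k", "20to50k", "gt50k"), n, TRUE,
                     prob = c(0.4, 0.4, 0.2))
    smoking <- sample(c("never", "former", "current"), n, TRUE,
                      prob = c(0.6, 0.25, 0.15))
    alcohol <- sample(c("never", "former", "current"), n, TRUE,
                      prob = c(0.35, 0.25, 0.4))
    physical_activity <- stats::rgamma(n, shape = 1.5, scale = 400)
    ahei2010 <- stats::rnorm(n, 47, 7)
    abx <- stats::rbinom(n, 1, 0.07)
    bmi <- pmin(pmax(stats::rnorm(n, 29.5, 5), 17), 55)
    sbp <- pmin(pmax(stats::rnorm(n, 126, 16), 85), 210)
    ldl_c <- pmax(stats::rnorm(n, 120, 32), 35)
    diabetes <- stats::rbinom(n, 1, stats::plogis(-1.1 + 0.06 * (bmi - 29.5)))
    med_ahtn <- stats::rbinom(n, 1, stats::plogis(-1.2 + 0.035 * (sbp - 126)))
    med_adm <- ifelse(diabetes == 1, stats::rbinom(n, 1, 0.6), 0)
    med_llm <- stats::rbinom(n, 1, 0.22)
    z <- function(x) as.numeric(scale(x))

    ## ---- species counts --------------------------------------------
    m_sp <- cfg$n_species
    sp_ids <- sprintf("sp%04d", seq_len(m_sp))
    mu <- stats::rnorm(m_sp, 0, cfg$species_log_sd)
    lat <- matrix(stats::rnorm(n * m_sp, 0, cfg$sample_log_sd), n, m_sp)
    lat <- sweep(lat, 2, mu, `+`)
    pr <- exp(lat)
    pr <- pr / rowSums(pr)
    depth <- stats::rnbinom(n, mu = cfg$seq_depth, size = 5) + 500L
    counts <- matrix(0L, n, m_sp, dimnames = list(ids, sp_ids))
    for (s in seq_len(n))
      counts[s, ] <- stats::rmultinom(1, depth[s], pr[s, ])

    ## planted species: drawn from the abundant half so they survive the
    ## prevalence filter and carry informative CLR variation
    abundant <- order(mu, decreasing = TRUE)[seq_len(floor(m_sp / 2))]
    picks <- sample(abundant, cfg$n_da_species + cfg$n_structural)
    da_idx <- picks[seq_len(cfg$n_da_species)]
    struct_idx <- picks[-seq_len(cfg$n_da_species)]
    n_neg <- min(3, max(0, cfg$n_da_species - 1))
    da_sign <- c(rep(-1, n_neg), rep(1, cfg$n_da_species - n_neg))
    da_beta <- cfg$effect_multiplier * cfg$species_effect * da_sign
    # proxy species: two protective, one risk (when available)
    proxy_pos <- c(1, 2, n_neg + 1)[seq_len(min(3, cfg$n_da_species))]

    lg <- log(counts + 0.5)
    clr <- lg - rowMeans(lg)
    clr_std <- scale(clr[, da_idx, drop = FALSE])

    ## ---- metabolites ------------------------------------------------
    m_mb <- cfg$n_metabolites
    mb_ids <- sprintf("met%04d", seq_len(m_mb))
    k_inc <- cfg$n_incident_metabolites
    k_prev <- cfg$n_prevalent_metabolites
    k_assoc <- cfg$n_assoc_metabolites
    inc_set <- seq_len(k_inc)
    prev_set <- seq_len(k_prev)
    assoc_set <- seq_len(k_assoc)

    # incident log-RR per SD: one third protective, rest risk
    n_inc_neg <- floor(k_inc / 3)
    u <- cfg$effect_multiplier *
      c(-stats::runif(n_inc_neg, cfg$incident_logrr_range[1],
                      cfg$incident_logrr_range[2]),
        stats::runif(k_inc - n_inc_neg, cfg$incident_logrr_range[1],
                     cfg$incident_logrr_range[2]))
    u <- sample(u)  # shuffle sign placement over the panel

    W <- matrix(0, cfg$n_da_species, m_mb)  # standardized species->metab slopes
    if (cfg$effect_multiplier != 0 && cfg$n_da_species >= 1) {
      pA <- proxy_pos[1]
      # proxy species carry signatures anti-aligned (protective) or
      # aligned (risk) with the incident risk panel
      W[pA, inc_set] <- -1.0 * u + stats::rnorm(k_inc, 0, 0.05)
      if (length(proxy_pos) >= 2)
        W[proxy_pos[2], inc_set] <- -0.8 * u + stats::rnorm(k_inc, 0, 0.07)
      if (length(proxy_pos) >= 3)
        W[proxy_pos[3], inc_set] <- 0.9 * u + stats::rnorm(k_inc, 0, 0.07)
      other_assoc <- setdiff(assoc_set, inc_set)
      pri_prob <- rep(0.14 / max(1, cfg$n_da_species - 3), cfg$n_da_species)
      pri_prob[proxy_pos[1]] <- 0.40
      if (length(proxy_pos) >= 2) pri_prob[proxy_pos[2]] <- 0.20
      if (length(proxy_pos) >= 3) pri_prob[proxy_pos[3]] <- 0.26
      for (j in other_assoc) {
        k <- sample.int(cfg$n_da_species, 1, prob = pri_prob)
        W[k, j] <- cfg$effect_multiplier * sample(c(-1, 1), 1) *
          stats::runif(1, cfg$metabolite_edge_range[1],
                       cfg$metabolite_edge_range[2])
      }
      W[, setdiff(seq_len(m_mb), assoc_set)] <- 0
    }
    if (cfg$effect_multiplier == 0) W[] <- 0

    cov_mb <- cbind(z(age), sex - mean(sex), z(bmi))
    cov_beta <- matrix(stats::rnorm(3 * m_mb, 0, 0.05), 3, m_mb)
    mb_latent <- clr_std %*% W + cov_mb %*% cov_beta +
      matrix(stats::rnorm(n * m_mb), n, m_mb)
    mb_std <- scale(mb_latent)

    base_j <- stats::rnorm(m_mb, 10, 1)
    intensity <- exp(sweep(0.6 * mb_latent, 2, base_j, `+`))
    dimnames(intensity) <- list(ids, mb_ids)
    qs <- rep(cfg$censor_quantile, m_mb)
    # heavily censored metabolites are drawn outside the planted set, so
    # planted signal is not destroyed by the detection filter itself
    lowdet <- sample(setdiff(seq_len(m_mb), assoc_set),
                     min(round(cfg$lowdetect_frac * m_mb),
                         m_mb - k_assoc))
    qs[lowdet] <- 0.30
    for (j in seq_len(m_mb)) {
      lod <- stats::quantile(intensity[, j], qs[j], names = FALSE)
      intensity[intensity[, j] < lod, j] <- NA
    }

    ## ---- prevalent outcome -----------------------------------------
    # prevalent effects: consistent with incident signs on the incident
    # panel, random signs on the remainder of the prevalent set
    v_prev <- numeric(m_mb)
    if (cfg$effect_multiplier != 0) {
      v_prev[inc_set] <- cfg$metab_prevalent_effect * sign(u)
      extra <- setdiff(prev_set, inc_set)
      v_prev[extra] <- cfg$effect_multiplier *
        sample(c(-1, 1), length(extra), TRUE) *
        stats::runif(length(extra), 0.20, 0.30)
    }
    lp_cov <- 0.5 * z(age) + 0.2 * (sex - mean(sex)) + 0.25 * z(bmi) +
      0.35 * z(sbp) + 0.15 * (diabetes - mean(diabetes))
    lp_prev <- lp_cov + drop(clr_std %*% da_beta) + drop(mb_std %*% v_prev)
    if (any(!is.finite(lp_prev)))
      stop("infeasible config: non-finite risk score")
    b0 <- .calibrate_intercept(lp_prev, cfg$prevalent_rate, stats::plogis)
    prevalent <- stats::rbinom(n, 1, stats::plogis(b0 + lp_prev))

    grade <- integer(n)
    cases <- which(prevalent == 1)
    if (length(cases)) {
      sev <- lp_prev[cases] + stats::rnorm(length(cases), 0, 0.8)
      cutpts <- stats::quantile(sev, c(0.55, 0.85))
      grade[cases] <- 1L + (sev > cutpts[1]) + (sev > cutpts[2])
    }

    ## ---- incident outcome ------------------------------------------
    followup <- prevalent == 0 & stats::rbinom(n, 1, cfg$followup_frac) == 1
    u_full <- numeric(m_mb); u_full[inc_set] <- u
    lp_inc <- 0.45 * z(age) + 0.25 * z(bmi) + 0.30 * z(sbp) +
      0.35 * (diabetes - mean(diabetes)) +
      0.15 * ((alcohol == "current") - mean(alcohol == "current")) +
      drop(mb_std %*% u_full)
    incident <- rep(NA_integer_, n)
    if (sum(followup) >= 20) {
      lp_f <- lp_inc[followup]
      c0 <- .calibrate_intercept(lp_f, cfg$incident_rate,
                                 function(x) pmin(exp(x), 0.95))
      incident[followup] <- stats::rbinom(sum(followup), 1,
                                          pmin(exp(c0 + lp_f), 0.95))
    }

    ## ---- KO gene families ------------------------------------------
    m_ko <- cfg$n_kos
    ko_ids <- sprintf("K%05d", seq_len(m_ko))
    ko_edges <- NULL
    ko_lat <- matrix(stats::rnorm(n * m_ko), n, m_ko)
    ko_lat <- sweep(ko_lat, 2, stats::rnorm(m_ko, 0, 1.5), `+`)
    if (cfg$effect_multiplier != 0 && cfg$n_ko_per_proxy > 0 &&
        m_ko >= length(proxy_pos) * cfg$n_ko_per_proxy) {
      slots <- sample.int(m_ko, length(proxy_pos) * cfg$n_ko_per_proxy)
      ko_edges <- data.frame(
        species = sp_ids[da_idx[rep(proxy_pos, each = cfg$n_ko_per_proxy)]],
        ko = ko_ids[slots],
        effect = sample(c(-1, 1), length(slots), TRUE) *
          stats::runif(length(slots), cfg$ko_effect_range[1],
                       cfg$ko_effect_range[2]) * cfg$effect_multiplier,
        stringsAsFactors = FALSE)
      for (e in seq_len(nrow(ko_edges))) {
        sp_col <- match(ko_edges$species[e], sp_ids[da_idx])
        ko_col <- match(ko_edges$ko[e], ko_ids)
        ko_lat[, ko_col] <- ko_lat[, ko_col] +
          ko_edges$effect[e] * clr_std[, sp_col]
      }
    }
    ko_rel <- exp(ko_lat)
    ko_rel <- ko_rel / rowSums(ko_rel)
    dimnames(ko_rel) <- list(ids, ko_ids)

    ## ---- structural zeros (after outcomes are fixed) ----------------
    if (length(struct_idx))
      counts[prevalent == 1, struct_idx] <- 0L

    ## ---- analysis sets ----------------------------------------------
    disc <- stats::rbinom(n, 1, cfg$discovery_frac) == 1
    concurrent <- stats::rbinom(n, 1, cfg$concurrent_frac) == 1
    baseline_v1 <- stats::rbinom(n, 1, cfg$baseline_v1_frac) == 1

    meta <- data.frame(
      sample_id = ids, age = age, sex = sex, center = center,
      education = education, income = income, smoking = smoking,
      alcohol = alcohol, physical_activity = physical_activity,
      ahei2010 = ahei2010, abx_probiotic_use = abx, bmi = bmi, sbp = sbp,
      ldl_c = ldl_c, diabetes = diabetes,
      med_antidiabetic = med_adm, med_antihypertensive = med_ahtn,
      med_lipidlowering = med_llm,
      smoking_current = as.integer(smoking == "current"),
      alcohol_current = as.integer(alcohol == "current"),
      prevalent_lvdd = prevalent, lvdd_grade = grade,
      incident_lvdd = incident,
      set_discovery = disc, set_validation = !disc,
      in_concurrent = concurrent, in_baseline_v1 = baseline_v1,
      has_followup = followup,
      stringsAsFactors = FALSE)
    validate_metadata(meta)

    mb_meta <- data.frame(
      annotation = sample(.super_pathways, m_mb, TRUE,
                          prob = c(0.32, 0.20, 0.14, 0.05, 0.05, 0.05,
                                   0.07, 0.03, 0.09)),
      row.names = mb_ids)

    da_effects <- stats::setNames(da_beta, sp_ids[da_idx])
    out_mets <- data.frame(
      metabolite = mb_ids[prev_set],
      prevalent_effect = v_prev[prev_set],
      incident_log_rr = u_full[prev_set],
      stringsAsFactors = FALSE)
    truth <- list(
      da_species = da_effects[da_effects != 0],
      proxy_species = if (cfg$effect_multiplier != 0) stats::setNames(
        c(-1, -1, 1)[seq_along(proxy_pos)],
        sp_ids[da_idx[proxy_pos]]) else
          stats::setNames(numeric(0), character(0)),
      structural_species = sp_ids[struct_idx],
      species_metabolite_edges = {
        nz <- which(W != 0, arr.ind = TRUE)
        data.frame(species = sp_ids[da_idx[nz[, 1]]],
                   metabolite = mb_ids[nz[, 2]],
                   effect = W[nz], stringsAsFactors = FALSE)
      },
      outcome_metabolites = out_mets[out_mets$prevalent_effect != 0 |
                                       out_mets$incident_log_rr != 0, ],
      ko_edges = ko_edges,
      params = unclass(cfg), seed = seed)

    list(species = feature_table(counts + 0, kind = "counts"),
         metabolites = feature_table(intensity, kind = "intensity",
                                     feature_meta = mb_meta),
         kos = feature_table(ko_rel, kind = "ko_relabund"),
         meta = meta, truth = truth)
  })
}

#' Write a generated cohort to disk
#'
#' Emits the three feature tables and the metadata as TSV plus the
#' ground-truth record as JSON, under a directory.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$species, file.path(dir, "species_counts.tsv"))
  write_feature_table(cohort$metabolites, file.path(dir, "metabolite_intensities.tsv"))
  write_feature_table(cohort$kos, file.path(dir, "ko_relabund.tsv"))
  utils::write.table(cohort$meta, file.path(dir, "sample_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$da_species <- as.list(truth$da_species)        # keep names in JSON
  truth$proxy_species <- as.list(truth$proxy_species)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
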