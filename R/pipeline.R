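# All-pairs covariate-adjusted OLS between two residualized blocks
# (Frisch-Waugh): regress each column of Y on each column of X plus the
# covariates, returning slope/SE/p matrices identical to the full fits.
.all_pairs_ols <- function(X, Y, covariates = NULL) {
  C <- cbind(`(Intercept)` = rep(1, nrow(as.matrix(X))), covariates)
  ok <- stats::complete.cases(C) & stats::complete.cases(X) &
    stats::complete.cases(Y)
  C <- C[ok, , drop = FALSE]
  RX <- stats::lm.fit(C, X[ok, , drop = FALSE])$residuals
  RY <- stats::lm.fit(C, Y[ok, , drop = FALSE])$residuals
  RX <- as.matrix(RX); RY <- as.matrix(RY)
  n <- nrow(RX)
  df <- n - ncol(C) - 1
  sxx <- colSums(RX^2)
  syy <- colSums(RY^2)
  sxy <- crossprod(RX, RY)                 # a x b
  beta <- sxy / sxx
  rss <- outer(rep(1, length(sxx)), syy) - beta * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  list(beta = beta, se = se, p = p, n = n, df = df)
}

# Prepare a log-scale, zero-imputed KO matrix for linear association work.
.ko_log <- function(values) {
  out <- values
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    if (any(x == 0, na.rm = TRUE)) {
      mp <- min(x[x > 0], na.rm = TRUE) / 2
      x[x == 0] <- mp
    }
    out[, j] <- log(x)
  }
  out
}

#' Species-KO-metabolite association triangle
#'
#' Links each retained species to incident-associated metabolites through
#' KO gene families: KO-species and KO-metabolite associations are
#' covariate-adjusted linear regressions at FDR < 0.1 (one BH family per
#' exposure), KO-outcome associations are logistic fits flagged at
#' nominal p < 0.05, and an edge is reported when a KO connects a species
#' to a metabolite with sign-concordant paths — the product of the
#' species-to-KO and KO-to-metabolite signs must match the sign of the
#' direct species-to-metabolite association. Partial correlations
#' (KO vs metabolite given covariates) accompany reported edges.
#'
#' @param species_clr samples x species CLR matrix for the retained
#'   species (concurrent analysis set).
#' @param kos a filtered `ko_relabund` `feature_table` on the same
#'   samples.
#' @param metabolites_int samples x metabolites INT matrix restricted to
#'   the incident-associated panel.
#' @param species_met species x metabolite matrix of direct association
#'   signs (e.g. MWAA slopes); only significant direct pairs receive
#'   edges.
#' @param outcome binary prevalent labels for the KO-outcome fits (may be
#'   on a larger sample set).
#' @param outcome_kos samples x KOs matrix aligned with `outcome` (log
#'   scale is taken internally); defaults to the concurrent KO table.
#' @param covariates,outcome_covariates design blocks for the linear and
#'   logistic fits.
#' @param fdr_level FDR level for the linear layers.
#' @return list with `edges` (data.frame of triangle edges),
#'   `ko_species`, `ko_metabolite` (long-form association tables) and
#'   `ko_outcome`.
#' @export
ko_triangle <- function(species_clr, kos, metabolites_int, species_met,
                        outcome, outcome_kos = NULL,
                        covariates = NULL, outcome_covariates = NULL,
                        fdr_level = 0.1) {
  stopifnot(inherits(kos, "feature_table"))
  if (ncol(kos$values) == 0) stop("empty KO table after filtering")
  species_clr <- as.matrix(species_clr)
  klog <- .ko_log(kos$values)
  klog <- scale(klog)

  sp_ko <- .all_pairs_ols(species_clr, klog, covariates)
  dimnames(sp_ko$beta) <- dimnames(sp_ko$se) <- dimnames(sp_ko$p) <-
    list(colnames(species_clr), colnames(klog))
  q_sp_ko <- sp_ko$p                                   # species x KO
  for (i in seq_len(nrow(q_sp_ko)))
    q_sp_ko[i, ] <- bh_fdr(sp_ko$p[i, ])               # BH per species

  ko_met <- .all_pairs_ols(klog, as.matrix(metabolites_int), covariates)
  dimnames(ko_met$beta) <- dimnames(ko_met$se) <- dimnames(ko_met$p) <-
    list(colnames(klog), colnames(metabolites_int))
  q_ko_met <- ko_met$p                                 # KO x metabolite
  for (i in seq_len(nrow(q_ko_met)))
    q_ko_met[i, ] <- bh_fdr(ko_met$p[i, ])             # BH per KO

  assoc_any <- colnames(klog)[apply(q_sp_ko < fdr_level, 2, any)]
  ko_out <- NULL
  if (length(assoc_any) && !is.null(outcome)) {
    if (is.null(outcome_kos)) outcome_kos <- kos$values
    olog <- scale(.ko_log(outcome_kos[, assoc_any, drop = FALSE]))
    ko_out <- do.call(rbind, lapply(assoc_any, function(k) {
      fit_logistic(outcome, olog[, k], outcome_covariates,
                   feature = k, exposure_id = "prevalent_lvdd")
    }))
    ko_out$nominal_significant <- ko_out$p < 0.05
  }

  edges <- list()
  for (s in rownames(q_sp_ko)) {
    for (k in which(q_sp_ko[s, ] < fdr_level)) {
      mets <- which(q_ko_met[k, ] < fdr_level)
      for (m in mets) {
        met_id <- colnames(metabolites_int)[m]
        direct <- species_met[s, met_id]
        if (is.na(direct) || direct == 0) next
        s1 <- sign(sp_ko$beta[s, k])
        s2 <- sign(ko_met$beta[k, m])
        conc <- (s1 * s2) == sign(direct)
        r <- ko_met$beta[k, m] / ko_met$se[k, m]
        r <- r / sqrt(r^2 + ko_met$df)
        edges[[length(edges) + 1]] <- data.frame(
          species = s, ko = colnames(klog)[k], metabolite = met_id,
          beta_species_ko = sp_ko$beta[s, k],
          beta_ko_metabolite = ko_met$beta[k, m],
          beta_species_metabolite = direct,
          partial_r_ko_metabolite = r,
          concordant = conc, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(species = character(), ko = character(),
               metabolite = character(), beta_species_ko = numeric(),
               beta_ko_metabolite = numeric(),
               beta_species_metabolite = numeric(),
               partial_r_ko_metabolite = numeric(),
               concordant = logical())
  list(edges = edges,
       ko_species = list(beta = sp_ko$beta, q = q_sp_ko),
       ko_metabolite = list(beta = ko_met$beta, q = q_ko_met),
       ko_outcome = ko_out)
}

# Filter + CLR for one analysis set (prevalence computed on that set).
.species_clr_set <- function(species, idx, config) {
  sub <- ft_subset(species, samples = sample_ids(species)[idx])
  filt <- filter_by_prevalence(sub, config$species_prevalence)
  list(clr = clr_transform(filt$table, config$pseudocount),
       report = filt$report)
}

# Detection filter + INT for one analysis set.
.metab_int_set <- function(metabolites, idx, config) {
  sub <- ft_subset(metabolites, samples = sample_ids(metabolites)[idx])
  filt <- filter_by_detection(sub, config$metabolite_detection)
  int_transform(filt$table)$table
}

#' Run the full multi-omics study
#'
#' Executes the analysis graph end to end on aligned species, metabolite
#' and KO tables: ANCOM-II species discovery (discovery set) with
#' logistic quantification in discovery and validation, random-effects
#' pooling with the concordance retention rule, final Model 1-3 logistic
#' quantification and grade trend on the combined set, metabolome-wide
#' association of retained species (concurrent set), metabolite-prevalent
#' logistic (baseline-visit set), incident modified Poisson (follow-up
#' set), Z-score proxy association, elastic-net risk prediction with AUC
#' comparison, and the species-KO-metabolite triangle.
#'
#' @param species counts `feature_table` over all samples.
#' @param metabolites intensity `feature_table` (NA = below detection).
#' @param kos `ko_relabund` `feature_table`.
#' @param meta sample metadata with the analysis-set flag columns
#'   produced by [generate_cohort()] (`set_discovery`, `set_validation`,
#'   `in_concurrent`, `in_baseline_v1`, `has_followup`).
#' @param config a [run_config()].
#' @param output_dir optional directory for stage TSVs, the JSON manifest
#'   and a plain-text summary.
#' @return a study report: list of per-stage results, a `manifest` of
#'   sample sizes, thresholds and seeds, and a `summary` of headline
#'   counts.
#' @export
run_study <- function(species, metabolites, kos, meta,
                      config = run_config(), output_dir = NULL) {
  validate_metadata(meta)
  bundle <- align_samples(list(species = species, metabolites = metabolites,
                               kos = kos), meta)
  species <- bundle$tables$species
  metabolites <- bundle$tables$metabolites
  kos <- bundle$tables$kos
  meta <- bundle$meta
  n <- nrow(meta)
  manifest <- list(config = unclass(config), n_aligned = n,
                   layer_n = as.list(bundle$layer_n))

  idx_disc <- meta$set_discovery
  idx_valid <- meta$set_validation
  idx_conc <- meta$in_concurrent
  idx_v1 <- meta$in_baseline_v1
  idx_fu <- meta$has_followup & !is.na(meta$incident_lvdd)
  manifest$n_sets <- list(discovery = sum(idx_disc),
                          validation = sum(idx_valid),
                          concurrent = sum(idx_conc),
                          baseline_v1 = sum(idx_v1),
                          followup = sum(idx_fu))

  ## ---- stage 1: ANCOM-II species discovery -------------------------
  log_msg("ancom2", "discovery set n = ", sum(idx_disc))
  disc <- .species_clr_set(species, idx_disc, config)
  disc_counts <- ft_subset(species, samples = sample_ids(species)[idx_disc])
  disc_counts <- ft_subset(disc_counts, features = feature_ids(disc$clr))
  cov_ancom <- covariate_matrix(meta[idx_disc, ], model_covariates("ancom"))
  ancom <- ancom_w(disc_counts, meta$prevalent_lvdd[idx_disc], cov_ancom,
                   alpha = config$ancom_alpha, cutoff = config$ancom_cutoff,
                   pseudocount = config$pseudocount,
                   structural_threshold = config$structural_threshold)
  candidates <- ancom$taxon[ancom$detected]
  log_msg("ancom2", length(candidates), " candidate species detected")

  ## ---- stage 2: discovery/validation logistic + meta ---------------
  valid <- .species_clr_set(species, idx_valid, config)
  cov_d <- covariate_matrix(meta[idx_disc, ], model_covariates(1))
  cov_v <- covariate_matrix(meta[idx_valid, ], model_covariates(1))
  meta_rows <- list(); quant_rows <- list()
  for (sp in candidates) {
    if (!sp %in% feature_ids(valid$clr)) next
    fd <- fit_logistic(meta$prevalent_lvdd[idx_disc],
                       disc$clr$values[, sp], cov_d, feature = sp,
                       exposure_id = "prevalent_lvdd", model_id = 1L)
    fv <- fit_logistic(meta$prevalent_lvdd[idx_valid],
                       valid$clr$values[, sp], cov_v, feature = sp,
                       exposure_id = "prevalent_lvdd", model_id = 1L)
    if (!fd$converged || !fv$converged) next
    quant_rows[[sp]] <- rbind(cbind(set = "discovery", fd),
                              cbind(set = "validation", fv))
    meta_rows[[sp]] <- random_effects_meta(c(fd$beta, fv$beta),
                                           c(fd$se, fv$se), feature = sp)
  }
  meta_tab <- if (length(meta_rows)) do.call(rbind, meta_rows) else NULL
  retained <- if (is.null(meta_tab)) character() else
    meta_tab$feature[meta_tab$retained]
  log_msg("meta", length(retained), " species retained after pooling")

  ## ---- stage 3: final quantification + grade trend (combined) ------
  comb <- .species_clr_set(species, rep(TRUE, n), config)
  final_quant <- NULL; trend <- NULL
  if (length(retained)) {
    rows <- list()
    for (mid in 1:3) {
      cv <- covariate_matrix(meta, model_covariates(mid))
      for (sp in retained)
        rows[[paste(sp, mid)]] <- fit_logistic(
          meta$prevalent_lvdd, comb$clr$values[, sp], cv, feature = sp,
          exposure_id = "prevalent_lvdd", model_id = mid)
    }
    final_quant <- do.call(rbind, rows)
    cv1 <- covariate_matrix(meta, model_covariates(1))
    trend <- do.call(rbind, lapply(retained, function(sp)
      grade_trend(comb$clr$values[, sp], meta$lvdd_grade, cv1,
                  feature = sp)))
  }

  ## ---- stage 4: MWAA (concurrent set) ------------------------------
  mwaa_tab <- NULL; assoc_mets <- character()
  if (length(retained) && sum(idx_conc) > 30) {
    conc_clr <- .species_clr_set(species, idx_conc, config)$clr
    conc_int <- .metab_int_set(metabolites, idx_conc, config)
    cvc <- covariate_matrix(meta[idx_conc, ], model_covariates(1))
    mwaa_tab <- do.call(rbind, lapply(retained, function(sp)
      mwaa(conc_int, conc_clr$values[, sp], cvc, exposure_id = sp,
           model_id = 1L)))
    assoc_mets <- unique(mwaa_tab$feature[mwaa_tab$q < config$fdr_level])
  }
  log_msg("mwaa", length(assoc_mets), " species-associated metabolites")

  ## ---- stage 5: metabolite-prevalent logistic (baseline V1) --------
  prev_met <- NULL; prev_mets <- character()
  if (length(assoc_mets) && sum(idx_v1) > 30) {
    v1_int <- .metab_int_set(metabolites, idx_v1, config)
    mets <- intersect(assoc_mets, feature_ids(v1_int))
    cvm <- covariate_matrix(meta[idx_v1, ], model_covariates("metabolite"))
    prev_met <- do.call(rbind, lapply(mets, function(mb) {
      x <- v1_int$values[, mb]
      fit_logistic(meta$prevalent_lvdd[idx_v1], x / stats::sd(x), cvm,
                   feature = mb, exposure_id = "prevalent_lvdd",
                   model_id = 1L)
    }))
    prev_met$q <- bh_fdr(prev_met$p)
    prev_mets <- prev_met$feature[prev_met$q < config$fdr_level]
  }
  log_msg("prevalent-metabolites", length(prev_mets),
          " prevalent-associated metabolites")

  ## ---- stage 6: incident modified Poisson (follow-up set) ----------
  inc_met <- NULL; inc_mets <- character(); fu_int <- NULL
  if (length(prev_mets) && sum(idx_fu) > 30) {
    fu_int <- .metab_int_set(metabolites, idx_fu, config)
    mets <- intersect(prev_mets, feature_ids(fu_int))
    cvf <- covariate_matrix(meta[idx_fu, ], model_covariates("metabolite"))
    inc_met <- do.call(rbind, lapply(mets, function(mb) {
      x <- fu_int$values[, mb]
      modified_poisson(meta$incident_lvdd[idx_fu], x / stats::sd(x), cvf,
                       feature = mb, exposure_id = "incident_lvdd",
                       model_id = 1L)
    }))
    inc_met$q <- bh_fdr(inc_met$p)
    inc_mets <- inc_met$feature[inc_met$p < 0.05]
  }
  log_msg("incident-metabolites", length(inc_mets),
          " incident-associated metabolites")

  ## ---- stage 7: proxy association ----------------------------------
  proxy <- NULL; proxy_scatter <- NULL
  if (length(inc_mets) >= 3 && !is.null(mwaa_tab)) {
    z_out <- to_zscores(inc_met[match(inc_mets, inc_met$feature), ])
    proxy <- list(); scat <- list()
    for (sp in retained) {
      sub <- mwaa_tab[mwaa_tab$exposure == sp &
                        mwaa_tab$feature %in% inc_mets, ]
      if (nrow(sub) < 3) next
      z_sp <- to_zscores(sub)
      proxy[[sp]] <- proxy_association(z_sp, z_out[names(z_sp)],
                                       species_id = sp)
      ann <- metabolites$feature_meta
      scat[[sp]] <- data.frame(species = sp, metabolite = names(z_sp),
                               z_species = unname(z_sp),
                               z_outcome = unname(z_out[names(z_sp)]),
                               super_pathway = if (!is.null(ann))
                                 ann[names(z_sp), "annotation"] else NA,
                               stringsAsFactors = FALSE)
    }
    proxy <- do.call(rbind, proxy)
    proxy_scatter <- do.call(rbind, scat)
    rownames(proxy) <- rownames(proxy_scatter) <- NULL
  }

  ## ---- stage 8: risk prediction (follow-up set) --------------------
  prediction <- NULL
  trad_cols <- c("age", "bmi", "sbp", "smoking_current", "alcohol_current",
                 "ldl_c", "diabetes")
  if (sum(idx_fu) > 60 && length(inc_mets) >= 2) {
    fu_meta <- meta[idx_fu, ]
    y <- fu_meta$incident_lvdd
    Xtrad <- scale(as.matrix(fu_meta[, trad_cols]))
    Xmet <- fu_int$values[, intersect(inc_mets, feature_ids(fu_int)),
                          drop = FALSE]
    Xaug <- cbind(Xtrad, Xmet)
    fit_trad <- nested_cv_enr(Xtrad, y, outer = config$cv_outer,
                              inner = config$cv_inner,
                              repeats = config$cv_repeats,
                              seed = config$seed)
    fit_aug <- nested_cv_enr(Xaug, y, outer = config$cv_outer,
                             inner = config$cv_inner,
                             repeats = config$cv_repeats,
                             seed = config$seed)
    ci_trad <- roc_auc_ci(fit_trad$cv_predictions, y, config$n_boot,
                          seed = config$seed + 1L)
    ci_aug <- roc_auc_ci(fit_aug$cv_predictions, y, config$n_boot,
                         seed = config$seed + 2L)
    p_delta <- compare_auc(fit_trad$cv_predictions, fit_aug$cv_predictions,
                           y)
    prediction <- list(traditional = fit_trad, augmented = fit_aug,
                       auc_traditional = ci_trad, auc_augmented = ci_aug,
                       delta_auc_p = p_delta)
    log_msg("prediction", sprintf(
      "AUC %.3f (traditional) vs %.3f (augmented), p = %.3g",
      ci_trad$auc, ci_aug$auc, p_delta))
  }

  ## ---- stage 9: KO triangle ----------------------------------------
  triangle <- NULL
  proxy_sig <- if (!is.null(proxy)) proxy$species[proxy$significant] else
    character()
  if (length(proxy_sig) && length(inc_mets) >= 1 && sum(idx_conc) > 30) {
    conc_ids <- sample_ids(kos)[idx_conc]
    ko_conc <- ft_subset(kos, samples = conc_ids)
    kof <- filter_kos(ko_conc, config$ko_prevalence, config$ko_floor)
    if (ncol(kof$table$values) > 0) {
      conc_clr <- .species_clr_set(species, idx_conc, config)$clr
      conc_int <- .metab_int_set(metabolites, idx_conc, config)
      sp_met <- matrix(0, length(proxy_sig), length(inc_mets),
                       dimnames = list(proxy_sig, inc_mets))
      for (sp in proxy_sig) {
        sub <- mwaa_tab[mwaa_tab$exposure == sp &
                          mwaa_tab$feature %in% inc_mets &
                          mwaa_tab$q < config$fdr_level, ]
        sp_met[sp, sub$feature] <- sub$beta
      }
      cvc <- covariate_matrix(meta[idx_conc, ], model_covariates(1))
      cv_all <- covariate_matrix(meta, model_covariates(1))
      mets_use <- intersect(inc_mets, feature_ids(conc_int))
      triangle <- ko_triangle(
        conc_clr$values[, proxy_sig, drop = FALSE], kof$table,
        conc_int$values[, mets_use, drop = FALSE],
        sp_met[, mets_use, drop = FALSE],
        outcome = meta$prevalent_lvdd,
        outcome_kos = kos$values[, feature_ids(kof$table), drop = FALSE],
        covariates = cvc, outcome_covariates = cv_all,
        fdr_level = config$fdr_level)
      log_msg("ko-triangle", nrow(triangle$edges), " edges (",
              sum(triangle$edges$concordant), " concordant)")
    }
  }

  summary <- list(
    n_candidate_species = length(candidates),
    n_retained_species = length(retained),
    retained_species = retained,
    n_species_associated_metabolites = length(assoc_mets),
    n_prevalent_metabolites = length(prev_mets),
    n_incident_metabolites = length(inc_mets),
    proxy = if (!is.null(proxy))
      proxy[, c("species", "R", "p", "significant")] else NULL,
    auc_traditional = if (!is.null(prediction))
      prediction$auc_traditional$auc else NA,
    auc_augmented = if (!is.null(prediction))
      prediction$auc_augmented$auc else NA,
    delta_auc_p = if (!is.null(prediction)) prediction$delta_auc_p else NA)

  report <- list(ancom = ancom, quantification = if (length(quant_rows))
    do.call(rbind, quant_rows) else NULL,
    meta_analysis = meta_tab, final_quantification = final_quant,
    grade_trend = trend, mwaa = mwaa_tab,
    prevalent_metabolites = prev_met, incident_metabolites = inc_met,
    proxy = proxy, proxy_scatter = proxy_scatter,
    prediction = prediction, triangle = triangle,
    manifest = manifest, summary = summary)

  if (!is.null(output_dir)) .write_report(report, output_dir)
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible())
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$ancom, "ancom_results")
  wt(report$quantification, "species_logistic")
  wt(report$meta_analysis, "species_meta")
  wt(report$final_quantification, "species_final_models")
  wt(report$grade_trend, "grade_trend")
  wt(report$mwaa, "mwaa")
  wt(report$prevalent_metabolites, "metabolites_prevalent")
  wt(report$incident_metabolites, "metabolites_incident")
  wt(report$proxy, "proxy_association")
  wt(report$proxy_scatter, "proxy_scatter")
  if (!is.null(report$triangle)) wt(report$triangle$edges, "triangle_edges")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  s <- report$summary
  lines <- c(
    sprintf("candidate species (ANCOM-II): %d", s$n_candidate_species),
    sprintf("retained species: %d (%s)", s$n_retained_species,
            paste(s$retained_species, collapse = ", ")),
    sprintf("species-associated metabolites: %d",
            s$n_species_associated_metabolites),
    sprintf("prevalent-associated metabolites: %d",
            s$n_prevalent_metabolites),
    sprintf("incident-associated metabolites: %d",
            s$n_incident_metabolites),
    sprintf("AUC traditional = %.3f, augmented = %.3f, p(change) = %.4g",
            s$auc_traditional, s$auc_augmented, s$delta_auc_p))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
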