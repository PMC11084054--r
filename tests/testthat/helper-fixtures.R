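# Shared fixtures built in code at test time.

# Tiny counts table with explicit values.
tiny_counts <- function(values, ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- if (is.null(ids)) sprintf("t%02d", seq_len(ncol(m))) else ids
  feature_table(m, kind = "counts")
}

# Null compositional table: log-normal latent abundances pushed through
# per-sample multinomials, independent of any outcome.
null_count_table <- function(n, m, depth = 8000, mu_sd = 1.5,
                             sample_sd = 1) {
  mu <- stats::rnorm(m, 0, mu_sd)
  lat <- sweep(matrix(stats::rnorm(n * m, 0, sample_sd), n, m), 2, mu, `+`)
  pr <- exp(lat); pr <- pr / rowSums(pr)
  counts <- t(vapply(seq_len(n),
                     function(s) stats::rmultinom(1, depth, pr[s, ])[, 1],
                     numeric(m)))
  dimnames(counts) <- list(sprintf("S%04d", seq_len(n)),
                           sprintf("t%03d", seq_len(m)))
  feature_table(counts, kind = "counts")
}

# Shift one taxon's latent log abundance by `shift` SDs in the case group.
shifted_count_table <- function(n, m, shift_taxon = 1, shift = 1,
                                depth = 8000) {
  outcome <- rep(0:1, length.out = n)
  mu <- stats::rnorm(m, 0, 1.5)
  lat <- sweep(matrix(stats::rnorm(n * m), n, m), 2, mu, `+`)
  lat[outcome == 1, shift_taxon] <- lat[outcome == 1, shift_taxon] + shift
  pr <- exp(lat); pr <- pr / rowSums(pr)
  counts <- t(vapply(seq_len(n),
                     function(s) stats::rmultinom(1, depth, pr[s, ])[, 1],
                     numeric(m)))
  dimnames(counts) <- list(sprintf("S%04d", seq_len(n)),
                           sprintf("t%03d", seq_len(m)))
  list(table = feature_table(counts, kind = "counts"), outcome = outcome)
}

# A zero classification treating every zero as a sampling zero, so the
# W-equivalence oracle and the production path share one imputation rule.
all_sampling_zeros <- function(table) {
  v <- table$values
  list(structural = matrix(FALSE, ncol(v), 2,
                           dimnames = list(colnames(v),
                                           c("group0", "group1"))),
       outlier = matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v)),
       sampling = v == 0)
}

# Naive double-loop ANCOM W oracle: per-pair lm on the log-ratio, BH
# within taxon. Independent of the production closed-form path.
brute_force_w <- function(table, outcome, covariates = NULL, alpha = 0.05,
                          pseudocount = 0.5) {
  L <- log(table$values + pseudocount)
  m <- ncol(L)
  W <- integer(m)
  for (i in seq_len(m)) {
    pv <- numeric(0)
    for (j in seq_len(m)) {
      if (j == i) next
      df <- data.frame(y = L[, i] - L[, j], x = outcome)
      if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
      fit <- stats::lm(y ~ ., data = df)
      pv <- c(pv, summary(fit)$coefficients["x", 4])
    }
    W[i] <- sum(stats::p.adjust(pv, "BH") < alpha)
  }
  W
}

# Small cohort configuration used across tests (kept light for speed).
small_cohort_config <- function(...) {
  cohort_config(n = 400, n_species = 60, n_metabolites = 80, n_kos = 40,
                n_assoc_metabolites = 30, n_prevalent_metabolites = 15,
                n_incident_metabolites = 8, n_structural = 1,
                n_ko_per_proxy = 5, ...)
}
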