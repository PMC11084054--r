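test_that("prevalence filter uses a strict > threshold and matches a direct scan", {
  set.seed(11)
  m <- matrix(0, 100, 3, dimnames = list(sprintf("S%03d", 1:100),
                                         c("at21", "at20", "dense")))
  m[sample(100, 21), "at21"] <- 5
  m[sample(100, 20), "at20"] <- 5
  m[, "dense"] <- 1
  out <- filter_by_prevalence(feature_table(m, "counts"), 0.20)
  expect_true("at21" %in% feature_ids(out$table))   # 21/100 > 20%
  expect_false("at20" %in% feature_ids(out$table))  # exactly 20% is dropped
  expect_equal(out$report$features_out, 2L)

  # random 0/1 table vs brute-force column scan
  r <- matrix(rbinom(50 * 40, 1, 0.25), 50, 40,
              dimnames = list(sprintf("S%02d", 1:50),
                              sprintf("f%02d", 1:40)))
  res <- filter_by_prevalence(feature_table(r + 0, "counts"), 0.25)
  manual <- colnames(r)[vapply(seq_len(40),
                               function(j) sum(r[, j] > 0) > 0.25 * 50,
                               logical(1))]
  expect_identical(feature_ids(res$table), manual)

  # idempotence
  again <- filter_by_prevalence(res$table, 0.25)
  expect_identical(again$table$values, res$table$values)
  expect_error(filter_by_prevalence(feature_table(r + 0, "counts"), 0),
               "threshold")
})

test_that("KO filter applies the relative-abundance floor before prevalence", {
  n <- 100
  m <- matrix(0, n, 3, dimnames = list(sprintf("S%03d", 1:n),
                                       c("ok", "too_rare", "borderline")))
  m[1:30, "ok"] <- 2e-5            # 0.002% in 30% of samples
  m[, "too_rare"] <- 5e-6          # 0.0005% everywhere: floor dominates
  m[1:20, "borderline"] <- 2e-5    # exactly 20% does not pass
  ft <- feature_table(m, "ko_relabund")
  out <- filter_kos(ft, prev_threshold = 0.20, relabund_floor = 1e-5)
  expect_identical(feature_ids(out$table), "ok")

  # randomized table vs two-condition brute-force scan
  set.seed(5)
  r <- matrix(10^stats::runif(60 * 30, -7, -3), 60, 30,
              dimnames = list(sprintf("S%02d", 1:60),
                              sprintf("K%02d", 1:30)))
  res <- filter_kos(feature_table(r, "ko_relabund"), 0.2, 1e-5)
  manual <- colnames(r)[vapply(seq_len(30),
                               function(j) sum(r[, j] >= 1e-5) > 0.2 * 60,
                               logical(1))]
  expect_identical(feature_ids(res$table), manual)
  expect_error(filter_kos(ft, 0.2, 0), "positive")
})

test_that("CLR transform matches hand computation and sums to zero", {
  eq <- tiny_counts(matrix(1, 2, 4))
  expect_equal(unname(clr_transform(eq, pseudocount = 2)$values),
               matrix(0, 2, 4))

  two <- tiny_counts(matrix(c(4, 1), 1, 2))
  got <- clr_transform(two, pseudocount = 0)$values
  expect_equal(unname(got[1, ]), c(log(2), -log(2)), tolerance = 1e-12)

  set.seed(2)
  rnd <- tiny_counts(matrix(rpois(60, 10) + 1, 10, 6))
  clr <- clr_transform(rnd, pseudocount = 0.5)
  expect_lt(max(abs(rowSums(clr$values))), 1e-10)
  expect_identical(clr$kind, "clr")

  # scale invariance with pseudocount 0 and no zeros
  v <- matrix(c(2, 3, 5, 4, 6, 10), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  base <- clr_transform(feature_table(v, "counts"), 0)$values
  scaled <- clr_transform(feature_table(v * 7, "counts"), 0)$values
  expect_equal(base, scaled, tolerance = 1e-12)

  zero_row <- tiny_counts(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE))
  expect_error(clr_transform(zero_row), "all-zero sample")
})

test_that("inverse normal transform follows the Blom convention", {
  # n = 3, all detected: middle maps to 0, ends are symmetric
  out <- inverse_normal_transform(c(5, 9, 2))
  expect_equal(out[1], 0)
  expect_equal(out[2], -out[3])
  expect_gt(out[2], 0)

  # below-LOD replaced by half the minimum detected value before ranking
  x <- c(10, 20, NA, 30)
  out <- inverse_normal_transform(x)
  expect_equal(attr(out, "half_minimum"), 5)
  expect_equal(order(c(10, 20, 5, 30)), order(out))
  expect_equal(which.min(out), 3L)

  # n = 5 distinct values: Blom-formula oracle
  x5 <- c(3.2, -1, 0.5, 7, 2)
  got <- inverse_normal_transform(x5)
  expected_probs <- (rank(x5) - 3 / 8) / (5 + 1 / 4)
  expect_equal(as.numeric(got), stats::qnorm(expected_probs),
               tolerance = 1e-12)
  expect_equal(sort(expected_probs),
               c(0.11905, 0.30952, 0.5, 0.69048, 0.88095),
               tolerance = 1e-4)

  # ties get average ranks (equal values map equally)
  tied <- inverse_normal_transform(c(1, 1, 5))
  expect_equal(tied[1], tied[2])
  expect_error(inverse_normal_transform(c(NA_real_, NA, NA)),
               "below detection")
})

test_that("INT is monotone and asymptotically centered", {
  set.seed(8)
  x <- rlnorm(500)
  out <- inverse_normal_transform(x)
  expect_identical(order(x), order(out))
  expect_lt(abs(mean(out)), 0.02)
})

test_that("table-level INT and detection filter work together", {
  set.seed(9)
  v <- matrix(rlnorm(200), 40, 5,
              dimnames = list(sprintf("S%02d", 1:40), paste0("m", 1:5)))
  v[1:15, 2] <- NA  # 62.5% detection: dropped at 75%
  v[1, 3] <- NA     # 97.5% detection: kept, imputed
  ft <- feature_table(v, "intensity")
  filt <- filter_by_detection(ft, 0.75)
  expect_identical(feature_ids(filt$table), c("m1", "m3", "m4", "m5"))
  res <- int_transform(filt$table)
  expect_identical(res$table$kind, "int_transformed")
  expect_false(anyNA(res$table$values))
  expect_equal(unname(res$report$half_minimum["m3"]),
               min(v[-1, 3]) / 2)
})
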