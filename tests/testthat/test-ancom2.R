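test_that("zero classification identifies the definitional cases", {
  set.seed(21)
  n <- 40
  outcome <- rep(0:1, each = n / 2)
  v <- matrix(rpois(n * 4, 50) + 1, n, 4,
              dimnames = list(sprintf("S%02d", 1:n), paste0("t", 1:4)))
  v[outcome == 1, 1] <- 0                      # structural in group 1
  # low-abundance taxon: its zeros are plausible sampling zeros
  v[, 2] <- rpois(n, 2)
  v[sample(which(outcome == 0), 8), 2] <- 0
  # t3: abundant everywhere except one technical zero
  v[, 3] <- rpois(n, 5000) + 1000
  v[3, 3] <- 0
  ft <- feature_table(v + 0, "counts")
  zc <- classify_zeros(ft, outcome)
  expect_true(zc$structural["t1", "group1"])
  expect_false(zc$structural["t1", "group0"])
  expect_false(any(zc$structural["t2", ]))
  expect_true(zc$outlier[3, "t3"])             # extreme lower outlier
  expect_true(any(zc$sampling[, "t2"]))
  # taxon present everywhere: no flags of any kind
  expect_false(any(zc$structural["t4", ]) || any(zc$outlier[, "t4"]) ||
                 any(zc$sampling[, "t4"]))
  # each zero receives exactly one class
  zero_mask <- v == 0
  classed <- zc$outlier | zc$sampling
  for (g in 0:1) {
    idx <- outcome == g
    struct_taxa <- which(zc$structural[, g + 1])
    classed[idx, struct_taxa] <- classed[idx, struct_taxa] |
      zero_mask[idx, struct_taxa]
  }
  expect_identical(unname(classed), unname(zero_mask))
  expect_error(classify_zeros(ft, c(rep(0, 37), 1, 1, 1)), "at least 5")
})

test_that("structural zeros injected by the generator are recovered", {
  co <- generate_cohort(small_cohort_config(), seed = 44)
  filt <- filter_by_prevalence(co$species, 0.20)$table
  zc <- classify_zeros(filt, co$meta$prevalent_lvdd)
  called <- rownames(zc$structural)[zc$structural[, "group1"] &
                                      !zc$structural[, "group0"]]
  expect_setequal(intersect(called, feature_ids(filt)),
                  intersect(co$truth$structural_species, feature_ids(filt)))
})

test_that("W equals the naive double-loop oracle for small m", {
  set.seed(33)
  n <- 60
  outcome <- rep(0:1, each = n / 2)
  covs <- cbind(age = rnorm(n), sexf = rbinom(n, 1, 0.5))
  v <- matrix(rpois(n * 8, 40) + 1, n, 8,
              dimnames = list(sprintf("S%02d", 1:n), paste0("t", 1:8)))
  v[outcome == 1, 2] <- v[outcome == 1, 2] * 3  # one shifted taxon
  ft <- feature_table(v + 0, "counts")
  res <- ancom_w(ft, outcome, covariates = covs)
  expect_equal(res$W, brute_force_w(ft, outcome, covs))

  # same equivalence without covariates and with a sampling zero present
  # (declared sampling so both paths impute it with the pseudocount)
  v2 <- v; v2[5, 4] <- 0
  ft2 <- feature_table(v2 + 0, "counts")
  res2 <- ancom_w(ft2, outcome, zero_class = all_sampling_zeros(ft2))
  expect_equal(res2$W, brute_force_w(ft2, outcome))
})

test_that("a strongly shifted taxon attains the maximum W", {
  set.seed(71)
  sim <- shifted_count_table(n = 200, m = 10, shift = 2)
  res <- ancom_w(sim$table, sim$outcome)
  expect_equal(which.max(res$W), 1L)
  expect_true(res$detected[1])
})

test_that("null data with few taxa yields W near zero", {
  set.seed(55)
  tb <- null_count_table(n = 400, m = 3)
  outcome <- rep(0:1, 200)
  res <- ancom_w(tb, outcome)
  expect_true(all(res$W <= 1))
  expect_false(any(res$detected))
})

test_that("adding a constant-composition taxon preserves the W ordering", {
  set.seed(60)
  sim <- shifted_count_table(n = 150, m = 8, shift = 1.5)
  base <- ancom_w(sim$table, sim$outcome)
  v <- sim$table$values
  # a taxon in fixed proportion to the total: all its log-ratios are
  # outcome-independent up to multinomial noise
  aug <- cbind(v, ref = round(rowSums(v) * 0.2))
  res <- ancom_w(feature_table(aug, "counts"), sim$outcome)
  # the shifted taxon stays on top and detection decisions are unchanged
  # (ties among near-zero W values may reshuffle, detection may not)
  expect_equal(which.max(res$W[seq_len(8)]), which.max(base$W))
  expect_equal(res$detected[seq_len(8)], base$detected)
})

test_that("one-sided structural-zero taxa are auto-detected and pooled out", {
  set.seed(14)
  n <- 100
  outcome <- rep(0:1, each = 50)
  v <- matrix(rpois(n * 6, 60) + 1, n, 6,
              dimnames = list(sprintf("S%03d", 1:n), paste0("t", 1:6)))
  v[outcome == 1, 6] <- 0
  res <- ancom_w(feature_table(v + 0, "counts"), outcome)
  row6 <- res[res$taxon == "t6", ]
  expect_true(row6$detected)
  expect_true(row6$structural_zero_call)
  expect_true(is.na(row6$W))
  expect_identical(attr(res, "m_pool"), 5L)
  expect_true(all(res$W[1:5] <= 4))
})

test_that("degenerate inputs are rejected", {
  set.seed(3)
  tb <- null_count_table(50, 5)
  outcome <- rep(0:1, 25)
  expect_error(ancom_w(tb, outcome, covariates = cbind(1, 1)[rep(1, 50), ]),
               "rank-deficient")
  tiny <- ft_subset(tb, features = feature_ids(tb)[1:2])
  expect_error(ancom_w(tiny, outcome), "fewer than 3 taxa")
})
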