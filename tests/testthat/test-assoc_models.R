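test_that("logistic OR reproduces the 2x2 cross-product ratio exactly", {
  outcome <- rep(c(1, 0, 1, 0), c(20, 80, 10, 90))
  exposure <- rep(c(1, 0), c(100, 100))
  fit <- fit_logistic(outcome, exposure)
  expect_equal(fit$effect, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_identical(fit$effect_measure, "OR")
  expect_true(fit$ci_lo < fit$effect && fit$effect < fit$ci_hi)
  expect_error(fit_logistic(rep(1, 50), rnorm(50)), "both classes")
})

test_that("separation is flagged rather than silently returned", {
  y <- rep(0:1, each = 20)
  x <- c(rnorm(20, -5), rnorm(20, 5))
  fit <- fit_logistic(y, x)
  expect_false(fit$converged)
})

test_that("MWAA linear fits recover identities and planted slopes", {
  set.seed(19)
  x <- rnorm(300)
  idfit <- fit_linear_mwaa(x, x)
  expect_equal(idfit$beta, 1, tolerance = 1e-10)
  expect_lt(idfit$p, 1e-10)

  covs <- cbind(rnorm(300), rbinom(300, 1, 0.4))
  y <- 0.4 * x + 0.3 * covs[, 1] + rnorm(300)
  fit <- fit_linear_mwaa(y, x, covs)
  expect_lt(abs(fit$beta - 0.4), 3 * fit$se)

  # vectorized MWAA equals the per-metabolite scalar path
  Y <- cbind(m1 = y, m2 = rnorm(300), m3 = -0.2 * x + rnorm(300))
  vec <- mwaa(Y, x, covs, exposure_id = "sp")
  for (j in 1:3) {
    single <- fit_linear_mwaa(Y[, j], x, covs)
    expect_equal(vec$beta[j], single$beta, tolerance = 1e-12)
    expect_equal(vec$se[j], single$se, tolerance = 1e-12)
    expect_equal(vec$p[j], single$p, tolerance = 1e-12)
  }
  expect_equal(vec$q, bh_fdr(vec$p))
})

test_that("modified Poisson matches the closed-form 2x2 relative risk", {
  outcome <- rep(c(1, 0, 1, 0), c(10, 40, 5, 45))
  exposure <- rep(c(1, 0), c(50, 50))
  fit <- modified_poisson(outcome, exposure)
  expect_equal(fit$effect, 2.0, tolerance = 1e-7)
  expect_equal(fit$se, sqrt(1 / 10 - 1 / 50 + 1 / 5 - 1 / 50),
               tolerance = 1e-6)
  expect_identical(fit$effect_measure, "RR")
  expect_error(modified_poisson(rep(0, 40), rnorm(40)), "no events")
})

test_that("DerSimonian-Laird pooling matches its closed forms and metafor", {
  hom <- random_effects_meta(c(0.5, 0.5), c(0.2, 0.2))
  expect_equal(hom$beta_pooled, 0.5)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$se_pooled, 0.2 / sqrt(2))

  disc <- random_effects_meta(c(0.5, -0.5), c(0.1, 0.1))
  expect_false(disc$concordant)
  expect_false(disc$retained)

  skip_if_not_installed("metafor")
  beta <- c(0.8, 0.25, 0.5); se <- c(0.15, 0.1, 0.3)
  ours <- random_effects_meta(beta, se)
  ref <- metafor::rma(yi = beta, sei = se, method = "DL")
  expect_equal(ours$beta_pooled, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se_pooled, ref$se, tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  expect_error(random_effects_meta(c(1, 1), c(0.1, 0)), "positive")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("grade trend detects planted monotone decreases", {
  grade <- rep(0:3, each = 25)
  # exactly orthogonal response: slope 0, p = 1
  flat <- rep(c(1.5, -1.5, -1.5, 1.5), each = 25)
  res <- grade_trend(flat, grade)
  expect_equal(res$beta, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-8)

  ident <- grade_trend(as.numeric(grade), grade)
  expect_equal(ident$beta, 1, tolerance = 1e-10)

  set.seed(40)
  g1000 <- sample(0:3, 1000, replace = TRUE)
  y <- -0.15 * g1000 + rnorm(1000)
  sim <- grade_trend(y, g1000)
  expect_lt(sim$beta, 0)
  expect_lt(sim$p, 0.05)
  expect_error(grade_trend(rnorm(10), rep(1, 10)), "distinct grades")
})

test_that("partial correlation matches its trivariate closed form", {
  set.seed(26)
  x <- rnorm(200); y <- x + rnorm(200)
  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(x, x)$r, 1, tolerance = 1e-12)

  n <- 40000
  z <- rnorm(n)
  xx <- 0.6 * z + rnorm(n)
  yy <- 0.5 * z + rnorm(n)
  r_xy <- cor(xx, yy); r_xz <- cor(xx, z); r_zy <- cor(z, yy)
  expected <- (r_xy - r_xz * r_zy) /
    sqrt((1 - r_xz^2) * (1 - r_zy^2))
  got <- partial_correlation(xx, yy, cbind(z))
  expect_equal(got$r, expected, tolerance = 1e-3)
  expect_gt(got$p, 0.001)  # xx and yy are independent given z
})

test_that("the covariate registry nests Models 1-3", {
  m1 <- model_covariates(1); m2 <- model_covariates(2)
  m3 <- model_covariates(3)
  expect_setequal(setdiff(m2, m1), c("bmi", "sbp"))
  expect_setequal(setdiff(m3, m2),
                  c("med_antidiabetic", "med_antihypertensive",
                    "med_lipidlowering"))
  expect_true(all(m1 %in% m2) && all(m2 %in% m3))
  expect_false("abx_probiotic_use" %in% model_covariates("metabolite"))
  expect_true(all(model_covariates("ancom") %in% m1))
  co <- generate_cohort(small_cohort_config(), seed = 2)
  mm <- covariate_matrix(co$meta, m3)
  expect_equal(nrow(mm), nrow(co$meta))
  expect_gt(ncol(mm), length(m3))  # factors expand to dummies
  bad <- co$meta; bad$age[1] <- NA
  expect_error(covariate_matrix(bad, m1), "missing covariate")
})
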