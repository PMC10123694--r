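test_that("a noiseless line is fit exactly", {
  design <- data.frame(age = c(1, 2, 3, 4, 5))
  y <- 2 * design$age + 1
  # summary.lm warns about the (intended) perfect fit
  m <- suppressWarnings(fit_ols(design, y))
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$terms$b, 2, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$adj_r2, 1, tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle on random designs", {
  for (seed in c(21L, 22L, 23L)) {
    design <- random_design(n = 40, p = 2, seed = seed)
    set.seed(seed + 1000)
    y <- 3 + 1.5 * design$x1 - 0.7 * design$x2 + rnorm(40)
    m <- fit_ols(design, y)
    oracle <- ols_normal_equations(design, y)
    expect_equal(unname(c(m$intercept, m$terms$b)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("fitted summaries satisfy their defining identities", {
  ch <- example_cohort()$cohort
  cov <- model_covariates(ch)
  design <- as.data.frame(cov[, c("gender", "age", "weight",
                                  "p2i_minus_p1", "ri_iso")])
  y <- ch$vo2max_iso
  m <- fit_ols(design, y)
  n <- nrow(design); p <- ncol(design)
  expect_equal(m$terms$t, m$terms$b / m$terms$se, tolerance = 1e-10)
  expect_equal(m$terms$p,
               2 * pt(abs(m$terms$t), df = n - p - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(m$adj_r2, 1 - (1 - m$r2) * (n - 1) / (n - p - 1),
               tolerance = 1e-10)
  expect_equal(m$terms$beta,
               m$terms$b * vapply(design, sd, numeric(1)) / sd(y),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lte(m$adj_r2, m$r2)
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  design <- random_design(n = 50, p = 3, seed = 31L)
  set.seed(32)
  y <- 1 + design$x1 - 2 * design$x2 + 0.5 * design$x3 + rnorm(50)
  m1 <- fit_ols(design, y)
  scaled <- design
  scaled$x1 <- scaled$x1 * 100 + 7  # e.g. a unit change
  m2 <- fit_ols(scaled, y)
  expect_equal(m1$terms$beta, m2$terms$beta, tolerance = 1e-10)
})

test_that("null responses give small R-squared and roughly uniform p-values", {
  set.seed(40)
  pvals <- replicate(500, {
    design <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
    y <- rnorm(200)  # independent of the design
    fit_ols(design, y)$terms$p[1]
  })
  # uniformity at coarse resolution: deciles populated within binomial noise
  h <- hist(pvals, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_true(all(h > 20) && all(h < 85))
  expect_gt(mean(pvals), 0.42)
  expect_lt(mean(pvals), 0.58)
})

test_that("rank-deficient designs fail loudly, naming dependent columns", {
  design <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  design$x3 <- design$x1 + design$x2
  expect_error(fit_ols(design, rnorm(20)), "rank-deficient.*x3")
  expect_error(fit_ols(design[, 1:2], c(rnorm(19), NA)), "complete")
  expect_error(fit_ols(data.frame(x1 = rnorm(2)), rnorm(2)), "rows")
})

test_that("naive leave-one-out equals the hat-matrix closed form", {
  for (seed in 51:100) {
    n <- sample(15:35, 1)
    p <- sample(1:4, 1)
    design <- random_design(n, p, seed)
    set.seed(seed + 5000)
    y <- rnorm(n, mean = rowSums(design))
    cv <- loocv(design, y, mean_for_normalization = 40)
    expect_equal(cv$per_fold, loocv_hat_matrix(design, y),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out error metrics are coherent and vanish on noiseless data", {
  design <- data.frame(x1 = seq_len(12))
  y <- 3 + 2 * design$x1
  cv <- loocv(design, y, mean_for_normalization = mean(y))
  expect_equal(cv$rmse, 0, tolerance = 1e-9)
  expect_equal(cv$mae, 0, tolerance = 1e-9)

  set.seed(61)
  design <- random_design(30, 2, 62L)
  y <- rnorm(30, rowSums(design), 1)
  cv <- loocv(design, y, mean_for_normalization = 40)
  expect_gte(cv$rmse, cv$mae)
  expect_equal(cv$nrmse, cv$rmse / 40, tolerance = 1e-12)
  expect_equal(cv$nmae, cv$mae / 40, tolerance = 1e-12)
  expect_length(cv$per_fold, 30)
})

test_that("cross-validated error recovers the generating noise level", {
  ch <- generate_cohort(generator_config(n = 500L, prop_women = 0.4,
                                         noise_sd = 2.0, seed = 70L))
  fits <- fit_study_models(ch)
  nrmse <- fits$model2$loocv$nrmse
  expected <- 2.0 / mean(ch$vo2max_classic)
  expect_lt(abs(nrmse - expected) / expected, 0.10)
})

test_that("study-model refits use the fixed predictor sets and classic-mean normalization", {
  ch <- example_cohort()$cohort
  fits <- fit_study_models(ch)
  expect_identical(fits$model1$model$terms$term[5], "p2i_minus_p3i")
  expect_identical(fits$model2$model$terms$term[5], "ri_iso")
  expect_identical(fits$model3$model$terms$term[5], "rdi_iso")
  expect_equal(fits$model2$loocv$nrmse,
               fits$model2$loocv$rmse / mean(ch$vo2max_classic),
               tolerance = 1e-12)

  # duplicating every record leaves coefficients unchanged, shrinks SEs
  ch2 <- ch[rep(seq_len(nrow(ch)), 2), ]
  ch2$id <- sprintf("D%03d", seq_len(nrow(ch2)))
  fits2 <- fit_study_models(as_cohort(ch2))
  expect_equal(fits2$model2$model$terms$b, fits$model2$model$terms$b,
               tolerance = 1e-8)
  expect_true(all(fits2$model2$model$terms$se < fits$model2$model$terms$se))
})
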