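test_that("generation is a deterministic function of the config", {
  cfg <- generator_config(seed = 123L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c2 <- generate_cohort(generator_config(seed = 124L))
  expect_false(identical(a$p1, c2$p1))
})

test_that("gender composition follows prop_women exactly", {
  ch <- generate_cohort(generator_config(n = 35L, prop_women = 15 / 35,
                                         seed = 2L))
  expect_identical(sum(ch$gender == 1L), 15L)
  expect_identical(sum(ch$gender == 0L), 20L)
  expect_identical(anyDuplicated(ch$id), 0L)
  expect_error(generator_config(n = 35L, prop_women = 0.5), "whole number")
})

test_that("large samples reproduce the calibration targets", {
  cfg <- generator_config(n = 5000L, prop_women = 0.5, seed = 3L)
  ch <- generate_cohort(cfg)
  m <- cfg$margins
  for (g in 0:1) {
    tgt <- if (g == 0) m$men else m$women
    sub <- ch[ch$gender == g, ]
    n_g <- nrow(sub)
    # resting and post-exercise heart rates: truncation bounds are far
    # from the means, so sample means sit within 3 SE of the targets
    for (v in c("p1", "p2_iso")) {
      se <- tgt$sd[v] / sqrt(n_g)
      expect_lt(abs(mean(sub[[v]]) - tgt$mean[v]), 3 * se + 1e-9,
                label = sprintf("gender %d mean %s", g, v))
    }
    # age and weight: truncation bites (eligibility window [18, 25];
    # 40 kg floor within ~2.3 SD of the women's mean), so the generator's
    # true expectation is the truncated-normal mean
    tn <- isoruffier:::truncnorm_mean
    for (v in c("age", "weight_kg")) {
      bounds <- if (v == "age") c(18, 25) else c(40, 130)
      se <- tgt$sd[v] / sqrt(n_g)
      expect_lt(abs(mean(sub[[v]]) -
                      tn(tgt$mean[v], tgt$sd[v], bounds[1], bounds[2])),
                3 * se, label = sprintf("gender %d mean %s", g, v))
    }
    expect_true(all(sub$age >= 18 & sub$age <= 25))
  }
  # enforced protocol consistency
  expect_true(all(ch$p2_classic >= ch$p1))
  expect_true(all(ch$p2_iso >= ch$p1))
})

test_that("heart-rate correlation structure is realized and infeasible configs fail", {
  ch <- generate_cohort(generator_config(n = 4000L, prop_women = 0,
                                         seed = 4L))
  expect_gt(cor(ch$p1, ch$p2_iso), 0.35)
  expect_gt(cor(ch$p2_iso, ch$p3_iso), 0.45)
  expect_gt(cor(ch$p2_classic, ch$p2_iso), 0.45)
  expect_error(generator_config(cor_p2_p1 = 0.99, cor_p3_p2 = 0.99,
                                cor_classic_iso = -0.9),
               "positive-definite")
})

test_that("VO2max columns follow the truth model plus configured noise", {
  cfg <- generator_config(n = 3000L, prop_women = 0.5, seed = 6L)
  ch <- generate_cohort(cfg)
  cov <- model_covariates(ch)
  truth <- apply(cov[, c("gender", "age", "weight", "p2i_minus_p1",
                         "ri_iso")], 1,
                 function(z) evaluate_model(published_equation(), z))
  resid_iso <- ch$vo2max_iso - truth
  expect_lt(abs(mean(resid_iso)), 0.15)
  expect_lt(abs(sd(resid_iso) - cfg$noise_sd) / cfg$noise_sd, 0.10)
  d <- ch$vo2max_classic - ch$vo2max_iso
  expect_lt(abs(mean(d) - cfg$paired_diff_mean), 3 * cfg$paired_diff_sd /
              sqrt(nrow(ch)))
  expect_lt(abs(sd(d) - cfg$paired_diff_sd) / cfg$paired_diff_sd, 0.10)
  expect_true(all(ch$vo2max_iso > 10 & ch$vo2max_iso < 90))
})

test_that("the bundled example cohort is self-consistent and serializable", {
  ex <- example_cohort()
  ch <- ex$cohort
  expect_identical(nrow(ch), 35L)
  expect_identical(sum(ch$gender == 1L), 15L)
  # indices column equals a fresh index computation
  expect_equal(ch$ri_iso, ruffier_index(ch$p1, ch$p2_iso, ch$p3_iso),
               tolerance = 1e-12)
  # bundled predictions equal a fresh published-equation evaluation
  fresh <- predict_cohort(ch, published_equation())
  expect_equal(ex$predictions,
               fresh$vo2max_pred_published_model2_equation,
               tolerance = 1e-12)
  # lossless CSV round trip
  f <- withr::local_tempfile()
  write_cohort(ch, f)
  back <- read_cohort(f)
  f2 <- withr::local_tempfile()
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("equivalence holds on generated cohorts at the study's paired-difference settings", {
  # paired difference ~ N(0.46, 3.0), margin 3.726, n = 35: the TOST
  # should declare equivalence in the large majority of replicates
  set.seed(7)
  verdicts <- vapply(1:200, function(k) {
    ch <- generate_cohort(generator_config(seed = 1000L + k))
    tost_paired(ch$vo2max_classic, ch$vo2max_iso, margin = 3.726)$equivalent
  }, logical(1))
  expect_gte(mean(verdicts), 0.9)
})
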