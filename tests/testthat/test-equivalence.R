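test_that("Cohen's d margins convert to raw units as d * sd", {
  expect_equal(d_to_margin(0.46, 8.10), 3.726, tolerance = 1e-12)
  expect_equal(d_to_margin(0, 5), 0)
  # pooled SD of the two printed group SDs gives a slightly different
  # margin than the 2-decimal convention 8.10 — a documented 0.002 gap
  pooled <- sqrt((8.08^2 + 8.11^2) / 2)
  expect_equal(d_to_margin(0.46, pooled), 3.7237, tolerance = 1e-4)
  expect_lt(abs(d_to_margin(0.46, pooled) - 3.726), 0.003)
  expect_error(d_to_margin(0.46, 0), "positive")
  expect_error(d_to_margin(0.46, -1), "positive")
})

test_that("paired TOST reproduces the hand-computed six-point example", {
  # differences (1,-1,0,2,-2,0) vs margin 3: sd = sqrt(2),
  # SE = sqrt(2)/sqrt(6) = 0.5773503, t_{0.95,5} = 2.0150484,
  # CI = 0 -/+ 1.1633887, one-sided p = P(t_5 > 3/SE) = 0.0017391
  # (values verified against an independent TOST implementation)
  x <- c(1, -1, 0, 2, -2, 0)
  r <- tost_paired(x, rep(0, 6), margin = 3)
  expect_equal(r$mean_difference, 0)
  expect_equal(r$sd_used / sqrt(6), 0.57735027, tolerance = 1e-6)
  expect_equal(r$ci_lower, -1.16338872, tolerance = 1e-6)
  expect_equal(r$ci_upper, 1.16338872, tolerance = 1e-6)
  expect_equal(r$p_lower, 0.0017390826, tolerance = 1e-6)
  expect_equal(r$p_upper, 0.0017390826, tolerance = 1e-6)
  expect_true(r$equivalent)
})

test_that("a shift larger than the margin is never equivalent; a huge margin always is", {
  set.seed(101)
  for (k in 1:5) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 50, 5)
    x <- y + 4.5  # constant shift beyond margin 3
    r <- tost_paired(x + rnorm(n, 0, 0.5), y, margin = 3)
    expect_false(r$equivalent)

    r2 <- tost_paired(y + rnorm(n, 0, 1), y, margin = 1e6)
    expect_true(r2$equivalent)
    expect_lt(max(r2$p_lower, r2$p_upper), 1e-6)
  }
})

test_that("verdict by p-values equals verdict by CI containment on random data", {
  set.seed(202)
  for (k in 1:1000) {
    n <- sample(4:25, 1)
    d <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.3, 3))
    margin <- runif(1, 0.2, 3)
    r <- tost_paired(d, rep(0, n), margin = margin)
    by_p <- r$p_lower < r$alpha && r$p_upper < r$alpha
    by_ci <- r$margin_lower < r$ci_lower && r$ci_upper < r$margin_upper
    expect_identical(by_p, by_ci)
    expect_identical(r$equivalent, by_ci)
    expect_lte(r$ci_lower, r$ci_upper)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(tost_paired(c(1, 1, 1), c(0, 0, 0), margin = 1),
               "zero variance")
  expect_error(tost_paired(1:2, 1:2 + 0.5, margin = 1))
  expect_error(tost_power(35, 3, 0, 3.7, method = "monte_carlo", reps = 50),
               "reps")
})

test_that("two-sample TOST agrees with the paired version in structure", {
  set.seed(77)
  x <- rnorm(30, 42, 8)
  y <- rnorm(25, 42.3, 8)
  r <- tost_two_sample(x, y, margin = 3.726)
  expect_identical(r$design, "two_sample")
  expect_equal(r$mean_difference, mean(x) - mean(y))
  expect_identical(r$equivalent,
                   r$margin_lower < r$ci_lower && r$ci_upper < r$margin_upper)
})

test_that("analytic and Monte-Carlo power agree and behave at limits", {
  # cross-validation of the two methods at study-like conditions
  pa <- tost_power(35, 3.0, 0.46, 3.726, method = "analytic")
  pm <- tost_power(35, 3.0, 0.46, 3.726, method = "monte_carlo",
                   reps = 20000, seed = 99)
  expect_lt(abs(pa - pm), 0.02)
  # huge margin, zero truth: certain equivalence
  expect_gt(tost_power(20, 1, 0, 50), 0.999)
  # truth on the margin: power collapses to about alpha
  expect_lte(tost_power(40, 2, 2.5, 2.5), 0.05 + 1e-6)
  pm_edge <- tost_power(40, 2, 2.5, 2.5, method = "monte_carlo",
                        reps = 4000, seed = 3)
  expect_lte(pm_edge, 0.05 + 0.02)
})

test_that("power is monotone in n and margin, antitone in sd and |true diff|", {
  base <- list(n = 30, sd = 2.5, diff = 0.5, margin = 2.0)
  p0 <- tost_power(base$n, base$sd, base$diff, base$margin)
  expect_gte(tost_power(60, base$sd, base$diff, base$margin), p0)
  expect_gte(tost_power(base$n, base$sd, base$diff, 3.0), p0)
  expect_lte(tost_power(base$n, 4.0, base$diff, base$margin), p0)
  expect_lte(tost_power(base$n, base$sd, 1.2, base$margin), p0)
  # the same ordering holds under Monte Carlo within simulation noise
  mc <- function(...) tost_power(..., method = "monte_carlo", reps = 3000,
                                 seed = 11)
  expect_gte(mc(60, base$sd, base$diff, base$margin) + 0.02,
             mc(base$n, base$sd, base$diff, base$margin))
})

test_that("equivalence report writes the full key-value surface", {
  r <- tost_paired(c(1, -1, 0, 2, -2, 0), rep(0, 6), margin = 3)
  f <- withr::local_tempfile()
  write_equivalence_report(r, f, power = 0.99)
  lines <- readLines(f)
  expect_match(lines, "^equivalent=true$", all = FALSE)
  expect_match(lines, "^power=0.99$", all = FALSE)
  expect_match(lines, "^margin_upper=3$", all = FALSE)
})
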