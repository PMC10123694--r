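#' @importFrom MASS mvrnorm
NULL

# Per-gender calibration targets: means and SDs of the study cohort
# summary (20 men, 15 women, healthy 18-25-year-olds). Units: years, cm,
# kg, beats/min.
study_margins <- function() {
  list(
    men = list(
      n = 20L,
      mean = c(age = 21.7, height_cm = 176.45, weight_kg = 75.35,
               p1 = 67.15, p2_classic = 133.45, p3_classic = 105.25,
               p2_iso = 131.55, p3_iso = 105.25),
      sd = c(age = 1.69, height_cm = 5.17, weight_kg = 8.63,
             p1 = 10.4, p2_classic = 12.84, p3_classic = 14.82,
             p2_iso = 13.06, p3_iso = 18.67)
    ),
    women = list(
      n = 15L,
      mean = c(age = 22.53, height_cm = 162.47, weight_kg = 61.87,
               p1 = 72.8, p2_classic = 144.27, p3_classic = 107.33,
               p2_iso = 140.13, p3_iso = 106.93),
      sd = c(age = 2.59, height_cm = 8.13, weight_kg = 9.58,
             p1 = 8.56, p2_classic = 17.16, p3_classic = 20.88,
             p2_iso = 15.45, p3_iso = 19.44)
    )
  )
}

#' Synthetic cohort generator configuration
#'
#' Bundles every knob of the generator with defaults that emulate the
#' study cohort: 35 participants, 15/35 women, per-gender marginal means
#' and SDs of age, height, weight and the five heart rates taken from
#' the printed summary table, heart rates drawn jointly with plausible
#' positive within-participant correlations, isoinertial VO2max
#' generated from the published prediction equation plus residual noise,
#' and classic VO2max as isoinertial plus a paired difference. The
#' paired-difference mean defaults to 0.46 ml/kg/min (the gap between
#' the two printed cohort means, 42.39 - 41.93); its SD is not published
#' and defaults to 3.0 ml/kg/min. Covariates are truncated to
#' physiological/eligibility bounds: age [18, 25], heart rates
#' [40, 220], weight [40, 130], height [140, 210].
#'
#' @param n cohort size.
#' @param prop_women proportion of women; `prop_women * n` must be a
#'   whole number of women.
#' @param margins per-gender means/SDs (structure of the default; only
#'   override for sensitivity experiments).
#' @param cor_p2_p1 correlation between resting and post-exercise rates.
#' @param cor_p3_p2 correlation between post-exercise and recovery
#'   rates within a protocol.
#' @param cor_classic_iso correlation between a classic measurement and
#'   its isoinertial counterpart.
#' @param truth_model `vo2_model` used as ground-truth isoinertial
#'   VO2max (default [published_equation()]).
#' @param noise_sd residual SD around the truth model, ml/kg/min.
#' @param paired_diff_mean,paired_diff_sd distribution of the classic
#'   minus isoinertial VO2max difference, ml/kg/min.
#' @param divisor Ruffier-Dickson divisor used for derived indices.
#' @param seed integer seed; the entire cohort is a deterministic
#'   function of the config.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n = 35L, prop_women = 15 / 35,
                             margins = study_margins(),
                             cor_p2_p1 = 0.5, cor_p3_p2 = 0.6,
                             cor_classic_iso = 0.6,
                             truth_model = published_equation(),
                             noise_sd = 2.0,
                             paired_diff_mean = 0.46,
                             paired_diff_sd = 3.0,
                             divisor = 10,
                             seed = 1L) {
  n_women <- prop_women * n
  if (abs(n_women - round(n_women)) > 1e-8) {
    stop("prop_women * n must be a whole number of women", call. = FALSE)
  }
  stopifnot(noise_sd > 0, paired_diff_sd > 0,
            all(unlist(lapply(margins, function(m) m$sd)) > 0))
  cfg <- list(n = as.integer(n), n_women = as.integer(round(n_women)),
              margins = margins, cor_p2_p1 = cor_p2_p1,
              cor_p3_p2 = cor_p3_p2, cor_classic_iso = cor_classic_iso,
              truth_model = truth_model, noise_sd = noise_sd,
              paired_diff_mean = paired_diff_mean,
              paired_diff_sd = paired_diff_sd,
              divisor = divisor, seed = as.integer(seed))
  # fail fast if the implied HR correlation matrix is infeasible
  hr_correlation(cfg)
  structure(cfg, class = "generator_config")
}

# Correlation matrix over (p1, p2_classic, p3_classic, p2_iso, p3_iso).
# Cross terms not directly configured are set to products of the
# configured path correlations, which keeps the matrix positive-definite
# for sensible settings; infeasible configurations are an error.
hr_correlation <- function(cfg) {
  a <- cfg$cor_p2_p1; b <- cfg$cor_p3_p2; g <- cfg$cor_classic_iso
  r <- diag(5)
  vars <- c("p1", "p2_classic", "p3_classic", "p2_iso", "p3_iso")
  dimnames(r) <- list(vars, vars)
  set <- function(i, j, v) {
    r[i, j] <<- v; r[j, i] <<- v
  }
  set("p1", "p2_classic", a); set("p1", "p2_iso", a)
  set("p2_classic", "p3_classic", b); set("p2_iso", "p3_iso", b)
  set("p2_classic", "p2_iso", g); set("p3_classic", "p3_iso", g)
  set("p1", "p3_classic", a * b); set("p1", "p3_iso", a * b)
  set("p2_classic", "p3_iso", g * b); set("p3_classic", "p2_iso", g * b)
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop("implied heart-rate correlation matrix is not positive-definite",
         call. = FALSE)
  }
  r
}

# Truncated-normal draw by rejection; bounds are far enough from the
# means that rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Theoretical mean of the truncated normal — the generator's true
# expectation for covariates whose eligibility window bites (notably
# age). Exposed for calibration tests.
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

trunc_bounds <- list(
  age = c(18, 25), height_cm = c(140, 210), weight_kg = c(40, 130),
  hr = c(40, 220)
)

# Draw one gender block: covariates independent truncated normals, the
# five HRs jointly normal with the configured correlation, rows
# resampled until HR bounds and p2 >= p1 hold for both protocols.
draw_gender_block <- function(cfg, gender, n_g) {
  m <- if (gender == 0L) cfg$margins$men else cfg$margins$women
  corr <- hr_correlation(cfg)
  hr_vars <- rownames(corr)
  sds <- m$sd[hr_vars]
  sigma <- corr * (sds %o% sds)
  draw_hr <- function(k) {
    x <- MASS::mvrnorm(k, mu = m$mean[hr_vars], Sigma = sigma)
    if (k == 1) x <- matrix(x, nrow = 1, dimnames = list(NULL, hr_vars))
    x
  }
  hr <- draw_hr(n_g)
  repeat {
    bad <- which(
      apply(hr, 1, min) < trunc_bounds$hr[1] |
        apply(hr, 1, max) > trunc_bounds$hr[2] |
        hr[, "p2_classic"] < hr[, "p1"] |
        hr[, "p2_iso"] < hr[, "p1"]
    )
    if (length(bad) == 0) break
    hr[bad, ] <- draw_hr(length(bad))
  }
  tibble::tibble(
    gender = rep(gender, n_g),
    age = rtruncnorm(n_g, m$mean["age"], m$sd["age"],
                     trunc_bounds$age[1], trunc_bounds$age[2]),
    height_cm = rtruncnorm(n_g, m$mean["height_cm"], m$sd["height_cm"],
                           trunc_bounds$height_cm[1],
                           trunc_bounds$height_cm[2]),
    weight_kg = rtruncnorm(n_g, m$mean["weight_kg"], m$sd["weight_kg"],
                           trunc_bounds$weight_kg[1],
                           trunc_bounds$weight_kg[2]),
    p1 = hr[, "p1"], p2_classic = hr[, "p2_classic"],
    p3_classic = hr[, "p3_classic"], p2_iso = hr[, "p2_iso"],
    p3_iso = hr[, "p3_iso"]
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configured study conditions (see
#' [generator_config()]). Isoinertial VO2max is the truth model
#' evaluated on each participant's covariates plus normal residual
#' noise; classic VO2max adds an independent normal paired difference.
#' VO2max draws outside the physiological (10, 90) ml/kg/min window are
#' redrawn. The result is a deterministic function of the config
#' (including its seed).
#'
#' @param config a [generator_config()].
#' @return a cohort table with `vo2max_classic` and `vo2max_iso`
#'   columns; provenance records the seed.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_men <- config$n - config$n_women
  blocks <- list()
  if (n_men > 0) blocks$men <- draw_gender_block(config, 0L, n_men)
  if (config$n_women > 0) {
    blocks$women <- draw_gender_block(config, 1L, config$n_women)
  }
  df <- do.call(rbind, blocks)
  df <- df[sample.int(nrow(df)), ]  # interleave genders
  df <- tibble::as_tibble(df)
  df$id <- sprintf("S%03d", seq_len(nrow(df)))
  df <- df[, cohort_schema]

  cov <- model_covariates(df, divisor = config$divisor)
  needed <- config$truth_model$terms$term
  x <- as.matrix(cov[, needed, drop = FALSE])
  truth <- config$truth_model$intercept + drop(x %*% config$truth_model$terms$b)
  draw_vo2 <- function(mu, sd) {
    v <- stats::rnorm(length(mu), mu, sd)
    bad <- which(v <= 10 | v >= 90)
    while (length(bad) > 0) {
      v[bad] <- stats::rnorm(length(bad), mu[bad], sd)
      bad <- bad[v[bad] <= 10 | v[bad] >= 90]
    }
    v
  }
  df$vo2max_iso <- draw_vo2(truth, config$noise_sd)
  df$vo2max_classic <- draw_vo2(df$vo2max_iso + config$paired_diff_mean,
                                config$paired_diff_sd)
  as_cohort(df, provenance = sprintf("generator seed %d", config$seed))
}

#' Deterministic study-scale example cohort
#'
#' A fixed n = 35 synthetic cohort (20 men, 15 women, seed 20230324)
#' under the default study conditions, bundled with its derived indices
#' and the predictions of the published equation. Used by the test
#' suite and the worked examples as a stable, fully synthetic stand-in
#' for the undeposited participant-level data.
#'
#' @return list with `cohort` (indices appended), `config`, and
#'   `predictions` (published-equation VO2max per participant).
#' @export
example_cohort <- function() {
  config <- generator_config(seed = 20230324L)
  cohort <- generate_cohort(config)
  cohort <- add_indices(cohort, divisor = config$divisor)
  pred <- predict_cohort(cohort, published_equation(),
                         divisor = config$divisor)
  list(cohort = cohort, config = config,
       predictions = pred$vo2max_pred_published_model2_equation)
}
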