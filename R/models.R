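#' Construct a linear VO2max model specification
#'
#' A model spec is the unit the prediction and regression stages exchange:
#' an intercept plus one row per predictor with coefficient `b` and,
#' when known, standard error `se`, t statistic `t`, standardized beta
#' `beta` and p-value `p` (for models transcribed from a printed table,
#' `p` holds the printed upper bound, e.g. 0.001 for "<0.001").
#' Predictor names are fixed and case-sensitive — silent name coercion is
#' a reliable way to hide unit errors.
#'
#' @param name model label.
#' @param intercept intercept in ml/kg/min.
#' @param terms tibble/data frame with columns `term`, `b` and optionally
#'   `se`, `t`, `beta`, `p`; `term` values must come from
#'   `gender, age, weight, p2i_minus_p1, p2i_minus_p3i, ri_iso, rdi_iso`.
#' @param r2,adj_r2 coefficient of determination and its adjusted form
#'   (`NA` when unknown).
#' @param check_names enforce the canonical covariate vocabulary
#'   (default). [fit_ols()] relaxes this: a fitted model takes its
#'   predictor names from its design.
#' @return object of class `vo2_model`.
#' @export
vo2_model <- function(name, intercept, terms, r2 = NA_real_,
                      adj_r2 = NA_real_, check_names = TRUE) {
  allowed <- c("gender", "age", "weight", "p2i_minus_p1", "p2i_minus_p3i",
               "ri_iso", "rdi_iso")
  terms <- tibble::as_tibble(terms)
  stopifnot("term" %in% names(terms), "b" %in% names(terms))
  bad <- if (check_names) setdiff(terms$term, allowed) else character(0)
  if (length(bad) > 0) {
    stop("unknown predictor name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  for (col in c("se", "t", "beta", "p")) {
    if (!col %in% names(terms)) terms[[col]] <- NA_real_
  }
  if (is.finite(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]")
  if (is.finite(r2) && is.finite(adj_r2) && adj_r2 > r2 + 1e-12) {
    stop("adjusted R^2 cannot exceed R^2")
  }
  structure(
    list(name = name, intercept = intercept,
         terms = terms[, c("term", "b", "se", "t", "beta", "p")],
         r2 = r2, adj_r2 = adj_r2),
    class = "vo2_model"
  )
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model> %s\n", x$name))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  print(as.data.frame(x$terms), row.names = FALSE)
  if (is.finite(x$r2)) {
    cat(sprintf("  R^2 = %.4f, adj R^2 = %.4f\n", x$r2, x$adj_r2))
  }
  invisible(x)
}

#' The published isoinertial VO2max prediction equation
#'
#' The final reported prediction model for the isoinertial squat
#' protocol, at its full printed precision:
#' `VO2max = 103.096 - 15.927 gender - 0.785 age - 0.560 weight
#'  + 0.172 (P2i - P1) - 0.806 RI-i`,
#' with gender coded 0 for men and 1 for women, weight in kg, heart-rate
#' terms in beats/min. These three-decimal coefficients are the canonical
#' ones for evaluation (the companion coefficient table prints the same
#' model at two decimals, see [builtin_models()]); they also serve as the
#' ground truth of the synthetic cohort generator.
#'
#' @return a `vo2_model`.
#' @examples
#' evaluate_model(published_equation(),
#'                c(gender = 0, age = 21.7, weight = 75.35,
#'                  p2i_minus_p1 = 64.40, ri_iso = 10.39))
#' @export
published_equation <- function() {
  vo2_model(
    name = "published_model2_equation",
    intercept = 103.096,
    terms = tibble::tibble(
      term = c("gender", "age", "weight", "p2i_minus_p1", "ri_iso"),
      b = c(-15.927, -0.785, -0.560, 0.172, -0.806)
    ),
    r2 = 0.94, adj_r2 = 0.937
  )
}

#' The three printed regression models
#'
#' Transcription of the study's coefficient table: three multiple linear
#' regressions of isoinertial VO2max on gender, age, body weight and
#' heart-rate features. Model 1 uses the raw heart-rate differences
#' (P2i - P1, P2i - P3i); model 2 replaces the second difference with
#' the isoinertial Ruffier index; model 3 with the isoinertial
#' Ruffier-Dickson index. Coefficients, SEs, t statistics, standardized
#' betas and R^2 values are stored as printed (two decimals; p-values as
#' printed upper bounds). Printed LOOCV and classification performance
#' (NRMSE, cross-validated r^2, NMAE, sensitivity, specificity, kappa)
#' is attached as the `performance` attribute of each model.
#'
#' @return named list of three `vo2_model` objects
#'   (`model1`, `model2`, `model3`).
#' @export
builtin_models <- function() {
  m1 <- vo2_model(
    name = "model1", intercept = 93.36,
    terms = tibble::tibble(
      term = c("gender", "age", "weight", "p2i_minus_p1", "p2i_minus_p3i"),
      b    = c(-17.28, -0.78, -0.51, 0.07, 0.15),
      se   = c(1.29, 0.24, 0.05, 0.03, 0.04),
      t    = c(-13.3, -3.22, -9.00, 2.09, 3.51),
      beta = c(-1.07, -0.20, -0.70, 0.22, 0.12),
      p    = c(0.001, 0.01, 0.001, 0.05, 0.01)
    ),
    r2 = 0.89, adj_r2 = 0.87
  )
  attr(m1, "performance") <- c(nrmse = 0.07, r2_cv = 0.84, nmae = 0.06,
                               sensitivity = 0.94, specificity = 0.76,
                               kappa = 0.77)
  m2 <- vo2_model(
    name = "model2", intercept = 103.09,
    terms = tibble::tibble(
      term = c("gender", "age", "weight", "p2i_minus_p1", "ri_iso"),
      b    = c(-15.92, -0.78, -0.56, 0.17, -0.80),
      se   = c(0.92, 0.17, 0.04, 0.02, 0.11),
      t    = c(-17.3, -4.52, -13.75, 6.42, -7.17),
      beta = c(-0.98, -0.20, -0.77, 0.31, -0.36),
      p    = c(0.001, 0.001, 0.001, 0.001, 0.001)
    ),
    r2 = 0.94, adj_r2 = 0.93
  )
  attr(m2, "performance") <- c(nrmse = 0.05, r2_cv = 0.92, nmae = 0.04,
                               sensitivity = 0.89, specificity = 0.81,
                               kappa = 0.81)
  m3 <- vo2_model(
    name = "model3", intercept = 95.33,
    terms = tibble::tibble(
      term = c("gender", "age", "weight", "p2i_minus_p1", "rdi_iso"),
      b    = c(-17.01, -0.78, -0.52, 0.29, -0.16),
      se   = c(1.09, 0.20, 0.04, 0.04, 0.03),
      t    = c(-15.50, -3.77, -10.84, 6.01, -5.26),
      beta = c(-1.05, -0.20, -0.72, 0.54, -0.46),
      p    = c(0.001, 0.001, 0.001, 0.001, 0.001)
    ),
    r2 = 0.92, adj_r2 = 0.91
  )
  attr(m3, "performance") <- c(nrmse = 0.06, r2_cv = 0.88, nmae = 0.04,
                               sensitivity = 0.94, specificity = 0.82,
                               kappa = 0.82)
  list(model1 = m1, model2 = m2, model3 = m3)
}

#' Evaluate a linear model at a covariate vector
#'
#' `intercept + sum(b * x)`, unrounded. Every predictor named by the
#' model must be present; extra covariates are ignored with a warning.
#'
#' @param model a `vo2_model`.
#' @param covariates named numeric vector (or single-row data frame).
#' @return predicted VO2max in ml/kg/min.
#' @export
evaluate_model <- function(model, covariates) {
  stopifnot(inherits(model, "vo2_model"))
  if (is.data.frame(covariates)) covariates <- unlist(covariates[1, ])
  needed <- model$terms$term
  missing_cov <- setdiff(needed, names(covariates))
  if (length(missing_cov) > 0) {
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(covariates), needed)
  if (length(extra) > 0) {
    warning("ignoring covariate(s) not in model: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  model$intercept + sum(model$terms$b * as.numeric(covariates[needed]))
}

#' Assemble model covariates from a cohort
#'
#' Builds the covariate columns the printed models use:
#' `gender`, `age`, `weight` (= `weight_kg`),
#' `p2i_minus_p1 = p2_iso - p1`, `p2i_minus_p3i = p2_iso - p3_iso`, and
#' the isoinertial indices `ri_iso`, `rdi_iso` (computed via
#' [add_indices()] when absent).
#'
#' @param cohort a cohort table.
#' @param divisor Ruffier-Dickson divisor used if indices must be
#'   computed.
#' @return tibble of covariates, one row per participant, with an `id`
#'   column.
#' @export
model_covariates <- function(cohort, divisor = 10) {
  if (!all(c("ri_iso", "rdi_iso") %in% names(cohort))) {
    cohort <- add_indices(cohort, divisor = divisor)
  }
  tibble::tibble(
    id = cohort$id,
    gender = as.numeric(cohort$gender),
    age = cohort$age,
    weight = cohort$weight_kg,
    p2i_minus_p1 = cohort$p2_iso - cohort$p1,
    p2i_minus_p3i = cohort$p2_iso - cohort$p3_iso,
    ri_iso = cohort$ri_iso,
    rdi_iso = cohort$rdi_iso
  )
}

#' Predict VO2max for every cohort record
#'
#' Per-record evaluation of a linear model over covariates assembled by
#' [model_covariates()]. Records with missing required fields get `NA`
#' predictions and are reported in the `failures` attribute instead of
#' aborting the run.
#'
#' @inheritParams model_covariates
#' @param model a `vo2_model`.
#' @return the cohort with a `vo2max_pred_<name>` column appended;
#'   attribute `failures` is a character vector of per-record messages
#'   (empty when all records predicted).
#' @export
predict_cohort <- function(cohort, model, divisor = 10) {
  cov <- model_covariates(cohort, divisor = divisor)
  needed <- model$terms$term
  x <- as.matrix(cov[, needed, drop = FALSE])
  ok <- stats::complete.cases(x)
  pred <- rep(NA_real_, nrow(cov))
  pred[ok] <- model$intercept + drop(x[ok, , drop = FALSE] %*% model$terms$b)
  failures <- sprintf("participant %s: missing covariate(s) %s",
                      cov$id[!ok],
                      vapply(which(!ok), function(i) {
                        paste(needed[is.na(x[i, ])], collapse = ", ")
                      }, character(1)))
  col <- paste0("vo2max_pred_", model$name)
  cohort[[col]] <- pred
  attr(cohort, "failures") <- failures
  cohort
}

#' A pluggable reference VO2max model
#'
#' The pipeline treats the external reference equation that converts a
#' Ruffier-test outcome into VO2max as a pluggable deterministic
#' callable: any function of `(profile, triplet, indices)` returning
#' ml/kg/min can stand in. [surrogate_reference_model()] supplies a
#' synthetic linear surrogate for use in tests and examples — it is a
#' stand-in of this package's own making, not a transcription of any
#' published reference equation.
#'
#' @param fn function `(profile, triplet, indices) -> numeric`.
#' @param name label for reports.
#' @return object of class `reference_vo2max_model` (callable).
#' @export
reference_vo2max_model <- function(fn, name) {
  stopifnot(is.function(fn))
  structure(fn, class = c("reference_vo2max_model", "function"), name = name)
}

#' @rdname reference_vo2max_model
#' @export
surrogate_reference_model <- function() {
  reference_vo2max_model(
    function(profile, triplet, indices) {
      60 - 1.5 * indices$ri - 8 * profile$gender - 0.3 * profile$age
    },
    name = "synthetic_linear_surrogate"
  )
}
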