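#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd
NULL

# Canonical cohort column order. One row per participant; a single resting
# heart rate p1 is shared by the classic and isoinertial protocols by
# construction of the table.
cohort_schema <- c(
  "id", "gender", "age", "height_cm", "weight_kg",
  "p1", "p2_classic", "p3_classic", "p2_iso", "p3_iso"
)

# Optional derived / outcome columns that round-trip through the CSV when
# present.
cohort_extra_cols <- c(
  "vo2max_classic", "vo2max_iso",
  "ri_classic", "rdi_classic", "ri_iso", "rdi_iso"
)

#' Body mass index from height in centimetres
#'
#' Height is carried in centimetres throughout (the unit of the source
#' tables) and converted to metres only here, so the conversion happens in
#' exactly one place.
#'
#' @param weight_kg body weight in kilograms.
#' @param height_cm stature in centimetres.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(75.35, 176.45)
#' @export
bmi <- function(weight_kg, height_cm) {
  assert_finite(weight_kg, "weight_kg")
  assert_finite(height_cm, "height_cm")
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Assemble a cohort table
#'
#' Builds the canonical participant table used by every analysis stage:
#' one row per subject with demographic covariates and the five heart-rate
#' measurements (resting `p1`; post-exercise and 1-min recovery for each
#' protocol). BMI is always recomputed from weight and height, never
#' stored independently.
#'
#' @param df data frame with at least the columns
#'   `id, gender, age, height_cm, weight_kg, p1, p2_classic, p3_classic,
#'   p2_iso, p3_iso`; optional `vo2max_classic`, `vo2max_iso` and derived
#'   index columns are kept.
#' @param provenance free-text origin of the data (file path, generator
#'   seed/config); stored as an attribute.
#' @param validate if `TRUE` (default) invariant violations are an error;
#'   if `FALSE` they are demoted to a single warning.
#' @return a `tibble` with class `ruffier_cohort` and a `provenance`
#'   attribute.
#' @export
as_cohort <- function(df, provenance = "unspecified", validate = TRUE) {
  df <- as_tibble(df)
  missing_cols <- setdiff(cohort_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(cohort_schema, intersect(cohort_extra_cols, names(df)))
  df <- df[, keep]
  df$id <- as.character(df$id)
  df$gender <- as.integer(df$gender)
  for (col in setdiff(keep, c("id", "gender"))) df[[col]] <- as.double(df[[col]])

  violations <- validate_cohort(df)
  if (nrow(violations) > 0) {
    msg <- paste0(utils::head(violations$message, 5L), collapse = "; ")
    if (validate) {
      stop(sprintf("cohort has %d invariant violation(s): %s",
                   nrow(violations), msg), call. = FALSE)
    }
    warning(sprintf("cohort has %d invariant violation(s): %s",
                    nrow(violations), msg), call. = FALSE)
  }
  structure(df, class = c("ruffier_cohort", class(df)),
            provenance = provenance)
}

#' Validate cohort invariants
#'
#' Checks every row of a cohort table against the domain invariants and
#' returns the violations as data, one row per broken rule, rather than
#' raising. Rules: gender code in \{0, 1\}; age, height, weight strictly
#' positive; heart rates strictly positive and below 250 beats/min;
#' VO2max, when present, within (10, 90) ml/kg/min; unique ids. A
#' post-exercise rate below resting (`p2 < p1`) is physiologically odd but
#' occurs in real data, so it produces a violation of severity
#' `"warning"`, never an error.
#'
#' @param df cohort-shaped data frame.
#' @return tibble with columns `id`, `rule`, `severity`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_cohort <- function(df) {
  v <- list()
  add <- function(ids, rule, msg, severity = "error") {
    if (length(ids) > 0) {
      v[[length(v) + 1L]] <<- tibble(
        id = as.character(ids), rule = rule, severity = severity,
        message = sprintf("participant %s: %s", ids, msg)
      )
    }
  }
  dup <- df$id[duplicated(df$id)]
  add(unique(dup), "unique_id", "duplicated id")
  add(df$id[!(df$gender %in% c(0L, 1L))], "gender_code",
      "gender code must be 0 (man) or 1 (woman)")
  for (col in c("age", "height_cm", "weight_kg")) {
    bad <- df$id[!is.na(df[[col]]) & df[[col]] <= 0]
    add(bad, paste0(col, "_positive"), sprintf("%s must be > 0", col))
  }
  for (col in c("p1", "p2_classic", "p3_classic", "p2_iso", "p3_iso")) {
    x <- df[[col]]
    bad <- df$id[!is.na(x) & (x <= 0 | x >= 250)]
    add(bad, paste0(col, "_range"),
        sprintf("%s must lie strictly between 0 and 250 beats/min", col))
  }
  for (col in intersect(c("vo2max_classic", "vo2max_iso"), names(df))) {
    x <- df[[col]]
    bad <- df$id[!is.na(x) & (x <= 10 | x >= 90)]
    add(bad, paste0(col, "_range"),
        sprintf("%s must lie in (10, 90) ml/kg/min", col))
  }
  for (col in c("p2_classic", "p2_iso")) {
    bad <- df$id[!is.na(df[[col]]) & !is.na(df$p1) & df[[col]] < df$p1]
    add(bad, paste0(col, "_below_resting"),
        sprintf("%s below resting p1 (kept, flagged)", col),
        severity = "warning")
  }
  out <- if (length(v) == 0) {
    tibble(id = character(), rule = character(), severity = character(),
           message = character())
  } else {
    do.call(rbind, v)
  }
  out
}

#' Validate a single test record
#'
#' Record-level counterpart of [validate_cohort()] for data arriving as
#' one nested record per participant (profile plus one heart-rate triplet
#' per protocol). Unlike the flat cohort table, a nested record carries a
#' resting rate inside each triplet, so the shared-resting-measurement
#' rule (`classic$p1 == isoinertial$p1`) is checked explicitly. BMI is
#' recomputed from weight and height; a stored `bmi` field is ignored.
#'
#' @param record list with elements `profile` (list: `id`, `gender`,
#'   `age`, `height_cm`, `weight_kg`), `classic` and `isoinertial`
#'   (lists: `p1`, `p2`, `p3`), and optional `vo2max_classic`,
#'   `vo2max_iso`.
#' @return character vector of violation messages, empty when the record
#'   is valid; the recomputed BMI is attached as attribute `"bmi"`.
#' @export
validate_record <- function(record) {
  p <- record$profile
  msgs <- character()
  if (!(p$gender %in% c(0, 1))) {
    msgs <- c(msgs, "gender code must be 0 (man) or 1 (woman)")
  }
  for (f in c("age", "height_cm", "weight_kg")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] <= 0) {
      msgs <- c(msgs, sprintf("%s must be a positive finite number", f))
    }
  }
  for (proto in c("classic", "isoinertial")) {
    tri <- record[[proto]]
    for (f in c("p1", "p2", "p3")) {
      x <- tri[[f]]
      if (is.null(x) || !is.finite(x) || x <= 0 || x >= 250) {
        msgs <- c(msgs, sprintf(
          "%s %s must lie strictly between 0 and 250 beats/min", proto, f))
      }
    }
  }
  if (is.finite(record$classic$p1 %||% NA) &&
      is.finite(record$isoinertial$p1 %||% NA) &&
      record$classic$p1 != record$isoinertial$p1) {
    msgs <- c(msgs,
      "resting heart rate is a single shared measurement: classic p1 must equal isoinertial p1")
  }
  for (f in c("vo2max_classic", "vo2max_iso")) {
    x <- record[[f]]
    if (!is.null(x) && is.finite(x) && (x <= 10 || x >= 90)) {
      msgs <- c(msgs, sprintf("%s must lie in (10, 90) ml/kg/min", f))
    }
  }
  b <- if (length(msgs) == 0) bmi(p$weight_kg, p$height_cm) else NA_real_
  structure(msgs, bmi = b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a numeric for the cohort CSV: 15 significant digits, plain
# notation, NA as empty field. 15 digits makes serialize-parse-serialize
# a fixed point.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.15g", x))
  out
}

#' Write a cohort to its CSV interchange format
#'
#' Comma-separated UTF-8 table, header
#' `id,gender,age,height_cm,weight_kg,p1,p2_classic,p3_classic,p2_iso,p3_iso`
#' (plus any VO2max/index columns present), one row per participant,
#' missing values as empty fields. Numbers are written with 15
#' significant digits so that write -> read -> write reproduces the file
#' byte for byte.
#'
#' @param cohort a cohort table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- names(cohort)
  lines <- paste(cols, collapse = ",")
  body <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- vapply(cols, function(cl) {
      x <- cohort[[cl]][i]
      if (cl == "id") as.character(x)
      else if (cl == "gender") as.character(as.integer(x))
      else fmt_num(x)
    }, character(1))
    paste(row, collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from its CSV interchange format
#'
#' @param path CSV file written by [write_cohort()] or following the same
#'   schema.
#' @param validate error on invariant violations (default); `FALSE`
#'   demotes them to a warning.
#' @return a cohort table with provenance set to the file path.
#' @export
read_cohort <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  for (col in setdiff(names(df), "id")) {
    x <- df[[col]]
    x[x == ""] <- NA
    df[[col]] <- as.numeric(x)
  }
  as_cohort(df, provenance = path, validate = validate)
}

#' Append the recomputed BMI column
#'
#' @param cohort a cohort table.
#' @return the cohort with a `bmi` column (kg/m^2), recomputed from
#'   weight and height.
#' @export
add_bmi <- function(cohort) {
  cohort$bmi <- bmi(cohort$weight_kg, cohort$height_cm)
  cohort
}
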