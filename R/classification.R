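crf_levels <- c("poor", "fair", "good")

#' Default pooled fitness threshold table
#'
#' Cardiorespiratory fitness categories follow the pooled ACSM-style
#' scheme: "poor" pools the very-poor and poor bands, "fair" is the fair
#' band, "good" pools good and above, with sex-specific VO2max bounds.
#' No authoritative numeric cut-offs ship with the analysis inputs, so
#' this packaged default (read from
#' `inst/extdata/acsm_thresholds_synthetic.csv`) is an approximate,
#' synthetic transcription in the spirit of ACSM percentile norms for
#' ages 20-29; it makes the pipeline runnable out of the box but should
#' be replaced by the user's reference table (via `read_thresholds()` or
#' a data frame with the same columns) for any substantive use.
#'
#' @return tibble with columns `gender` (0 man, 1 woman), `poor_upper`,
#'   `fair_upper` (ml/kg/min) and `source`.
#' @export
default_crf_thresholds <- function() {
  path <- system.file("extdata", "acsm_thresholds_synthetic.csv",
                      package = "isoruffier")
  read_thresholds(path)
}

#' @rdname default_crf_thresholds
#' @param path CSV with columns `gender,poor_upper,fair_upper,source`.
#' @export
read_thresholds <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("gender", "poor_upper", "fair_upper") %in% names(df)))
  if (any(df$fair_upper <= df$poor_upper)) {
    stop("thresholds must increase within gender: fair_upper > poor_upper",
         call. = FALSE)
  }
  df
}

#' Classify cardiorespiratory fitness
#'
#' Pooled three-category classification: `poor` if VO2max <= the poor
#' bound, `fair` if <= the fair bound, `good` otherwise. Boundary values
#' fall in the lower category.
#'
#' @param vo2max VO2max values, ml/kg/min.
#' @param gender 0/1 gender codes, recycled against `vo2max`.
#' @param thresholds threshold table, see [default_crf_thresholds()].
#' @return factor with levels `poor < fair < good`.
#' @export
classify_crf <- function(vo2max, gender, thresholds = default_crf_thresholds()) {
  if (!all(gender %in% thresholds$gender)) {
    stop("no thresholds for gender code(s): ",
         paste(setdiff(unique(gender), thresholds$gender), collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(vo2max), length(gender))
  vo2max <- rep_len(vo2max, n)
  gender <- rep_len(gender, n)
  i <- match(gender, thresholds$gender)
  out <- ifelse(vo2max <= thresholds$poor_upper[i], "poor",
                ifelse(vo2max <= thresholds$fair_upper[i], "fair", "good"))
  factor(out, levels = crf_levels, ordered = TRUE)
}

#' Binary-pooled confusion counts between fitness classifications
#'
#' Pools the three categories into positive = \{fair, good\} and
#' negative = \{poor\} and counts: TPc (reference positive, predicted
#' positive — the model did not underestimate into poor), FNc (reference
#' positive, predicted poor — fitness underestimated), TNc (both poor),
#' FPc (reference poor, predicted positive — fitness overestimated).
#'
#' @param reference,predicted category vectors over
#'   \{poor, fair, good\}, equal length.
#' @return named integer vector `c(tpc, fnc, tnc, fpc)`.
#' @export
confusion_from_pairs <- function(reference, predicted) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  stopifnot(length(reference) == length(predicted))
  bad <- setdiff(unique(c(reference, predicted)), crf_levels)
  if (length(bad) > 0) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ref_pos <- reference != "poor"
  pred_pos <- predicted != "poor"
  c(tpc = sum(ref_pos & pred_pos),
    fnc = sum(ref_pos & !pred_pos),
    tnc = sum(!ref_pos & !pred_pos),
    fpc = sum(!ref_pos & pred_pos))
}

#' Sensitivity and specificity from pooled confusion counts
#'
#' `sensitivity = TPc / (TPc + FNc)`,
#' `specificity = TNc / (TNc + FPc)`.
#'
#' @param confusion result of [confusion_from_pairs()].
#' @return named numeric `c(sensitivity, specificity)` (`NaN` when a
#'   denominator is empty).
#' @export
agreement_from_confusion <- function(confusion) {
  c(sensitivity = unname(confusion["tpc"] /
                           (confusion["tpc"] + confusion["fnc"])),
    specificity = unname(confusion["tnc"] /
                           (confusion["tnc"] + confusion["fpc"])))
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` over the full
#' three-category cross-table (agreement is assessed on all three
#' labels, unlike sensitivity/specificity which use the binary pooling).
#' Returns 1 when observed agreement is perfect; errors when expected
#' agreement is 1 while observed is not (kappa undefined).
#'
#' @param reference,predicted category vectors over a shared label set,
#'   equal length >= 1.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(reference, predicted) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  stopifnot(length(reference) == length(predicted), length(reference) >= 1)
  labels <- union(crf_levels, unique(c(reference, predicted)))
  tab <- table(factor(reference, levels = labels),
               factor(predicted, levels = labels))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (po == 1) return(1)
  if (pe == 1) {
    stop("expected agreement is 1 with imperfect observed agreement: kappa undefined",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}
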