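#' Ruffier index
#'
#' Heart-rate recovery index of the Ruffier squat test,
#' `RI = (P1 + P2 + P3 - 200) / 10`, where P1 is the resting rate, P2 the
#' rate immediately after exercise and P3 the rate after one minute of
#' recovery (all beats/min). Lower values indicate better
#' cardiorespiratory fitness. The same formula applies to the isoinertial
#' protocol with its own P2 and P3. The value is returned unrounded; use
#' [round_half_up()] when reporting at printed precision.
#'
#' @param p1,p2,p3 heart rates in beats/min (positive, finite).
#' @return unitless index, unrounded. Vectorised.
#' @examples
#' ruffier_index(69.57, 135.23, 105.97)  # 11.077
#' @export
ruffier_index <- function(p1, p2, p3) {
  assert_finite(p1, "p1"); assert_finite(p2, "p2"); assert_finite(p3, "p3")
  if (any(p1 <= 0) || any(p2 <= 0) || any(p3 <= 0)) {
    stop("heart rates must be strictly positive", call. = FALSE)
  }
  (p1 + p2 + p3 - 200) / 10
}

#' Ruffier-Dickson index
#'
#' `RDI = ((P2 - 70) + 2 * (P3 - P1)) / divisor`. The textbook divisor is
#' 10 and is the default. A `divisor` argument is exposed because
#' published summary tables for the isoinertial protocol are numerically
#' consistent with a divisor of 2, not 10 (e.g. heart rates 69.57,
#' 135.23, 105.97 give 13.803 with divisor 10 but 69.015 with divisor 2,
#' matching a printed 69.01). Which convention a given source used cannot
#' always be recovered from its text, so both are reachable and neither
#' is silently substituted for the other.
#'
#' @inheritParams ruffier_index
#' @param divisor positive scale divisor, default 10.
#' @return unitless index, unrounded. Vectorised.
#' @examples
#' ruffier_dickson_index(69.57, 135.23, 105.97)              # 13.803
#' ruffier_dickson_index(69.57, 135.23, 105.97, divisor = 2) # 69.015
#' @export
ruffier_dickson_index <- function(p1, p2, p3, divisor = 10) {
  assert_finite(p1, "p1"); assert_finite(p2, "p2"); assert_finite(p3, "p3")
  if (any(p1 <= 0) || any(p2 <= 0) || any(p3 <= 0)) {
    stop("heart rates must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop("`divisor` must be a single positive number", call. = FALSE)
  }
  ((p2 - 70) + 2 * (p3 - p1)) / divisor
}

#' Both indices for one heart-rate triplet
#'
#' @inheritParams ruffier_dickson_index
#' @param protocol protocol tag, `"classic"` or `"isoinertial"`.
#' @return one-row tibble with `protocol`, `ri`, `rdi` (unrounded).
#' @export
index_set <- function(p1, p2, p3, divisor = 10,
                      protocol = c("classic", "isoinertial")) {
  protocol <- match.arg(protocol)
  tibble::tibble(
    protocol = protocol,
    ri = ruffier_index(p1, p2, p3),
    rdi = ruffier_dickson_index(p1, p2, p3, divisor = divisor)
  )
}

#' Append index columns to a cohort
#'
#' Computes `ri_classic`, `rdi_classic`, `ri_iso`, `rdi_iso` from the
#' cohort's heart-rate columns. Both indices are linear in the heart
#' rates, so group means of the per-participant indices equal the indices
#' of the group mean heart rates; that is what makes index values
#' computed from printed group means exact.
#'
#' @param cohort a cohort table.
#' @param divisor Ruffier-Dickson divisor, see
#'   [ruffier_dickson_index()].
#' @return the cohort with the four index columns appended/overwritten.
#' @export
add_indices <- function(cohort, divisor = 10) {
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop("`divisor` must be a single positive number", call. = FALSE)
  }
  # formulas applied inline so that a missing heart rate yields a missing
  # index for that record (per-record NA propagation) instead of aborting
  # the whole cohort, unlike the strict scalar index functions
  ri <- function(p1, p2, p3) (p1 + p2 + p3 - 200) / 10
  rdi <- function(p1, p2, p3) ((p2 - 70) + 2 * (p3 - p1)) / divisor
  cohort$ri_classic <- ri(cohort$p1, cohort$p2_classic, cohort$p3_classic)
  cohort$rdi_classic <- rdi(cohort$p1, cohort$p2_classic, cohort$p3_classic)
  cohort$ri_iso <- ri(cohort$p1, cohort$p2_iso, cohort$p3_iso)
  cohort$rdi_iso <- rdi(cohort$p1, cohort$p2_iso, cohort$p3_iso)
  cohort
}
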