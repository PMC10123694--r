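#' @name screening
#' @title Eligibility screening
#' @description
#' The study design admits healthy young adults: the inclusion criteria
#' are age 18-25 (inclusive), no cardiovascular disease, the ability to
#' squat to a 90-degree knee angle, and the ability to follow an
#' 80 beats/min squat rhythm. Ten exclusion criteria remove candidates
#' with recent lower-limb joint trauma, pain during squatting,
#' neurodegenerative disease, musculoskeletal disease or injury, internal
#' medical devices (pacemaker, hearing aid, ...), inability to squat
#' properly or to follow the rhythm in practice, pregnancy, or heart
#' disease. Screening is bookkeeping over explicitly recorded flags — no
#' clinical judgement is applied here.
NULL

# Inclusion flags beyond the age window (age is read off the profile).
inclusion_flags <- c("no_cardiovascular_disease", "can_squat_90deg",
                     "can_follow_80bpm")

exclusion_flags <- c(
  "recent_joint_trauma", "pain_during_squat", "neurodegenerative_disease",
  "musculoskeletal_disease", "musculoskeletal_injury",
  "internal_medical_device", "cannot_squat_properly",
  "cannot_follow_rhythm", "pregnancy", "heart_disease"
)

#' Screen a recruitment roster for eligibility
#'
#' A candidate is eligible iff all four inclusion criteria hold (the age
#' window 18-25 is evaluated from the `age` column; the other three from
#' their 0/1 flag columns) and all ten exclusion flags are 0. A candidate
#' may carry several exclusion reasons; each reason is tallied in the
#' per-reason counts, but the candidate is counted once in the excluded
#' total.
#'
#' @param roster data frame with columns `id`, `age`, the three named
#'   inclusion flag columns and the ten exclusion flag columns (0/1 or
#'   logical).
#' @param strict if `TRUE` (default) any missing flag value is an error
#'   naming the participant and the flag; if `FALSE`, `NA` inclusion
#'   flags are treated as not met and `NA` exclusion flags as not
#'   present.
#' @return list with `eligible` (character ids), `excluded` (tibble
#'   `id`, `reasons` — semicolon-joined), and `reason_counts` (tibble
#'   `reason`, `count`, one row per criterion including the age window).
#' @export
screen_roster <- function(roster, strict = TRUE) {
  stopifnot(nrow(roster) > 0)
  needed <- c("id", "age", inclusion_flags, exclusion_flags)
  missing_cols <- setdiff(needed, names(roster))
  if (length(missing_cols) > 0) {
    stop("roster is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags <- c(inclusion_flags, exclusion_flags)
  if (strict) {
    for (f in flags) {
      bad <- roster$id[is.na(roster[[f]])]
      if (length(bad) > 0) {
        stop(sprintf("unset screening flag `%s` for participant %s",
                     f, bad[1]), call. = FALSE)
      }
    }
  }
  age_ok <- !is.na(roster$age) & roster$age >= 18 & roster$age <= 25
  reasons <- lapply(seq_len(nrow(roster)), function(i) character(0))
  for (i in seq_len(nrow(roster))) {
    r <- character(0)
    if (!age_ok[i]) r <- c(r, "age_in_18_25")
    for (f in inclusion_flags) {
      v <- roster[[f]][i]
      if (is.na(v) || !as.logical(v)) r <- c(r, f)
    }
    for (f in exclusion_flags) {
      v <- roster[[f]][i]
      if (!is.na(v) && as.logical(v)) r <- c(r, f)
    }
    reasons[[i]] <- r
  }
  is_eligible <- lengths(reasons) == 0
  counts <- vapply(c("age_in_18_25", inclusion_flags, exclusion_flags),
                   function(f) sum(vapply(reasons, function(r) f %in% r,
                                          logical(1))),
                   integer(1))
  list(
    eligible = as.character(roster$id[is_eligible]),
    excluded = tibble::tibble(
      id = as.character(roster$id[!is_eligible]),
      reasons = vapply(reasons[!is_eligible], paste, character(1),
                       collapse = ";")
    ),
    reason_counts = tibble::tibble(reason = names(counts),
                                   count = unname(counts))
  )
}

#' Recruitment roster emulating the study's screening outcome
#'
#' Deterministic roster of 50 candidates reproducing the study's printed
#' screening arithmetic: 35 eligible (20 men, 15 women) and 15 excluded,
#' one reason each — 2 recent joint traumas, 1 pain during squatting,
#' 1 neurodegenerative disease, 1 musculoskeletal disease,
#' 2 musculoskeletal injuries, 3 internal medical devices, 3 unable to
#' squat properly, 2 unable to follow the rhythm, 0 pregnancies, 0 heart
#' diseases. Ages and covariates are synthetic placeholders inside the
#' eligible window.
#'
#' @return roster data frame accepted by [screen_roster()].
#' @export
example_screening_roster <- function() {
  reason_plan <- c(
    recent_joint_trauma = 2L, pain_during_squat = 1L,
    neurodegenerative_disease = 1L, musculoskeletal_disease = 1L,
    musculoskeletal_injury = 2L, internal_medical_device = 3L,
    cannot_squat_properly = 3L, cannot_follow_rhythm = 2L,
    pregnancy = 0L, heart_disease = 0L
  )
  n_excluded <- sum(reason_plan)
  n <- 35L + n_excluded
  roster <- tibble::tibble(
    id = sprintf("R%02d", seq_len(n)),
    gender = c(rep(0L, 20L), rep(1L, 15L),
               rep(c(0L, 1L), length.out = n_excluded)),
    age = rep(c(20, 22, 24), length.out = n)
  )
  for (f in inclusion_flags) roster[[f]] <- 1L
  for (f in exclusion_flags) roster[[f]] <- 0L
  i <- 36L
  for (f in names(reason_plan)) {
    k <- reason_plan[[f]]
    if (k > 0) {
      roster[[f]][i:(i + k - 1L)] <- 1L
      i <- i + k
    }
  }
  roster
}

#' Write a screening report
#'
#' Two-column `reason,count` text table over the excluded participants,
#' preceded by the eligible/excluded totals as comment lines.
#'
#' @param screening result of [screen_roster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(screening, path) {
  lines <- c(
    sprintf("# eligible: %d", length(screening$eligible)),
    sprintf("# excluded: %d", nrow(screening$excluded)),
    "reason,count",
    sprintf("%s,%d", screening$reason_counts$reason,
            screening$reason_counts$count)
  )
  writeLines(lines, path)
  invisible(path)
}
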