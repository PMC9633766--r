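#' Severity indicator columns and their qualifying thresholds
#'
#' A PPH case is severe when it shows major bleeding (blood loss >= 1500 mL,
#' transfusion of >= 4 red-blood-cell units, or a surgical
#' procedure/embolization), acute hematologic dysfunction (hemoglobin nadir
#' <= 7 g/dL, platelets <= 50,000 /mm3, disseminated intravascular
#' coagulation), any organ failure, ICU admission, or maternal death.
#' Thresholds are inclusive; a missing value never qualifies.
#'
#' @param blood_loss_ml,rbc_units_transfused,hemoglobin_nadir_g_dl,platelets_per_mm3
#'   numeric (NA allowed).
#' @param surgical_procedure_or_embolization,dic,organ_failure,icu_admission,maternal_death
#'   logical (NA treated as FALSE).
#' @return Logical vector: severe PPH or not.
#' @export
is_severe_pph <- function(blood_loss_ml = NA, rbc_units_transfused = NA,
                          surgical_procedure_or_embolization = FALSE,
                          hemoglobin_nadir_g_dl = NA, platelets_per_mm3 = NA,
                          dic = FALSE, organ_failure = FALSE,
                          icu_admission = FALSE, maternal_death = FALSE) {
  ge <- function(x, t) !is.na(x) & x >= t
  le <- function(x, t) !is.na(x) & x <= t
  tf <- function(x) !is.na(x) & as.logical(x)
  ge(blood_loss_ml, 1500) | ge(rbc_units_transfused, 4) |
    tf(surgical_procedure_or_embolization) |
    le(hemoglobin_nadir_g_dl, 7) | le(platelets_per_mm3, 50000) |
    tf(dic) | tf(organ_failure) | tf(icu_admission) | tf(maternal_death)
}

#' Etiology exclusion flags
#'
#' Cases whose management is etiology-specific and outside the standard
#' first-line PPH pathway are excluded from scoring: surgical wound without
#' associated atony, abnormal placental insertion, uterine rupture, amniotic
#' fluid embolism, vaginal thrombus without associated atony, uterine
#' inversion, secondary PPH, and PPH occurring at home.
#'
#' @return Character vector of the eight flag column names.
#' @export
etiology_flag_names <- function() {
  c("surgical_wound_without_atony", "abnormal_placental_insertion",
    "uterine_rupture", "amniotic_fluid_embolism",
    "vaginal_thrombus_without_atony", "uterine_inversion",
    "secondary_pph", "pph_at_home")
}

#' Is a case excluded on etiology grounds?
#'
#' Union semantics: any true flag excludes the case; flags are not mutually
#' exclusive, so per-flag tallies may overlap and their sum may exceed the
#' number of excluded cases.
#'
#' @param flags data frame (or named list) with logical columns from
#'   [etiology_flag_names()]; absent columns count as all-FALSE.
#' @return Logical vector.
#' @export
is_excluded <- function(flags) {
  flags <- as.data.frame(flags)
  present <- intersect(etiology_flag_names(), names(flags))
  if (!length(present)) return(rep(FALSE, nrow(flags)))
  m <- sapply(present, function(f) {
    v <- flags[[f]]
    !is.na(v) & as.logical(v)
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(flags))
  apply(m, 1, any)
}

#' Build the eligibility flow account for a cohort
#'
#' Applies severity inclusion, then etiology exclusion (as a union over
#' flags), then scoreability, and returns the full flow accounting:
#' `n_input`, `n_severe`, per-flag exclusion counts (overlapping),
#' `n_eligible`, `n_unscoreable`, `n_final`, together with the logical
#' `eligible` vector over input rows.
#'
#' @param cohort data frame carrying the severity indicator columns, the
#'   etiology flag columns, and the context/criterion columns used by
#'   [score_cohort()] to decide scoreability. Missing columns default to
#'   non-qualifying / all-FALSE.
#' @param exclude_missing_criteria passed to [score_cohort()].
#' @return Object of class `pph_flow`: the counts above plus `eligible` and
#'   `scoreable` row masks.
#' @export
build_flow <- function(cohort, exclude_missing_criteria = FALSE) {
  n <- nrow(cohort)
  col <- function(nm, default) if (nm %in% names(cohort)) cohort[[nm]] else
    rep(default, n)
  severe <- is_severe_pph(
    blood_loss_ml = col("blood_loss_ml", NA_real_),
    rbc_units_transfused = col("rbc_units_transfused", NA_real_),
    surgical_procedure_or_embolization =
      col("surgical_procedure_or_embolization", FALSE),
    hemoglobin_nadir_g_dl = col("hemoglobin_nadir_g_dl", NA_real_),
    platelets_per_mm3 = col("platelets_per_mm3", NA_real_),
    dic = col("dic", FALSE), organ_failure = col("organ_failure", FALSE),
    icu_admission = col("icu_admission", FALSE),
    maternal_death = col("maternal_death", FALSE))
  excl <- is_excluded(cohort)
  per_flag <- vapply(etiology_flag_names(), function(f) {
    v <- col(f, FALSE)
    sum(severe & !is.na(v) & as.logical(v))
  }, integer(1))
  eligible <- severe & !excl
  scoreable <- rep(FALSE, n)
  if (any(eligible)) {
    sub <- cohort[eligible, , drop = FALSE]
    sc <- score_cohort(sub, exclude_missing_criteria = exclude_missing_criteria)
    scoreable[eligible] <- !sc$unscoreable
  }
  structure(
    list(n_input = n, n_severe = sum(severe),
         n_excluded_by_flag = as.list(per_flag),
         n_eligible = sum(eligible),
         n_unscoreable = sum(eligible & !scoreable),
         n_final = sum(eligible & scoreable),
         eligible = eligible, scoreable = scoreable),
    class = "pph_flow")
}

#' @export
print.pph_flow <- function(x, ...) {
  cat(sprintf(
    "<flow: %d input -> %d severe -> %d eligible -> %d scored (%d unscoreable)>\n",
    x$n_input, x$n_severe, x$n_eligible, x$n_final, x$n_unscoreable))
  invisible(x)
}

#' Flow account as a flat list for JSON export
#' @param flow a `pph_flow`.
#' @return Named list of integer counts.
#' @export
flow_to_list <- function(flow) {
  stopifnot(inherits(flow, "pph_flow"))
  flow[c("n_input", "n_severe", "n_excluded_by_flag", "n_eligible",
         "n_unscoreable", "n_final")]
}
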