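#' Cohort column registry
#'
#' The columns the pipeline consumes, with their semantic type. Criterion
#' columns use the cell encoding of [parse_status()] (integer delay in
#' minutes, "done", "not_done", "" = missing); unknown columns pass
#' through untouched. Missing values are encoded as the empty string.
#'
#' @return Data frame: `column`, `type`.
#' @export
cohort_schema <- function() {
  rbind(
    data.frame(column = c("woman_id", "unit_id"), type = "identifier"),
    data.frame(column = c("delivery_mode", "uterine_atony"), type = "context"),
    data.frame(column = criterion_names(), type = "criterion"),
    data.frame(column = c("age_band", "country_of_birth", "bmi_band",
                          "parity_cesarean", "previous_pph",
                          "multiple_pregnancy", "pre_eclampsia",
                          "birth_weight_g", "gestational_age_weeks",
                          "delivery_mode_detail"), type = "covariate"),
    data.frame(column = c("blood_loss_ml", "rbc_units_transfused",
                          "surgical_procedure_or_embolization",
                          "hemoglobin_nadir_g_dl", "platelets_per_mm3",
                          "dic", "organ_failure", "icu_admission",
                          "maternal_death", "near_miss"), type = "severity"),
    data.frame(column = etiology_flag_names(), type = "etiology"))
}

#' Read a cohort CSV
#'
#' UTF-8, comma-separated, mandatory header, one row per woman, empty
#' string for missing. Criterion cells are validated against the
#' [parse_status()] encoding; validation problems are collected per row
#' and column and reported — fatally in strict mode, as a warning
#' otherwise. Row order is preserved and extra columns pass through.
#'
#' @param path CSV file path.
#' @param strict stop on any cell-level validation error (default FALSE).
#' @param required columns that must be present (default: identifiers,
#'   context and criterion columns).
#' @return Data frame (all columns character except where numeric parses
#'   cleanly), with attribute `validation` (data frame of row/column/
#'   message, zero rows when clean).
#' @export
read_cohort <- function(path, strict = FALSE,
                        required = c("woman_id", "unit_id", "delivery_mode",
                                     "uterine_atony", criterion_names())) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  absent <- setdiff(required, names(df))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  problems <- list()
  for (cr in intersect(criterion_names(), names(df))) {
    for (i in seq_len(nrow(df))) {
      ok <- tryCatch({ parse_status(df[[cr]][i]); TRUE },
                     error = function(e) FALSE)
      if (!ok) problems[[length(problems) + 1L]] <-
          data.frame(row = i, column = cr,
                     message = sprintf("unparseable value '%s'", df[[cr]][i]))
    }
  }
  validation <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(0), column = character(0),
               message = character(0))
  if (nrow(validation)) {
    msg <- sprintf("%d invalid cell(s), e.g. row %d column %s: %s",
                   nrow(validation), validation$row[1], validation$column[1],
                   validation$message[1])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  # numeric coercion for purely numeric passthrough columns
  for (nm in setdiff(names(df), c(criterion_names(), "woman_id", "unit_id"))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    filled <- nzchar(trimws(df[[nm]]))
    if (any(filled) && !anyNA(v[filled])) {
      v[!filled] <- NA
      df[[nm]] <- v
    }
  }
  attr(df, "validation") <- validation
  df
}

#' Write a cohort CSV in the canonical dialect
#' @param cohort data frame; `NA` written as the empty string.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) if (is.logical(out[[nm]]))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "", ifelse(out[[nm]], "TRUE", "FALSE"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-criterion compliance report
#'
#' For each expected item of care, the number and percentage of women in
#' whom it was met, with context-restricted denominators: the two
#' vaginal-only criteria are reported among vaginal deliveries, and the
#' second-line uterotonic is split into the non-atony row (administered at
#' any time) and the atony row (administered within 30 minutes of the
#' first-line drug). The first-line uterotonic gets both an
#' "administered" and an "on time" row. Percentages are rounded
#' half-away-from-zero to 1 decimal.
#'
#' @param cohort scoreable cohort rows (the rows actually scored).
#' @return Data frame: `item`, `numerator`, `denominator`, `percentage`
#'   (NA when the denominator is zero).
#' @export
compliance_table <- function(cohort) {
  st <- lapply(criterion_names(), function(cr)
    lapply(cohort[[cr]], parse_status))
  names(st) <- criterion_names()
  done <- function(cr) vapply(st[[cr]], status_done, logical(1))
  within <- function(cr, cut) vapply(st[[cr]], status_within, logical(1),
                                     cutoff = cut)
  vaginal <- cohort$delivery_mode == "vaginal"
  atony <- vapply(cohort$uterine_atony, function(x)
    isTRUE(parse_tristate(x)), logical(1))
  row <- function(item, num_mask, den_mask) {
    num <- sum(num_mask & den_mask); den <- sum(den_mask)
    data.frame(item = item, numerator = num, denominator = den,
               percentage = if (den > 0)
                 round_half_away(100 * num / den, 1) else NA_real_)
  }
  all_w <- rep(TRUE, nrow(cohort))
  do.call(rbind, list(
    row("prophylactic_uterotonic", done("prophylactic_uterotonic"), all_w),
    row("blood_loss_documented", done("blood_loss_documented"), all_w),
    row("first_line_uterotonic_administered", done("first_line_uterotonic"),
        all_w),
    row("first_line_uterotonic_within_30", within("first_line_uterotonic", 30),
        all_w),
    row("hemoglobin_within_60", within("hemoglobin_measured", 60), all_w),
    row("hemostasis_within_60", within("hemostasis_measured", 60), all_w),
    row("manual_uterine_exam_within_30_vaginal",
        within("manual_uterine_exam", 30), vaginal),
    row("cervix_vagina_exam_vaginal", done("cervix_vagina_exam"), vaginal),
    row("second_line_administered_no_atony", done("second_line_uterotonic"),
        !atony),
    row("second_line_within_30_atony", within("second_line_uterotonic", 30),
        atony)))
}

#' Cohort characteristics with inadequate-care proportions
#'
#' For each level of each requested characteristic: the share of the
#' cohort (column %) and the proportion with inadequate care within the
#' level (row %), both rounded half-away-from-zero to 1 decimal, with an
#' overall row first. Empty levels are omitted with a message.
#'
#' @param data classified cohort (needs logical `inadequate`).
#' @param characteristics character vector of column names to tabulate.
#' @return Data frame: `characteristic`, `level`, `n`, `column_pct`,
#'   `n_inadequate`, `row_pct`.
#' @export
characteristics_table <- function(data, characteristics) {
  stopifnot("inadequate" %in% names(data))
  n_all <- nrow(data)
  out <- list(data.frame(
    characteristic = "all_women", level = "", n = n_all, column_pct = 100.0,
    n_inadequate = sum(data$inadequate),
    row_pct = round_half_away(100 * mean(data$inadequate), 1)))
  for (ch in characteristics) {
    v <- data[[ch]]
    if (is.logical(v)) v <- ifelse(v, "yes", "no")
    v <- as.character(v)
    for (lev in unique(v[!is.na(v) & nzchar(v)])) {
      mask <- !is.na(v) & v == lev
      if (!sum(mask)) { message("empty level omitted: ", ch, "=", lev); next }
      out[[length(out) + 1L]] <- data.frame(
        characteristic = ch, level = lev, n = sum(mask),
        column_pct = round_half_away(100 * sum(mask) / n_all, 1),
        n_inadequate = sum(data$inadequate[mask]),
        row_pct = round_half_away(100 * mean(data$inadequate[mask]), 1))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the analysis dataset for the determinant models
#'
#' Scores the cohort, flags inadequate care against the percentile
#' threshold, derives the PPH risk profile, and joins the maternity-unit
#' characteristics — producing the per-woman data frame consumed by
#' [run_model_suite()] and [mice_impute()].
#'
#' @param cohort cohort data frame (scoring schema).
#' @param units unit profiles keyed by `unit_id`.
#' @param quantile_level,strict,quantile_method passed to
#'   [classify_inadequate()].
#' @return List: `data` (analysis rows, scored women only), `scores`,
#'   `classification` (`pph_inadequate`), `n_unscoreable`.
#' @export
prepare_analysis_dataset <- function(cohort, units, quantile_level = 0.25,
                                     strict = TRUE,
                                     quantile_method = "linear") {
  sc <- score_cohort(cohort)
  cls <- classify_inadequate(sc$scores$ratio, quantile_level = quantile_level,
                             strict = strict,
                             quantile_method = quantile_method)
  scored <- cohort[!sc$unscoreable, , drop = FALSE]
  scored$score <- sc$scores$ratio
  scored$inadequate <- cls$flags
  scored$risk_profile <- risk_profile(
    parse_logical_col(scored$previous_pph),
    parse_logical_col(scored$multiple_pregnancy),
    parse_logical_col(scored$pre_eclampsia),
    as.numeric(scored$birth_weight_g))
  scored$country_of_birth[!is.na(scored$country_of_birth) &
                            !nzchar(trimws(scored$country_of_birth))] <- NA
  keep_units <- intersect(
    c("unit_id", "status", "level_of_care", "annual_deliveries_band",
      "onsite_obstetrician_24_7", "onsite_anesthesiologist_24_7"),
    names(units))
  u <- units[, keep_units, drop = FALSE]
  for (nm in c("onsite_obstetrician_24_7", "onsite_anesthesiologist_24_7"))
    if (nm %in% names(u)) u[[nm]] <- parse_logical_col(u[[nm]])
  if ("level_of_care" %in% names(u))
    u$level_of_care <- as.character(u$level_of_care)
  merged <- merge(scored, u, by = "unit_id", sort = FALSE)
  merged <- merged[match(scored$woman_id, merged$woman_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(data = merged, scores = sc$scores, classification = cls,
       n_unscoreable = sc$n_unscoreable)
}

parse_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  vapply(x, function(v) {
    r <- parse_tristate(v)
    if (is.na(r)) NA else r
  }, logical(1), USE.NAMES = FALSE)
}

#' Score-run JSON summary
#' @param sc result of [score_cohort()].
#' @param cls result of [classify_inadequate()].
#' @return Named list (threshold, n, n_flagged, n_unscoreable) ready for
#'   [jsonlite::write_json()].
#' @export
score_summary <- function(sc, cls) {
  list(threshold = cls$threshold, quantile_level = cls$quantile_level,
       n = nrow(sc$scores), n_flagged = cls$n_flagged,
       n_unscoreable = sc$n_unscoreable)
}
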