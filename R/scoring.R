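#' Names of the eight quality-of-care criteria
#'
#' The composite score combines eight expert-selected components of PPH
#' prevention and first-line treatment. Criteria are identified throughout
#' the package by these names, in this order.
#'
#' @return Character vector of length 8.
#' @export
criterion_names <- function() {
  c("prophylactic_uterotonic", "blood_loss_documented",
    "first_line_uterotonic", "hemoglobin_measured", "hemostasis_measured",
    "manual_uterine_exam", "cervix_vagina_exam", "second_line_uterotonic")
}

#' Classify the clinical context of a severe PPH case
#'
#' The applicable criteria and the maximum attainable points depend on the
#' clinical context: mode of delivery crossed with whether the PPH cause was
#' uterine atony. Exactly four contexts exist, with maxima 11 (cesarean,
#' no atony), 12 (cesarean, atony), 14 (vaginal, no atony) and 15 (vaginal,
#' atony).
#'
#' @param delivery_mode "cesarean" or "vaginal".
#' @param uterine_atony logical flag; `NA` makes the context unscoreable.
#' @return An object of class `pph_context` with fields `delivery_mode`,
#'   `uterine_atony` and `max_points`.
#' @export
#' @examples
#' classify_context("vaginal", TRUE)$max_points   # 15
#' classify_context("cesarean", FALSE)$max_points # 11
classify_context <- function(delivery_mode, uterine_atony) {
  if (length(delivery_mode) != 1L || is.na(delivery_mode) ||
      !delivery_mode %in% c("cesarean", "vaginal")) {
    stop("unscoreable context: delivery mode must be 'cesarean' or 'vaginal'",
         call. = FALSE)
  }
  if (length(uterine_atony) != 1L || is.na(uterine_atony) ||
      !is.logical(uterine_atony)) {
    stop("unscoreable context: uterine atony flag is missing", call. = FALSE)
  }
  max_points <- if (delivery_mode == "cesarean") {
    if (uterine_atony) 12L else 11L
  } else {
    if (uterine_atony) 15L else 14L
  }
  structure(
    list(delivery_mode = delivery_mode, uterine_atony = uterine_atony,
         max_points = max_points),
    class = "pph_context")
}

#' @export
print.pph_context <- function(x, ...) {
  cat(sprintf("<pph_context: %s, %s (max %d points)>\n", x$delivery_mode,
              if (x$uterine_atony) "uterine atony" else "no uterine atony",
              x$max_points))
  invisible(x)
}

#' Construct a criterion status
#'
#' Care evidence for one criterion: performed with a recorded delay
#' (`done_timed`, minutes from the criterion's anchor), performed with no
#' usable timing (`done_timing_unknown` / `done_untimed`), `not_done`, or
#' `missing` from the chart. Procedures not noted, or incompletely noted, in
#' the medical chart are treated as not done by the scorer.
#'
#' @param state one of "done_timed", "done_timing_unknown", "done_untimed",
#'   "not_done", "missing".
#' @param delay_minutes non-negative delay, required iff `state` is
#'   "done_timed".
#' @return Object of class `pph_status`.
#' @export
criterion_status <- function(state, delay_minutes = NULL) {
  states <- c("done_timed", "done_timing_unknown", "done_untimed",
              "not_done", "missing")
  state <- match.arg(state, states)
  if (state == "done_timed") {
    if (is.null(delay_minutes) || is.na(delay_minutes) || delay_minutes < 0)
      stop("done_timed requires a non-negative delay in minutes", call. = FALSE)
  } else if (!is.null(delay_minutes)) {
    stop("delay_minutes is only meaningful for state 'done_timed'",
         call. = FALSE)
  }
  structure(list(state = state, delay_minutes = delay_minutes),
            class = "pph_status")
}

#' Parse the cohort-file encoding of a criterion cell
#'
#' Cohort CSVs encode each criterion as a delay in integer minutes
#' (performed, timed), the literal `"done"` (performed, timing unknown),
#' `"not_done"`, or the empty string (missing from the chart).
#'
#' @param x character or numeric scalar cell value.
#' @return A `pph_status`.
#' @export
parse_status <- function(x) {
  if (length(x) != 1L) stop("one cell at a time", call. = FALSE)
  if (is.na(x) || identical(trimws(as.character(x)), ""))
    return(criterion_status("missing"))
  x <- trimws(as.character(x))
  if (x == "done") return(criterion_status("done_timing_unknown"))
  if (x == "not_done") return(criterion_status("not_done"))
  delay <- suppressWarnings(as.numeric(x))
  if (is.na(delay))
    stop(sprintf("unparseable criterion value '%s'", x), call. = FALSE)
  criterion_status("done_timed", delay)
}

# TRUE for any "performed" state regardless of timing knowledge
status_done <- function(status) {
  status$state %in% c("done_timed", "done_timing_unknown", "done_untimed")
}

# TRUE when performed with recorded delay <= cutoff (cutoff inclusive)
status_within <- function(status, cutoff) {
  status$state == "done_timed" && status$delay_minutes <= cutoff
}

#' Score a single criterion in a clinical context
#'
#' Implements the published point grid. Weights: major criteria earn 2
#' points when met, minor criteria 1. Timed criteria use inclusive cut-offs
#' (a delay of exactly 30 or 60 minutes earns the on-time points). The
#' first-line uterotonic has a partial-credit row: administered more than 30
#' minutes after PPH diagnosis (or with unknown timing) earns 1. The
#' second-line uterotonic (sulprostone) earns, in non-atony contexts, 1
#' point for administration at any time; in atony contexts 2 points only
#' when given within 30 minutes of the first-line uterotonic, otherwise 0.
#' Manual uterine examination and cervix/vagina examination apply only after
#' vaginal delivery. A `missing` state scores as not done.
#'
#' @param criterion one of [criterion_names()].
#' @param status a `pph_status`.
#' @param context a `pph_context`.
#' @return Integer points awarded, or `NA_integer_` when the criterion is
#'   not applicable in the context.
#' @export
evaluate_criterion <- function(criterion, status, context) {
  criterion <- match.arg(criterion, criterion_names())
  stopifnot(inherits(status, "pph_status"), inherits(context, "pph_context"))
  vaginal <- context$delivery_mode == "vaginal"
  atony <- context$uterine_atony

  switch(criterion,
    prophylactic_uterotonic = if (status_done(status)) 2L else 0L,
    blood_loss_documented = if (status_done(status)) 2L else 0L,
    first_line_uterotonic =
      if (status_within(status, 30)) 2L
      else if (status_done(status)) 1L   # late or timing unknown: administered
      else 0L,
    hemoglobin_measured = if (status_within(status, 60)) 2L else 0L,
    hemostasis_measured = if (status_within(status, 60)) 2L else 0L,
    manual_uterine_exam =
      if (!vaginal) NA_integer_
      else if (status_within(status, 30)) 2L else 0L,
    cervix_vagina_exam =
      if (!vaginal) NA_integer_
      else if (status_done(status)) 1L else 0L,
    second_line_uterotonic =
      if (atony) {
        if (status_within(status, 30)) 2L else 0L
      } else {
        if (status_done(status)) 1L else 0L
      })
}

#' Build a care record from criterion statuses
#'
#' A care record always carries all eight criterion slots; slots that do not
#' apply in a context are ignored by the scorer. Unsupplied slots default to
#' `missing`. The `second_line_uterotonic` delay is anchored at first-line
#' uterotonic administration; every other timed delay is anchored at PPH
#' diagnosis.
#'
#' @param ... named `pph_status` values (or raw cell encodings, see
#'   [parse_status()]) for a subset of [criterion_names()].
#' @return Object of class `pph_care_record`: a named list of `pph_status`.
#' @export
care_record <- function(...) {
  supplied <- list(...)
  bad <- setdiff(names(supplied), criterion_names())
  if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rec <- stats::setNames(
    replicate(8, criterion_status("missing"), simplify = FALSE),
    criterion_names())
  for (nm in names(supplied)) {
    s <- supplied[[nm]]
    rec[[nm]] <- if (inherits(s, "pph_status")) s else parse_status(s)
  }
  structure(rec, class = "pph_care_record")
}

#' Compute the quality-of-care score for one woman
#'
#' Sums the awarded points over the criteria applicable in the clinical
#' context and divides by the context's maximum. The score is the fraction
#' of expected, weighted items of management implemented adequately: 0 when
#' nothing expected was done adequately, 1 when everything was.
#'
#' When the second-line uterotonic was administered but the first-line one
#' never was, the 30-minute anchor is undefined: the dose scores as
#' administered with unknown timing and the result carries a
#' `second_line_anchor_undefined` flag.
#'
#' @param record a `pph_care_record`.
#' @param context a `pph_context`.
#' @return Object of class `pph_quality_score`: `earned_points`,
#'   `max_points`, `ratio`, `scoreable`, `per_criterion` (named integer
#'   vector, `NA` = not applicable), `missing_as_not_done` (criteria where a
#'   missing chart entry was scored as not done),
#'   `second_line_anchor_undefined`.
#' @export
#' @examples
#' ctx <- classify_context("vaginal", TRUE)
#' rec <- care_record(prophylactic_uterotonic = "done",
#'                    blood_loss_documented = "done",
#'                    first_line_uterotonic = 10, hemoglobin_measured = 30,
#'                    hemostasis_measured = 45, manual_uterine_exam = 15,
#'                    cervix_vagina_exam = "done", second_line_uterotonic = 20)
#' compute_score(rec, ctx)$ratio  # 1
compute_score <- function(record, context) {
  stopifnot(inherits(record, "pph_care_record"), inherits(context, "pph_context"))
  per <- vapply(criterion_names(), function(cr)
    evaluate_criterion(cr, record[[cr]], context), integer(1))
  applicable <- !is.na(per)
  missing_sub <- criterion_names()[applicable & vapply(
    criterion_names(), function(cr) record[[cr]]$state == "missing", logical(1))]
  anchor_undef <- context$uterine_atony &&
    !status_done(record$first_line_uterotonic) &&
    record$second_line_uterotonic$state == "done_timed"
  if (anchor_undef) {
    # delay measured from a dose that was never given: the timed row cannot
    # be satisfied, the dose falls to the administered-any-timing row (0 in
    # atony contexts)
    per["second_line_uterotonic"] <- evaluate_criterion(
      "second_line_uterotonic", criterion_status("done_timing_unknown"),
      context)
  }
  earned <- sum(per[applicable])
  structure(
    list(earned_points = as.integer(earned),
         max_points = context$max_points,
         ratio = earned / context$max_points,
         scoreable = TRUE,
         per_criterion = per,
         missing_as_not_done = missing_sub,
         second_line_anchor_undefined = anchor_undef),
    class = "pph_quality_score")
}

#' @export
print.pph_quality_score <- function(x, ...) {
  cat(sprintf("<quality score: %d/%d = %.3f>\n", x$earned_points,
              x$max_points, x$ratio))
  invisible(x)
}

#' Score a whole cohort
#'
#' Applies [compute_score()] to every row of a cohort data frame. Women
#' whose clinical context cannot be established (missing delivery mode or
#' atony flag) cannot be scored; they are excluded from the score vector and
#' counted, mirroring audit practice of reporting how many charts could not
#' be assessed. Optionally, records with any applicable criterion missing
#' from the chart can also be treated as unscoreable rather than scoring
#' missing items as not done.
#'
#' @param cohort data frame with columns `delivery_mode`, `uterine_atony`
#'   and the eight criterion columns (cell encoding of [parse_status()]);
#'   a `woman_id` column is carried through if present.
#' @param exclude_missing_criteria if `TRUE`, a record with any applicable
#'   criterion in the `missing` state is counted as unscoreable instead of
#'   scoring the missing items as not done. Default `FALSE`.
#' @return List with `scores` (data frame: `woman_id`, `earned_points`,
#'   `max_points`, `ratio`, `percentage`), `unscoreable` (logical vector
#'   over input rows) and `n_unscoreable`.
#' @export
score_cohort <- function(cohort, exclude_missing_criteria = FALSE) {
  n <- nrow(cohort)
  if (is.null(cohort$woman_id)) cohort$woman_id <- seq_len(max(n, 0L))
  out <- vector("list", n)
  unscoreable <- logical(n)
  for (i in seq_len(n)) {
    atony <- parse_tristate(cohort$uterine_atony[i])
    ctx <- tryCatch(
      classify_context(as.character(cohort$delivery_mode[i]), atony),
      error = function(e) NULL)
    if (is.null(ctx)) { unscoreable[i] <- TRUE; next }
    rec <- do.call(care_record, stats::setNames(
      lapply(criterion_names(), function(cr) parse_status(cohort[[cr]][i])),
      criterion_names()))
    sc <- compute_score(rec, ctx)
    if (exclude_missing_criteria && length(sc$missing_as_not_done)) {
      unscoreable[i] <- TRUE; next
    }
    out[[i]] <- data.frame(woman_id = cohort$woman_id[i],
                           earned_points = sc$earned_points,
                           max_points = sc$max_points,
                           ratio = sc$ratio)
  }
  scores <- do.call(rbind, out[!unscoreable])
  if (is.null(scores))
    scores <- data.frame(woman_id = character(0), earned_points = integer(0),
                         max_points = integer(0), ratio = numeric(0))
  scores$percentage <- round_half_away(100 * scores$ratio, 1)
  list(scores = scores, unscoreable = unscoreable,
       n_unscoreable = sum(unscoreable))
}

# "yes"/"no"/TRUE/FALSE/1/0 -> logical, anything else NA
parse_tristate <- function(x) {
  if (is.logical(x)) return(x)
  x <- trimws(tolower(as.character(x)))
  if (is.na(x) || x == "") return(NA)
  if (x %in% c("yes", "true", "1")) return(TRUE)
  if (x %in% c("no", "false", "0")) return(FALSE)
  NA
}

#' Flag inadequate care against an empirical percentile threshold
#'
#' Inadequate care is a binary flag for a quality score strictly below the
#' cohort's empirical 25th percentile. The percentile definition is
#' configurable because published audits rarely state one: the default is
#' the linear-interpolation empirical quantile (type 7), the alternative the
#' lower order statistic (type 1). A non-strict (`<=`) comparison is
#' available for sensitivity analysis.
#'
#' @param scores numeric vector of score ratios in \[0, 1\].
#' @param quantile_level percentile defining the threshold (default 0.25).
#' @param strict use strict `<` comparison (default) rather than `<=`.
#' @param quantile_method "linear" (interpolated) or "lower" (order
#'   statistic).
#' @return Object of class `pph_inadequate`: `threshold`, `quantile_level`,
#'   `flags` (logical), `n_flagged`.
#' @export
classify_inadequate <- function(scores, quantile_level = 0.25, strict = TRUE,
                                quantile_method = c("linear", "lower")) {
  if (length(scores) == 0) stop("no scores", call. = FALSE)
  stopifnot(all(scores >= 0 & scores <= 1))
  quantile_method <- match.arg(quantile_method)
  type <- if (quantile_method == "linear") 7L else 1L
  threshold <- unname(stats::quantile(scores, quantile_level, type = type))
  flags <- if (strict) scores < threshold else scores <= threshold
  structure(list(threshold = threshold, quantile_level = quantile_level,
                 strict = strict, flags = flags, n_flagged = sum(flags)),
            class = "pph_inadequate")
}

# round half away from zero, the convention of the printed report tables
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
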