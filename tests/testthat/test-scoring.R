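test_that("the four clinical contexts carry the published point maxima", {
  expect_equal(classify_context("cesarean", FALSE)$max_points, 11L)
  expect_equal(classify_context("cesarean", TRUE)$max_points, 12L)
  expect_equal(classify_context("vaginal", FALSE)$max_points, 14L)
  expect_equal(classify_context("vaginal", TRUE)$max_points, 15L)
})

test_that("an unknown delivery mode or atony flag makes the context unscoreable", {
  expect_error(classify_context("vaginal", NA), "unscoreable")
  expect_error(classify_context("breech", TRUE), "unscoreable")
  expect_error(classify_context(NA_character_, TRUE), "unscoreable")
})

test_that("single-criterion awards match the printed grid rows", {
  vag_at <- classify_context("vaginal", TRUE)
  ces_no <- classify_context("cesarean", FALSE)
  late_fl <- criterion_status("done_timed", 45)
  expect_equal(evaluate_criterion("first_line_uterotonic", late_fl, vag_at), 1L)
  expect_equal(evaluate_criterion("first_line_uterotonic", late_fl, ces_no), 1L)
  # vaginal-only criteria are not applicable after cesarean
  expect_true(is.na(evaluate_criterion("manual_uterine_exam",
                                       criterion_status("done_timed", 10),
                                       ces_no)))
  expect_true(is.na(evaluate_criterion("cervix_vagina_exam",
                                       criterion_status("done_untimed"),
                                       ces_no)))
  # sulprostone within 30 min of oxytocin scores 2 in atony contexts
  expect_equal(evaluate_criterion("second_line_uterotonic",
                                  criterion_status("done_timed", 20), vag_at),
               2L)
  # ... but administration at any time scores 1 only without atony
  vag_no <- classify_context("vaginal", FALSE)
  expect_equal(evaluate_criterion("second_line_uterotonic",
                                  criterion_status("done_timed", 45), vag_no),
               1L)
  expect_equal(evaluate_criterion("second_line_uterotonic",
                                  criterion_status("done_timed", 45), vag_at),
               0L)
})

test_that("timing cut-offs are inclusive at 30 and 60 minutes", {
  ctx <- classify_context("vaginal", TRUE)
  for (spec in list(c("first_line_uterotonic", 30, 2, 1),
                    c("manual_uterine_exam", 30, 2, 0),
                    c("second_line_uterotonic", 30, 2, 0),
                    c("hemoglobin_measured", 60, 2, 0),
                    c("hemostasis_measured", 60, 2, 0))) {
    cr <- spec[1]; cut <- as.numeric(spec[2])
    expect_equal(evaluate_criterion(cr, criterion_status("done_timed", cut), ctx),
                 as.integer(spec[3]), info = cr)
    expect_equal(evaluate_criterion(cr, criterion_status("done_timed", cut + 1e-9), ctx),
                 as.integer(spec[4]), info = cr)
  }
})

test_that("procedures done with unknown timing earn partial credit only on administered rows", {
  vag_at <- classify_context("vaginal", TRUE)
  ces_no <- classify_context("cesarean", FALSE)
  unk <- criterion_status("done_timing_unknown")
  expect_equal(evaluate_criterion("first_line_uterotonic", unk, vag_at), 1L)
  expect_equal(evaluate_criterion("second_line_uterotonic", unk, ces_no), 1L)
  expect_equal(evaluate_criterion("second_line_uterotonic", unk, vag_at), 0L)
  expect_equal(evaluate_criterion("hemoglobin_measured", unk, vag_at), 0L)
  expect_equal(evaluate_criterion("hemostasis_measured", unk, vag_at), 0L)
  expect_equal(evaluate_criterion("manual_uterine_exam", unk, vag_at), 0L)
})

test_that("whole-record scores match hand-summed grid values", {
  all_best <- lapply(list(
    prophylactic_uterotonic = "done", blood_loss_documented = "done",
    first_line_uterotonic = 10, hemoglobin_measured = 30,
    hemostasis_measured = 45, manual_uterine_exam = 15,
    cervix_vagina_exam = "done", second_line_uterotonic = 20), identity)
  rec <- do.call(care_record, all_best)
  expect_equal(compute_score(rec, classify_context("vaginal", TRUE))$ratio, 1)
  s11 <- compute_score(rec, classify_context("cesarean", FALSE))
  expect_equal(s11$earned_points, 11L)
  expect_equal(s11$ratio, 1)
  none <- do.call(care_record, stats::setNames(
    as.list(rep("not_done", 8)), criterion_names()))
  s0 <- compute_score(none, classify_context("cesarean", TRUE))
  expect_equal(s0$earned_points, 0L)
  expect_equal(s0$max_points, 12L)
  expect_equal(s0$ratio, 0)
  late_fl <- all_best
  late_fl$first_line_uterotonic <- 45
  s <- compute_score(do.call(care_record, late_fl),
                     classify_context("vaginal", TRUE))
  expect_equal(s$earned_points, 14L)
  expect_equal(s$ratio, 14 / 15)
})

test_that("scorer agrees with the independently coded grid lookup, exhaustively per criterion", {
  for (mode in c("cesarean", "vaginal")) for (atony in c(FALSE, TRUE)) {
    ctx <- classify_context(mode, atony)
    for (cr in criterion_names()) {
      for (st in oracle_states(cr)) {
        got <- evaluate_criterion(cr, as_pph_status(st), ctx)
        want <- oracle_points(cr, st, mode, atony)
        # vaginal-only criteria: package returns NA (not applicable)
        if (is.na(want)) expect_true(is.na(got)) else
          expect_equal(got, as.integer(want),
                       info = sprintf("%s/%s/%s", cr, st$state,
                                      oracle_context_col(mode, atony)))
      }
    }
  }
})

test_that("scorer agrees with the grid lookup on sampled joint state combinations", {
  set.seed(20412)
  per_cr_states <- lapply(criterion_names(), oracle_states)
  names(per_cr_states) <- criterion_names()
  for (mode in c("cesarean", "vaginal")) for (atony in c(FALSE, TRUE)) {
    ctx <- classify_context(mode, atony)
    for (rep in 1:500) {
      pick <- lapply(per_cr_states, function(ss) ss[[sample.int(length(ss), 1)]])
      rec <- do.call(care_record, lapply(pick, as_pph_status))
      expect_equal(compute_score(rec, ctx)$earned_points,
                   as.integer(oracle_score(pick, mode, atony)))
    }
  }
})

test_that("improving a single criterion never lowers the score", {
  ladders <- list(
    first_line_uterotonic = list("not_done", "done", 45, 30),
    hemoglobin_measured = list("not_done", 61, 60),
    manual_uterine_exam = list("not_done", 31, 30),
    second_line_uterotonic = list("not_done", 31, 30),
    prophylactic_uterotonic = list("not_done", "done"),
    cervix_vagina_exam = list("not_done", "done"))
  base <- stats::setNames(as.list(rep("not_done", 8)), criterion_names())
  for (mode in c("cesarean", "vaginal")) for (atony in c(FALSE, TRUE)) {
    ctx <- classify_context(mode, atony)
    for (cr in names(ladders)) {
      prev <- -1
      for (lv in ladders[[cr]]) {
        rec <- base; rec[[cr]] <- lv
        sc <- compute_score(do.call(care_record, rec), ctx)$earned_points
        expect_gte(sc, prev)
        prev <- sc
      }
    }
  }
})

test_that("missing chart entries score as not done and are recorded", {
  rec <- care_record(prophylactic_uterotonic = "done")  # 7 slots missing
  ctx <- classify_context("vaginal", TRUE)
  sc <- compute_score(rec, ctx)
  expect_equal(sc$earned_points, 2L)
  expect_setequal(sc$missing_as_not_done, setdiff(criterion_names(),
                                                  "prophylactic_uterotonic"))
})

test_that("a second-line dose with no first-line anchor is flagged", {
  rec <- care_record(second_line_uterotonic = 20,
                     first_line_uterotonic = "not_done")
  sc <- compute_score(rec, classify_context("vaginal", TRUE))
  expect_true(sc$second_line_anchor_undefined)
  expect_equal(unname(sc$per_criterion["second_line_uterotonic"]), 0L)
  # without atony the anchorless dose still earns the any-timing point
  sc2 <- compute_score(rec, classify_context("vaginal", FALSE))
  expect_false(sc2$second_line_anchor_undefined)
  expect_equal(unname(sc2$per_criterion["second_line_uterotonic"]), 1L)
})

test_that("cohort scoring excludes and counts context-missing records", {
  rows <- do.call(rbind, c(
    lapply(1:5, function(i) best_row(id = paste0("W", i))),
    lapply(6:7, function(i) {
      r <- best_row(id = paste0("W", i)); r$uterine_atony <- ""; r
    })))
  sc <- score_cohort(rows)
  expect_equal(nrow(sc$scores), 5L)
  expect_equal(sc$n_unscoreable, 2L)
  expect_equal(nrow(sc$scores) + sc$n_unscoreable, nrow(rows))
  all_ok <- score_cohort(do.call(rbind, lapply(1:4, function(i)
    best_row(id = paste0("W", i)))))
  expect_equal(all_ok$n_unscoreable, 0L)
  empty <- score_cohort(best_row()[0, ])
  expect_equal(nrow(empty$scores), 0L)
  expect_equal(empty$n_unscoreable, 0L)
})

test_that("missing-criterion exclusion mode mimics chart-based exclusions", {
  r1 <- best_row(id = "W1")
  r2 <- best_row(id = "W2"); r2$hemoglobin_measured <- ""
  sc <- score_cohort(rbind(r1, r2), exclude_missing_criteria = TRUE)
  expect_equal(nrow(sc$scores), 1L)
  expect_equal(sc$n_unscoreable, 1L)
  sc2 <- score_cohort(rbind(r1, r2))
  expect_equal(nrow(sc2$scores), 2L)
})
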