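spec <- cohort_spec()

test_that("event validation rejects malformed input with the row identified", {
  ev <- toy_events(te("A", 2, "encounter", "ENC"),
                   te("A", 3, "martian", "X1"))
  expect_error(prepare_events(ev), "unknown event category 'martian'")
  ev2 <- toy_events(te("A", 2, "encounter", "ENC"))
  ev2$code[1] <- ""
  expect_error(prepare_events(ev2), "empty code")
})

test_that("cohort filters implement the eligibility rules on a toy cohort", {
  ev <- toy_events(
    enc("A", c(3, 5, 9)), te("A", 9, "diagnosis", "I63.9"),
    enc("B", 4),          te("B", 4, "diagnosis", "I21"),
    enc("C", 2),
    enc("D", 5),          te("D", 2, "diagnosis", "G45"),
    enc("E", 2))
  demo <- toy_demo(c("A", "B", "C", "D"))
  demo <- rbind(demo, toy_demo("E", birth = "2005-01-01"))
  flt <- apply_cohort_filters(prepare_events(ev, ORIGIN), demo, spec)

  expect_setequal(flt$eligible, c("A", "C"))
  expect_equal(flt$excluded[patient_id == "B", reason],
               "no_encounter_before_endpoint_month")
  expect_equal(flt$excluded[patient_id == "D", reason],
               "no_encounter_before_endpoint_month")
  expect_equal(flt$excluded[patient_id == "E", reason],
               "under_age_or_unknown_birth")

  # eligible endpoint patient: rows end the month before the endpoint
  rows <- build_patient_months(flt$events, flt$eligible)
  lab <- code_outcome(rows, flt$events, spec, horizon_end = 30L, demo)
  expect_lte(max(lab[patient_id == "A", month_index]), 8L)
})

test_that("patient-month construction counts encounters and gaps", {
  ev <- prepare_events(toy_events(enc("A", c(2, 2, 5))), ORIGIN)
  rows <- build_patient_months(ev, "A")
  expect_equal(rows$month_index, c(2L, 5L))
  expect_equal(rows$encounter_count, c(2L, 1L))
  expect_equal(rows$gap_months, c(0L, 3L))

  ev1 <- prepare_events(toy_events(enc("B", 7)), ORIGIN)
  expect_equal(build_patient_months(ev1, "B")$gap_months, 0L)

  many <- prepare_events(toy_events(enc(sprintf("P%02d", 1:10), 3)), ORIGIN)
  expect_equal(nrow(build_patient_months(many, sprintf("P%02d", 1:10))), 10L)

  # empty stream is not an error
  expect_equal(nrow(build_patient_months(ev1, character(0))), 0L)
})

test_that("outcome coding honors the window, horizon, censoring and deaths", {
  ev <- prepare_events(toy_events(
    enc("A", c(10, 16)), te("A", 15, "diagnosis", "I63"),
    enc("B", 20),
    enc("C", 6)), ORIGIN)
  demo <- toy_demo(c("A", "B", "C"),
                   extra = data.table(patient_id = "C", attribute = "death_date",
                                      value = as.character(month_start(10L, ORIGIN)),
                                      effective_date = as.Date(NA)))
  rows <- build_patient_months(ev, c("A", "B", "C"))
  lab <- code_outcome(rows, ev, spec, horizon_end = 25L, demo)

  # endpoint at m+5 inside the 12-month window
  expect_equal(lab[patient_id == "A" & month_index == 10, outcome], 1L)
  # endpoint-month row censored away
  expect_false(any(lab[patient_id == "A", month_index] >= 15))
  # window extends past the horizon -> unobservable
  expect_true(is.na(lab[patient_id == "B", outcome]))
  expect_false(lab[patient_id == "B", observable])
  # endpoint-free death at m+4 inside a truncated window -> outcome 0
  expect_equal(lab[patient_id == "C", outcome], 0L)

  expect_warning(
    code_outcome(build_patient_months(ev, "B"), ev, spec, horizon_end = 5L),
    "no patient-month has an observable outcome")
})

test_that("outcome labels match a brute-force relabeler", {
  L <- 12L; horizon <- 40L
  set.seed(421)
  for (i in 1:60) {
    m_enc <- sort(sample(1:38, sample(1:6, 1)))
    endpoint <- if (runif(1) < 0.4) sample(2:44, 1) else NA_integer_
    death <- if (runif(1) < 0.2) sample(2:44, 1) else NA_integer_
    parts <- list(enc("Z", m_enc))
    if (!is.na(endpoint)) parts <- c(parts, list(te("Z", endpoint, "diagnosis", "I63")))
    ev <- prepare_events(do.call(toy_events, parts), ORIGIN)
    demo <- toy_demo("Z")
    if (!is.na(death))
      demo <- rbind(demo, data.table(patient_id = "Z", attribute = "death_date",
                                     value = as.character(month_start(death, ORIGIN)),
                                     effective_date = as.Date(NA)))
    lab <- suppressWarnings(
      code_outcome(build_patient_months(ev, "Z"), ev, spec, horizon, demo))
    for (m in m_enc) {
      want <- relabel_brute(m, endpoint, death, L, horizon)
      got_row <- lab[month_index == m]
      if (want == "censored") {
        expect_equal(nrow(got_row), 0L)
      } else if (want == "unobservable") {
        expect_true(is.na(got_row$outcome))
      } else {
        expect_equal(got_row$outcome, as.integer(want))
      }
    }
  }
})

test_that("split plan reproduces the published window arithmetic", {
  # validation month Apr-17 with an Apr-15 origin is month 25; the analytic
  # window must end Mar-16 (month 12), with follow-up observation Apr-16 to
  # Mar-17 and validation follow-up May-17 to Apr-18
  ev <- prepare_events(toy_events(
    enc(rep(sprintf("P%02d", 1:30), each = 12), rep(1:12, times = 30)),
    te("P01", 14, "diagnosis", "I63"),
    enc(sprintf("P%02d", 1:10), 25)), ORIGIN)
  expect_equal(month_index(as.Date("2017-04-01"), ORIGIN), 25L)
  rows <- build_patient_months(ev, sprintf("P%02d", 1:30))
  lab <- code_outcome(rows, ev, spec, horizon_end = 24L)
  spl <- make_split_plan(lab, 25L, spec, split_seed = 9L)
  expect_equal(spl$plan$analytic_end, 12L)
  expect_equal(spl$plan$observation_window, c(13L, 24L))
  expect_equal(spl$plan$validation_followup, c(26L, 37L))
  expect_equal(month_start(spl$plan$analytic_end, ORIGIN), as.Date("2016-03-01"))
  expect_equal(month_start(spl$plan$validation_followup[2], ORIGIN),
               as.Date("2018-04-01"))

  # patient-level exclusivity and determinism
  spl2 <- make_split_plan(lab, 25L, spec, split_seed = 9L)
  expect_identical(spl$plan$assignment, spl2$plan$assignment)
  expect_length(intersect(unique(spl$training$patient_id),
                          unique(spl$test$patient_id)), 0L)

  # too-early T names the minimum feasible validation month
  expect_error(make_split_plan(lab, 3L, spec), "minimum feasible validation month is 14")
})

test_that("row structure and censoring hold on a generated cohort", {
  co <- small_cohort()
  ev <- prepare_events(co$events)
  flt <- apply_cohort_filters(ev, co$demographics)
  rows <- build_patient_months(flt$events, flt$eligible)

  # one row per distinct (patient, encounter month)
  pairs <- unique(ev[category == "encounter" & patient_id %chin% flt$eligible,
                     .(patient_id, month_index)])
  expect_equal(nrow(rows), nrow(pairs))

  lab <- code_outcome(rows, ev, cohort_spec(), horizon_end = co$config$n_months,
                      co$demographics)
  truth_ep <- co$truth$patients[!is.na(endpoint_month)]
  mx <- lab[, .(mx = max(month_index)), by = patient_id]
  chk <- merge(mx, truth_ep, by = "patient_id")
  expect_true(all(chk$mx <= chk$endpoint_month - 1L))

  # outcome labels agree with the generator's endpoint months
  pos <- lab[outcome == 1L]
  chk2 <- merge(pos, truth_ep, by = "patient_id")
  expect_true(all(chk2$endpoint_month.y >= chk2$month_index + 1L &
                    chk2$endpoint_month.y <= chk2$month_index + 12L))
})
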