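fake_decisions <- function(codes, categories) {
  data.table(code = codes, category = categories, retained = TRUE)
}

toy_plan_world <- function() {
  # one patient with rows at months 2, 5, 9; diagnosis D at 5; medication M at
  # 5; measurement BMI 7 at month 2 and 5 (value 5) with two-in-month at 9
  ev <- prepare_events(toy_events(
    enc("A", c(2, 5, 9)),
    te("A", 5, "diagnosis", "D1"),
    te("A", 5, "medication", "M1"),
    te("A", 2, "vital", "BMI", value = 7),
    te("A", 5, "vital", "BMI", value = 5),
    te("A", 9, "vital", "BMI", value = 3, day = 2),
    te("A", 9, "vital", "BMI", value = 4, day = 20)), ORIGIN)
  rows <- build_patient_months(ev, "A")
  rows[, outcome := 0L]
  list(ev = ev, rows = rows, demo = toy_demo("A"))
}

test_that("indicator schemas encode hand-traced series correctly", {
  w <- toy_plan_world()
  dec <- fake_decisions(c("D1", "M1"), c("diagnosis", "medication"))
  cfg <- encoding_config(numeric_measurements = character(0),
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(w$rows, w$ev, w$demo, dec, cfg)
  dm <- assemble_design_matrix(w$rows, w$ev, w$demo, plan)

  expect_equal(unname(dm$x[, "D1:pp"]), c(0, 1, 1))
  expect_equal(unname(dm$x[, "M1:hist"]), c(0, 0, 1))
  expect_equal(unname(dm$x[, "M1:now"]), c(0, 1, 0))
  # schema algebra on the standalone encoders
  expect_equal(encode_past_present(c(2, 5, 9), 5), c(0L, 1L, 1L))
  expect_equal(encode_historical(c(2, 5, 9), 5), c(0L, 0L, 1L))
  expect_equal(encode_contemporaneous(c(2, 5, 9), 5), c(0L, 1L, 0L))
  expect_equal(encode_past_present(c(2, 5), integer(0)), c(0L, 0L))
  expect_equal(encode_past_present(c(2, 5), 2), c(1L, 1L))
})

test_that("numeric pairs use last-in-month values and a prior running max", {
  w <- toy_plan_world()
  cfg <- encoding_config(numeric_measurements = "BMI",
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(w$rows, w$ev, w$demo, data.table(), cfg)
  dm <- assemble_design_matrix(w$rows, w$ev, w$demo, plan)
  sp <- plan$numeric_specs$BMI
  std <- function(v) (pmin(pmax(v, sp$lo), sp$hi) - sp$mean) / sp$sd

  expect_equal(unname(dm$x[, "BMI:present"]), c(1, 1, 1))
  # last chronological value within month 9 is 4 (day 20)
  expect_equal(unname(dm$x[, "BMI:value"]), std(c(7, 5, 4)))
  # historical value: none before month 2; stays at standardized(7) after
  expect_equal(unname(dm$x[, "BMI:present_hist"]), c(0, 1, 1))
  expect_equal(unname(dm$x[, "BMI:value_hist"]), c(0, std(7), std(7)))
})

test_that("absent measurements encode as (0, 0), i.e. at the analytic mean", {
  ev <- prepare_events(toy_events(
    enc("A", 1:4), te("A", 2, "vital", "SBP", value = 120),
    enc("B", 1:4)), ORIGIN)
  rows <- build_patient_months(ev, c("A", "B"))
  rows[, outcome := 0L]
  ev2 <- prepare_events(toy_events(
    enc("A", 1:4), te("A", 2, "vital", "SBP", value = 120),
    te("A", 3, "vital", "SBP", value = 135),
    enc("B", 1:4)), ORIGIN)
  cfg <- encoding_config(numeric_measurements = "SBP",
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(rows, ev2, toy_demo(c("A", "B")), data.table(), cfg)
  dm <- assemble_design_matrix(rows, ev2, toy_demo(c("A", "B")), plan)
  bidx <- dm$patient_id == "B"
  expect_true(all(dm$x[bidx, "SBP:present"] == 0))
  expect_true(all(dm$x[bidx, "SBP:value"] == 0))
  expect_true(all(dm$x[bidx, "SBP:value_hist"] == 0))
})

test_that("values beyond the trim bounds clip to the bound's encoding", {
  ids <- sprintf("P%03d", 1:100)
  ev <- prepare_events(toy_events(
    enc(ids, 1),
    te(ids, 1, "vital", "BMI", value = seq(15, 45, length.out = 100))), ORIGIN)
  rows <- build_patient_months(ev, ids)
  rows[, outcome := 0L]
  cfg <- encoding_config(numeric_measurements = "BMI",
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(rows, ev, toy_demo(ids), data.table(), cfg)
  sp <- plan$numeric_specs$BMI
  # linear-interpolation percentile bounds recomputed independently
  expect_equal(sp$lo, quantile7_brute(seq(15, 45, length.out = 100), 0.001))
  expect_equal(sp$hi, quantile7_brute(seq(15, 45, length.out = 100), 0.999))

  ev_huge <- prepare_events(toy_events(
    enc("Z", 1), te("Z", 1, "vital", "BMI", value = 1e6)), ORIGIN)
  rz <- build_patient_months(ev_huge, "Z"); rz[, outcome := 0L]
  dmz <- assemble_design_matrix(rz, ev_huge, toy_demo("Z"), plan)
  expect_equal(unname(dmz$x[, "BMI:value"]), (sp$hi - sp$mean) / sp$sd)
})

test_that("zero-variance numerics are dropped with a warning", {
  ev <- prepare_events(toy_events(
    enc(c("A", "B"), 1), te(c("A", "B"), 1, "vital", "BMI", value = 25)), ORIGIN)
  rows <- build_patient_months(ev, c("A", "B"))
  rows[, outcome := 0L]
  cfg <- encoding_config(numeric_measurements = "BMI",
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = FALSE)
  expect_warning(plan <- fit_encoding_plan(rows, ev, toy_demo(c("A", "B")),
                                           data.table(), cfg),
                 "zero analytic variance")
  expect_length(plan$numeric_specs, 0L)
})

test_that("demographics one-hot with missing indicator; time-varying flips", {
  ids <- c("A", "B", "C")
  ev <- prepare_events(toy_events(enc(rep(ids, each = 8), rep(1:8, 3))), ORIGIN)
  rows <- build_patient_months(ev, ids)
  rows[, outcome := 0L]
  demo <- toy_demo(ids, extra = rbind(
    data.table(patient_id = "A", attribute = "smoking", value = "never",
               effective_date = as.Date(NA)),
    data.table(patient_id = "A", attribute = "smoking", value = "current",
               effective_date = month_start(6L, ORIGIN)),
    data.table(patient_id = "B", attribute = "smoking", value = "past",
               effective_date = as.Date(NA))))
  cfg <- encoding_config(numeric_measurements = character(0),
                         demographic_attributes = "smoking",
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(rows, ev, demo, data.table(), cfg)
  dm <- assemble_design_matrix(rows, ev, demo, plan)
  sm_cols <- grep("^smoking=", colnames(dm$x), value = TRUE)
  expect_setequal(sm_cols, c("smoking=current", "smoking=never", "smoking=past",
                             "smoking=missing"))
  # exactly one indicator per row
  expect_true(all(rowSums(dm$x[, sm_cols]) == 1))
  # C has no smoking row -> missing
  expect_true(all(dm$x[dm$patient_id == "C", "smoking=missing"] == 1))
  # A flips from never to current exactly at month 6
  a_never <- dm$x[dm$patient_id == "A", "smoking=never"]
  a_cur <- dm$x[dm$patient_id == "A", "smoking=current"]
  expect_equal(unname(a_never), as.numeric(rows[patient_id == "A", month_index] < 6))
  expect_equal(unname(a_cur), as.numeric(rows[patient_id == "A", month_index] >= 6))
})

test_that("unseen scoring-time level maps to missing with a warning", {
  ids <- c("A", "B")
  ev <- prepare_events(toy_events(enc(rep(ids, each = 3), rep(1:3, 2))), ORIGIN)
  rows <- build_patient_months(ev, ids); rows[, outcome := 0L]
  demo_fit <- toy_demo(ids, extra = data.table(
    patient_id = ids, attribute = "sex", value = "female",
    effective_date = as.Date(NA)))
  cfg <- encoding_config(numeric_measurements = character(0),
                         demographic_attributes = "sex",
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(rows, ev, demo_fit, data.table(), cfg)
  demo_score <- copy(demo_fit)[attribute == "sex" & patient_id == "B",
                               value := "nonbinary"]
  expect_warning(dm <- assemble_design_matrix(rows, ev, demo_score, plan),
                 "unseen in the analytic dataset")
  expect_true(all(dm$x[dm$patient_id == "B", "sex=missing"] == 1))
})

test_that("age is a single standardized, strictly increasing column", {
  ev <- prepare_events(toy_events(enc(rep("A", 13), 1:13),
                                  enc(rep("B", 13), 1:13)), ORIGIN)
  rows <- build_patient_months(ev, c("A", "B")); rows[, outcome := 0L]
  demo <- rbind(toy_demo("A", birth = "1960-02-01"),
                toy_demo("B", birth = "1985-10-01"))
  cfg <- encoding_config(numeric_measurements = character(0),
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = TRUE)
  plan <- fit_encoding_plan(rows, ev, demo, data.table(), cfg)
  dm <- assemble_design_matrix(rows, ev, demo, plan)
  expect_equal(mean(dm$x[, "age"]), 0, tolerance = 1e-9)
  expect_equal(sd(dm$x[, "age"]), 1, tolerance = 1e-9)
  expect_true(all(diff(dm$x[dm$patient_id == "A", "age"]) > 0))
  # scoring uses the frozen analytic constants, not the scored rows' own
  dm_b <- assemble_design_matrix(rows[patient_id == "B"], ev, demo, plan)
  expect_false(abs(mean(dm_b$x[, "age"])) < 1e-6)
})

test_that("column counting follows the schema arithmetic", {
  codes <- c("DXA", "DXB", "DXC", "MEDA", "MEDB", "LABA")
  cats <- c("diagnosis", "diagnosis", "diagnosis", "medication", "medication", "lab")
  ev <- prepare_events(toy_events(
    enc("A", 1:3),
    te("A", rep(2, 6), cats, codes)), ORIGIN)
  rows <- build_patient_months(ev, "A"); rows[, outcome := 0L]
  cfg <- encoding_config(numeric_measurements = character(0),
                         demographic_attributes = character(0),
                         include_descriptors = FALSE, include_age = TRUE)
  plan <- fit_encoding_plan(rows, ev, toy_demo("A"), fake_decisions(codes, cats), cfg)
  dm <- assemble_design_matrix(rows, ev, toy_demo("A"), plan)
  # 3 diagnoses (pp) + 2 medications + 1 lab (hist+now each) + age = 10
  expect_equal(ncol(dm$x), 3 + 2 * 3 + 1)
  # empty retained set: fixed columns only
  plan0 <- fit_encoding_plan(rows, ev, toy_demo("A"), data.table(), cfg)
  dm0 <- assemble_design_matrix(rows, ev, toy_demo("A"), plan0)
  expect_equal(ncol(dm0$x), 1)
})

test_that("matrix contract: no missing cells, binary columns, purity", {
  co <- small_cohort()
  spec <- cohort_spec()
  ev <- prepare_events(co$events)
  flt <- apply_cohort_filters(ev, co$demographics, spec)
  rows <- build_patient_months(flt$events, flt$eligible)
  lab <- code_outcome(rows, ev, spec, horizon_end = 27L, co$demographics)
  analytic <- lab[observable == TRUE & month_index <= 15L]
  eva <- ev[month_index <= 15L]
  dec <- select_predictors(eva, analytic, analytic_end = 15L,
                           endpoint_codes = spec$endpoint_codes)
  plan <- fit_encoding_plan(analytic, eva, co$demographics, dec)
  dm <- assemble_design_matrix(analytic, eva, co$demographics, plan)

  expect_false(anyNA(dm$x))
  bin <- grep(":(pp|hist|now|present|present_hist)$|=", colnames(dm$x))
  expect_true(all(dm$x[, bin] %in% c(0, 1)))
  # standardized analytic columns have mean 0, sd 1
  expect_equal(mean(dm$x[, "age"]), 0, tolerance = 1e-9)
  expect_equal(sd(dm$x[, "age"]), 1, tolerance = 1e-9)

  # past-and-present equals historical OR contemporaneous, recomputed via the
  # standalone encoders patient by patient
  dxs <- head(plan$diagnosis_codes, 4)
  ids <- unique(dm$patient_id)[1:40]
  for (cd in dxs) {
    emo <- eva[code == cd & patient_id %chin% ids, .(patient_id, month_index)]
    for (id in ids) {
      rm_ <- dm$month_index[dm$patient_id == id]
      evm <- emo[patient_id == id, month_index]
      want <- as.integer(encode_historical(rm_, evm) |
                           encode_contemporaneous(rm_, evm))
      expect_equal(unname(dm$x[dm$patient_id == id, paste0(cd, ":pp")]),
                   as.numeric(encode_past_present(rm_, evm)))
      expect_equal(as.numeric(want),
                   unname(dm$x[dm$patient_id == id, paste0(cd, ":pp")]))
    }
  }

  # purity: identical inputs give identical matrices
  dm2 <- assemble_design_matrix(analytic, eva, co$demographics, plan)
  expect_identical(dm$x, dm2$x)

  # leakage guard: constants are invariant to deleting months > analytic end
  plan_trunc <- fit_encoding_plan(analytic, eva[month_index <= 15L],
                                  co$demographics, dec)
  expect_equal(plan_trunc$numeric_specs, plan$numeric_specs)
  expect_equal(plan_trunc$age_spec, plan$age_spec)
  expect_equal(plan_trunc$demographic_specs, plan$demographic_specs)
  # ...and refitting on later data moves them (the guard has teeth)
  later <- lab[observable == TRUE]
  plan_leaky <- fit_encoding_plan(later, ev, co$demographics, dec)
  expect_false(isTRUE(all.equal(plan_leaky$age_spec, plan$age_spec)))
})

test_that("encoding plans survive a JSON round trip", {
  w <- toy_plan_world()
  dec <- fake_decisions(c("D1", "M1"), c("diagnosis", "medication"))
  cfg <- encoding_config(demographic_attributes = character(0),
                         numeric_measurements = "BMI",
                         include_descriptors = FALSE, include_age = FALSE)
  plan <- fit_encoding_plan(w$rows, w$ev, w$demo, dec, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_encoding_plan(plan, path)
  plan2 <- read_encoding_plan(path)
  dm1 <- assemble_design_matrix(w$rows, w$ev, w$demo, plan)
  dm2 <- assemble_design_matrix(w$rows, w$ev, w$demo, plan2)
  expect_equal(dm1$x, dm2$x)
})
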