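#' Run the full algorithm for one pseudo-prospective validation month
#'
#' Executes one complete refresh: truncate the data system to what was known
#' before month `T`, apply cohort filters, build and label the patient-month
#' structure, apply both predictor retention criteria, fit the encoding plan
#' and design matrices, train the shallow network on the 90:10 patient-level
#' split, score the month-`T` validation cohort, observe its follow-up
#' window in the held-back future data, and compute the evaluation metrics.
#' No fitted quantity (retention decision, trim bound, standardization
#' constant, network weight) sees data from months `>= T`; month-`T` events
#' feed only the validation cohort's contemporaneous encodings.
#'
#' @param events full event table (the complete data system; the function
#'   performs the temporal truncation itself).
#' @param demographics long demographics table.
#' @param validation_month integer month index `T`.
#' @param spec a [cohort_spec()].
#' @param sel_cfg a [selection_config()].
#' @param enc_cfg an [encoding_config()].
#' @param model_cfg a [model_config()]; its `train_seed` is re-derived from
#'   `seed`.
#' @param seed integer seed driving the patient split, network
#'   initialization/shuffling and tie-breaking.
#' @param bands list of rank bands for PPV/OR reporting.
#' @param thresholds probability thresholds for sensitivity/specificity.
#' @param train_fraction training share of the analytic patients.
#' @param keep_internals also return the decisions, encoding plan and model
#'   (used by the temporal-hygiene audit and by downstream reporting).
#' @return object of class `validation_month_result`.
#' @export
run_month <- function(events, demographics, validation_month,
                      spec = cohort_spec(), sel_cfg = selection_config(),
                      enc_cfg = encoding_config(), model_cfg = model_config(),
                      seed = 1L, bands = list(c(1L, 100L), c(101L, 200L)),
                      thresholds = c(0.05, 0.025), train_fraction = 0.9,
                      keep_internals = FALSE) {
  T_ <- as.integer(validation_month)
  L <- spec$followup_months
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  ev_all <- stage("ingest", prepare_events(events))
  demo <- as.data.table(demographics)
  # what the system knew when the month-T run happened: months < T for all
  # fitting, month T itself only for the validation cohort's encodings
  ev_fit <- ev_all[month_index < T_]
  ev_thru_T <- ev_all[month_index <= T_]

  flt <- stage("cohort_filters", apply_cohort_filters(ev_thru_T, demo, spec))
  rows <- stage("patient_months", build_patient_months(flt$events, flt$eligible))
  rows_fit <- stage("outcome", code_outcome(rows[month_index < T_], ev_fit, spec,
                                            horizon_end = T_ - 1L,
                                            demographics = demo))
  val_rows <- rows[month_index == T_]
  if (nrow(val_rows) == 0L)
    stop("stage [validation]: validation month ", T_, " has an empty cohort")

  spl <- stage("split", make_split_plan(rows_fit, T_, spec,
                                        split_seed = derive_seed(seed, 11L),
                                        train_fraction = train_fraction))
  analytic <- rbind(spl$training, spl$test)
  analytic_end <- spl$plan$analytic_end
  ev_analytic <- ev_fit[month_index <= analytic_end]

  decisions <- stage("selection",
                     select_predictors(ev_analytic, analytic, sel_cfg,
                                       analytic_end = analytic_end,
                                       endpoint_codes = spec$endpoint_codes))
  plan <- stage("encoding_plan",
                fit_encoding_plan(analytic, ev_analytic, demo, decisions, enc_cfg))
  dm_train <- stage("encode_train",
                    assemble_design_matrix(spl$training, ev_analytic, demo, plan))
  dm_test <- stage("encode_test",
                   assemble_design_matrix(spl$test, ev_analytic, demo, plan))

  model_cfg$train_seed <- derive_seed(seed, 23L)
  model <- stage("train", {
    net <- build_network(ncol(dm_train$x), model_cfg)
    train_network(net, dm_train$x, dm_train$outcome, dm_test$x, dm_test$outcome)
  })

  # validation cohort: patients with an encounter in month T
  val_series <- rows[patient_id %chin% unique(val_rows$patient_id)]
  dm_val <- stage("encode_validation",
                  assemble_design_matrix(val_series, ev_thru_T, demo, plan,
                                         score_months = T_))
  scores_row <- stage("score", predict_risk(model, dm_val))

  # observe the follow-up window in the full (future) data
  val_labeled <- stage("observe",
                       code_outcome(val_rows, ev_all, spec,
                                    horizon_end = max(ev_all$month_index),
                                    demographics = demo))
  # one row per patient at month T; rank patients by their (maximum) score
  sc <- data.table(patient_id = dm_val$patient_id, score = scores_row)
  sc <- sc[, .(score = max(score)), by = patient_id]
  lab <- val_labeled[, .(patient_id, outcome, observable)]
  sc <- merge(sc, lab, by = "patient_id", all.x = TRUE)
  obs <- sc[observable == TRUE]
  if (nrow(obs) == 0L)
    warning("no validation outcome is observable for month ", T_,
            "; metrics are NA")

  mk_band <- function(b) {
    if (nrow(obs) < b[2])
      return(data.table(band = paste(b, collapse = "-"), ppv = NA_real_,
                        odds_ratio = NA_real_))
    pb <- ppv_at_band(obs$score, obs$outcome, b,
                      tiebreak_seed = derive_seed(seed, 31L))
    data.table(band = paste(b, collapse = "-"), ppv = pb$ppv,
               odds_ratio = as.numeric(
                 ppv_to_odds_ratio(pb$band_positives, pb$band_size,
                                   sum(obs$outcome == 1), nrow(obs))))
  }

  res <- list(
    validation_month = T_,
    analytic_patients = length(unique(analytic$patient_id)),
    analytic_outcome_pct = 100 * mean(
      analytic[, .(y = as.integer(any(outcome == 1L))), by = patient_id]$y),
    retained_predictors = sum(decisions$retained),
    predictor_encodings = ncol(dm_train$x),
    cohort_patients = nrow(sc),
    cohort_outcome_pct = if (nrow(obs)) 100 * mean(obs$outcome == 1) else NA_real_,
    auroc = if (nrow(obs)) auroc(obs$score, obs$outcome) else NA_real_,
    auprc = if (nrow(obs)) auprc(obs$score, obs$outcome) else NA_real_,
    band_metrics = rbindlist(lapply(bands, mk_band)),
    threshold_metrics = if (nrow(obs))
      threshold_metrics(obs$score, obs$outcome, thresholds) else NULL,
    risk_descriptives = if (nrow(obs) && length(unique(obs$outcome)) == 2L)
      risk_distribution_descriptives(obs$score, obs$outcome) else NULL,
    seed = seed
  )
  if (keep_internals)
    res$internals <- list(decisions = decisions, plan = plan, model = model,
                          split = spl$plan, scores = sc)
  class(res) <- "validation_month_result"
  res
}

#' @export
print.validation_month_result <- function(x, ...) {
  cat(sprintf(paste0("<validation_month_result> T = %d: %d analytic patients ",
                     "(%.2f%% outcome), %d retained predictors -> %d encodings\n",
                     "  cohort %d patients (%.2f%% outcome)  AUROC %.3f  AUPRC %.3f\n"),
              x$validation_month, x$analytic_patients, x$analytic_outcome_pct,
              x$retained_predictors, x$predictor_encodings,
              x$cohort_patients, x$cohort_outcome_pct, x$auroc, x$auprc))
  if (!is.null(x$band_metrics)) print(x$band_metrics)
  invisible(x)
}

#' Monthly rolling pseudo-prospective validation
#'
#' One full-algorithm run per validation month, plus ordinary-least-squares
#' trend slopes of the headline metrics across months. A failing month
#' aborts the loop with an error of class `rollrisk_rolling_error` whose
#' `partial` field preserves the completed months.
#'
#' @param events,demographics the full data system.
#' @param validation_months integer vector of month indices.
#' @param ... passed to [run_month()].
#' @param seed base seed; each month derives its own.
#' @return list of class `rolling_validation` with `results` (one
#'   [run_month()] result per month), `summary` (metric table) and `trends`
#'   (OLS slope per metric; `NA` with a single month).
#' @export
run_rolling <- function(events, demographics, validation_months, ...,
                        seed = 1L) {
  results <- list()
  for (T_ in validation_months) {
    r <- tryCatch(
      run_month(events, demographics, T_, ..., seed = derive_seed(seed, T_)),
      error = function(e) e)
    if (inherits(r, "error")) {
      cnd <- structure(
        class = c("rollrisk_rolling_error", "error", "condition"),
        list(message = paste0("validation month ", T_, " failed: ",
                              conditionMessage(r)),
             call = NULL, partial = results))
      stop(cnd)
    }
    results[[as.character(T_)]] <- r
  }
  summary <- rbindlist(lapply(results, function(r)
    data.table(validation_month = r$validation_month,
               analytic_patients = r$analytic_patients,
               analytic_outcome_pct = r$analytic_outcome_pct,
               retained_predictors = r$retained_predictors,
               predictor_encodings = r$predictor_encodings,
               cohort_patients = r$cohort_patients,
               cohort_outcome_pct = r$cohort_outcome_pct,
               auroc = r$auroc, auprc = r$auprc,
               or_band1 = r$band_metrics$odds_ratio[1],
               or_band2 = if (nrow(r$band_metrics) > 1)
                 r$band_metrics$odds_ratio[2] else NA_real_)))
  slope <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2L) return(NA_real_)
    unname(coef(lm(y[ok] ~ summary$validation_month[ok]))[2])
  }
  trends <- c(auroc = slope(summary$auroc), auprc = slope(summary$auprc),
              or_band1 = slope(summary$or_band1), or_band2 = slope(summary$or_band2))
  structure(list(results = results, summary = summary[], trends = trends),
            class = "rolling_validation")
}

#' @export
print.rolling_validation <- function(x, ...) {
  cat("<rolling_validation>", nrow(x$summary), "validation months\n")
  print(x$summary)
  cat("OLS trend slopes per month:\n")
  print(round(x$trends, 5))
  invisible(x)
}
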