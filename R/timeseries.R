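#' Cohort and endpoint specification
#'
#' Defines the endpoint code set, eligibility and follow-up rules used to
#' build the longitudinal structure. Endpoint codes are matched by prefix
#' (so `"I63"` matches `"I63.9"`), mirroring how ICD-10 chapter ranges are
#' named. The default code set is the package's worked example endpoint,
#' initial stroke/MI-like codes G45, I63-I64, I20-I25, with a 12-month
#' follow-up window and adult-only eligibility.
#'
#' @param endpoint_codes character vector of code prefixes defining the
#'   endpoint.
#' @param min_age_years minimum age at first encounter.
#' @param followup_months follow-up window length L: the outcome for a row at
#'   month m is observed over months `[m+1, m+L]`.
#' @param death_policy how endpoint-free death inside an outcome window is
#'   coded; only `"code_as_no_outcome"` is implemented (outcome 0).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(endpoint_codes = c("G45", "I63", "I64",
                                           "I20", "I21", "I22", "I23", "I24", "I25"),
                        min_age_years = 18L,
                        followup_months = 12L,
                        death_policy = "code_as_no_outcome") {
  stopifnot(length(endpoint_codes) >= 1, followup_months >= 1,
            death_policy == "code_as_no_outcome")
  structure(list(endpoint_codes = endpoint_codes,
                 min_age_years = as.integer(min_age_years),
                 followup_months = as.integer(followup_months),
                 death_policy = death_policy),
            class = "cohort_spec")
}

VALID_CATEGORIES <- c("encounter", "diagnosis", "procedure", "medication",
                      "lab", "flowsheet", "vital", "chief_complaint")

# prefix match against the endpoint code set
is_endpoint_code <- function(code, endpoint_codes) {
  hit <- rep(FALSE, length(code))
  for (p in endpoint_codes) hit <- hit | startsWith(code, p)
  hit
}

#' Validate an event table and attach month indices
#'
#' Checks the event-table contract (required columns, known categories,
#' non-empty codes, numeric values only on measurement categories) and adds
#' an integer `month_index` column counted from `origin`.
#'
#' @param events `data.frame`/`data.table` with `patient_id`, `category`,
#'   `code`, `event_date` and optionally `numeric_value`.
#' @param origin `Date` of the data system's inception month (index 1).
#'   Defaults to the month of the earliest event.
#' @return a keyed `data.table` with `month_index`; the origin used is
#'   attached as attribute `"origin"`.
#' @export
prepare_events <- function(events, origin = NULL) {
  ev <- as.data.table(events)
  req <- c("patient_id", "category", "code", "event_date")
  miss <- setdiff(req, names(ev))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  if (!"numeric_value" %in% names(ev)) ev[, numeric_value := NA_real_]
  if (!inherits(ev$event_date, "Date")) ev[, event_date := as.Date(event_date)]
  bad <- which(!ev$category %in% VALID_CATEGORIES)
  if (length(bad))
    stop("unknown event category '", ev$category[bad[1]], "' at row ", bad[1],
         " (patient ", ev$patient_id[bad[1]], ")")
  badcode <- which(is.na(ev$code) | ev$code == "")
  if (length(badcode)) stop("empty code at row ", badcode[1])
  if (is.null(origin)) origin <- attr(events, "origin") %||% min(ev$event_date)
  origin <- as.Date(format(min(origin), "%Y-%m-01"))
  ev[, month_index := month_index(event_date, origin)]
  setattr(ev, "origin", origin)
  setkey(ev, patient_id, month_index)
  ev[]
}

# per-patient summary used by the eligibility filter
patient_event_summary <- function(ev, spec) {
  enc <- ev[category == "encounter",
            .(first_enc_month = min(month_index)), by = patient_id]
  epv <- ev[is_endpoint_code(code, spec$endpoint_codes),
            .(endpoint_month = min(month_index)), by = patient_id]
  info <- merge(enc, epv, by = "patient_id", all = TRUE)
  info
}

#' Apply cohort eligibility filters
#'
#' A patient is eligible when they have at least one hospital encounter, are
#' at least `min_age_years` old at their first encounter, and -- if they ever
#' exhibit the endpoint -- their first encounter is endpoint-free and occurs
#' at least one calendar month before the endpoint's month.
#'
#' @param events an event table (run through [prepare_events()] if needed).
#' @param demographics long demographics table with `patient_id`,
#'   `attribute`, `value`, `effective_date`; `birth_date` is used for the
#'   age rule (patients without one fail eligibility).
#' @param spec a [cohort_spec()].
#' @param origin optional inception `Date` passed to [prepare_events()].
#' @return list with `eligible` (character vector of patient ids), `excluded`
#'   (`data.table` of id and reason), `events` (prepared table) and `info`
#'   (per-patient first-encounter/endpoint months).
#' @export
apply_cohort_filters <- function(events, demographics, spec = cohort_spec(),
                                 origin = NULL) {
  ev <- if (is.null(attr(events, "origin")) || !"month_index" %in% names(events))
    prepare_events(events, origin) else as.data.table(events)
  origin <- attr(ev, "origin")
  demo <- as.data.table(demographics)
  info <- patient_event_summary(ev, spec)

  birth <- demo[attribute == "birth_date",
                .(birth_date = as.Date(value[1])), by = patient_id]
  info <- merge(info, birth, by = "patient_id", all.x = TRUE)
  all_ids <- unique(ev$patient_id)
  info <- merge(data.table(patient_id = all_ids), info, by = "patient_id", all.x = TRUE)

  age_at_first <- as.numeric(month_start(info$first_enc_month, origin) - info$birth_date) / 365.25

  reason <- rep(NA_character_, nrow(info))
  reason[is.na(info$first_enc_month)] <- "no_encounter"
  sel <- is.na(reason) & (is.na(info$birth_date) | age_at_first < spec$min_age_years)
  reason[sel] <- "under_age_or_unknown_birth"
  # endpoint patients: need an encounter strictly before the endpoint month,
  # so a first encounter co-occurring with or following the endpoint excludes
  sel <- is.na(reason) & !is.na(info$endpoint_month) &
    info$first_enc_month >= info$endpoint_month
  reason[sel] <- "no_encounter_before_endpoint_month"

  excluded <- data.table(patient_id = info$patient_id, reason = reason)[!is.na(reason)]
  list(eligible = info$patient_id[is.na(reason)],
       excluded = excluded,
       events = ev,
       info = info)
}

#' Build the patient-month longitudinal structure
#'
#' One row per (patient, calendar month with at least one hospital
#' encounter). `encounter_count` is the number of encounter events that
#' month and `gap_months` the number of months since the patient's previous
#' patient-month (0 for the first row).
#'
#' @param events prepared event table.
#' @param eligible character vector of eligible patient ids.
#' @return `data.table` with `patient_id`, `month_index`, `encounter_count`,
#'   `gap_months`, sorted by patient then month.
#' @export
build_patient_months <- function(events, eligible) {
  ev <- as.data.table(events)
  rows <- ev[patient_id %chin% eligible & category == "encounter",
             .(encounter_count = .N), by = .(patient_id, month_index)]
  if (nrow(rows) == 0L)
    return(data.table(patient_id = character(), month_index = integer(),
                      encounter_count = integer(), gap_months = integer()))
  setorder(rows, patient_id, month_index)
  rows[, gap_months := {
    g <- month_index - shift(month_index)
    g[1] <- 0L
    as.integer(g)
  }, by = patient_id]
  rows[]
}

#' Code the outcome with censoring
#'
#' For a row at month `m` the outcome is 1 when an endpoint code occurs in
#' months `[m+1, m+L]`; 0 when that window is fully observable (i.e.
#' `m + L <= horizon_end`) and endpoint-free, or when the patient dies
#' endpoint-free inside the window (the default death policy); otherwise the
#' outcome is unobservable (`NA`) and `observable` is `FALSE`. Rows of
#' endpoint patients at or after the endpoint month are removed (censoring).
#'
#' @param rows patient-month table from [build_patient_months()].
#' @param events prepared event table (source of endpoint months).
#' @param spec a [cohort_spec()].
#' @param horizon_end last month index for which data exist.
#' @param demographics optional demographics table supplying `death_date`.
#' @return the row table with `endpoint_month`, `outcome` (integer/NA) and
#'   `observable` (logical) columns added and censored rows dropped.
#' @export
code_outcome <- function(rows, events, spec, horizon_end, demographics = NULL) {
  rows <- copy(as.data.table(rows))
  if (nrow(rows) == 0L) {
    rows[, `:=`(endpoint_month = integer(), outcome = integer(), observable = logical())]
    return(rows[])
  }
  ev <- as.data.table(events)
  origin <- attr(ev, "origin")
  epv <- ev[is_endpoint_code(code, spec$endpoint_codes),
            .(endpoint_month = min(month_index)), by = patient_id]
  rows[, endpoint_month := epv[rows, on = "patient_id", x.endpoint_month]]

  death <- NULL
  if (!is.null(demographics)) {
    demo <- as.data.table(demographics)
    death <- demo[attribute == "death_date",
                  .(death_month = month_index(as.Date(value[1]), origin)), by = patient_id]
  }
  rows[, death_month := if (is.null(death)) NA_integer_
       else death[rows, on = "patient_id", x.death_month]]

  # censoring: drop rows at/after the endpoint month
  rows <- rows[is.na(endpoint_month) | month_index < endpoint_month]

  L <- spec$followup_months
  rows[, outcome := NA_integer_]
  rows[, observable := FALSE]
  rows[!is.na(endpoint_month) & endpoint_month >= month_index + 1L &
         endpoint_month <= month_index + L,
       `:=`(outcome = 1L, observable = TRUE)]
  rows[is.na(outcome) & month_index + L <= horizon_end,
       `:=`(outcome = 0L, observable = TRUE)]
  rows[is.na(outcome) & !is.na(death_month) & death_month <= month_index + L &
         death_month <= horizon_end,
       `:=`(outcome = 0L, observable = TRUE)]
  if (!any(rows$observable))
    warning("no patient-month has an observable outcome (horizon_end = ",
            horizon_end, ")")
  rows[, death_month := NULL]
  rows[]
}

#' Temporal and patient-level data splits for a validation month
#'
#' For validation month `T` the analytic dataset comprises rows old enough
#' that the full follow-up window lies before `T` (months up to `T - L - 1`)
#' with observable outcomes; months `[T-L, T-1]` serve only for outcome
#' observation; month-`T` rows form the pseudo-prospective validation
#' cohort. The analytic patients are partitioned 90:10 into training and
#' test sets by a seeded uniform draw per patient id, so all rows of a
#' patient fall on one side.
#'
#' @param rows labeled patient-month table (see [code_outcome()]).
#' @param validation_month integer month index `T`.
#' @param spec a [cohort_spec()].
#' @param split_seed integer seed for the patient-level partition.
#' @param train_fraction training share of analytic patients (default 0.90).
#' @return list of class `split_plan` with the window bookkeeping and the
#'   four row subsets `training`, `test`, `validation`, `unused`.
#' @export
make_split_plan <- function(rows, validation_month, spec = cohort_spec(),
                            split_seed = 1L, train_fraction = 0.9) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  rows <- as.data.table(rows)
  L <- spec$followup_months
  T_ <- as.integer(validation_month)
  analytic_end <- T_ - L - 1L
  analytic <- rows[observable == TRUE & month_index <= analytic_end]
  if (nrow(analytic) == 0L) {
    min_T <- if (nrow(rows)) min(rows$month_index) + L + 1L else NA_integer_
    stop("validation month ", T_, " admits an empty analytic dataset; ",
         "the minimum feasible validation month is ", min_T)
  }
  validation <- rows[month_index == T_]
  ids <- sort(unique(analytic$patient_id))
  u <- withr::with_seed(as.integer(split_seed), runif(length(ids)))
  train_ids <- ids[u < train_fraction]
  plan <- list(validation_month = T_, followup_months = L,
               analytic_end = analytic_end,
               observation_window = c(T_ - L, T_ - 1L),
               validation_followup = c(T_ + 1L, T_ + L),
               train_fraction = train_fraction, split_seed = as.integer(split_seed),
               assignment = data.table(patient_id = ids,
                                       partition = fifelse(u < train_fraction,
                                                           "training", "test")))
  out <- list(plan = plan,
              training = analytic[patient_id %chin% train_ids],
              test = analytic[!patient_id %chin% train_ids],
              validation = validation,
              unused = rows[month_index > analytic_end & month_index != T_])
  class(out) <- "split_plan"
  out
}

#' @export
print.split_plan <- function(x, ...) {
  p <- x$plan
  cat(sprintf(paste0("<split_plan> T = %d (L = %d): analytic <= %d ",
                     "(%d train / %d test rows), validation %d rows\n"),
              p$validation_month, p$followup_months, p$analytic_end,
              nrow(x$training), nrow(x$test), nrow(x$validation)))
  invisible(x)
}
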