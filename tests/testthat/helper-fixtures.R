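library(data.table)

ORIGIN <- as.Date("2015-04-01")

# build a toy event table from (patient, month, category, code [, value, day])
toy_events <- function(...) {
  df <- rbindlist(lapply(list(...), function(r) {
    as.data.table(r)
  }), fill = TRUE)
  if (!"value" %in% names(df)) df[, value := NA_real_]
  if (!"day" %in% names(df)) df[, day := 5L]
  df[is.na(day), day := 5L]
  out <- df[, .(patient_id = pid, category, code,
                event_date = month_start(month, ORIGIN) + (day - 1L),
                numeric_value = value)]
  out
}

te <- function(pid, month, category, code, value = NA_real_, day = 5L) {
  data.table(pid = pid, month = month, category = category, code = code,
             value = value, day = day)
}

# demographics rows; adult birth date by default
toy_demo <- function(ids, birth = "1970-06-15", extra = NULL) {
  d <- data.table(patient_id = ids, attribute = "birth_date", value = birth,
                  effective_date = as.Date(NA))
  if (!is.null(extra)) d <- rbind(d, extra)
  d
}

# monthly encounters shorthand
enc <- function(pid, months) te(pid, months, "encounter", "ENC")

# cached synthetic cohorts (generation is the expensive step; testthat runs
# all files in one process so these are built at most once per run)
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, cfg) {
  if (is.null(.cohort_cache[[name]]))
    .cohort_cache[[name]] <- generate_cohort(cfg)
  .cohort_cache[[name]]
}

small_cohort <- function() {
  cached_cohort("small", synthetic_config(
    n_patients = 700L, n_months = 40L, n_null_codes = 250L,
    entry_window = c(1L, 14L), codes_per_encounter_month = 5,
    master_seed = 77L))
}

# the reference world at full scale (acceptance criteria 5 and 6)
reference_cohort <- function() {
  cached_cohort("reference", synthetic_config())
}
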