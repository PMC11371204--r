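#' Configuration for the synthetic EHR generator
#'
#' Describes a synthetic hospital world: patients enter the data system at
#' staggered months, attend in some calendar months (encounter months), and
#' accumulate sparse high-dimensional categorical codes, correlated
#' clinical-journey chains, numeric vitals with missingness, and demographic
#' attributes. A rare endpoint is driven by a per-month logistic hazard that
#' is log-odds additive in planted risk/protective factors, so ground-truth
#' hazards (and hence Bayes-optimal discrimination) are computable.
#'
#' The defaults are the package's reference world: 5,000 patients over 48
#' months, five planted risk factors with odds multipliers 4-8 at 20% carrier
#' prevalence and early onsets, two complete protective factors sized above
#' the minimum-N retention boundary, 2,000 heavy-tailed null codes, and a
#' baseline hazard calibrated so patient-level endpoint incidence is ~3%
#' (~2.4% among analytic patients, matching the incidence band the retention
#' criteria are designed around).
#'
#' @param n_patients number of patients.
#' @param n_months length of the data-system horizon in calendar months.
#' @param encounter_rate per-patient-month probability of at least one
#'   hospital encounter while the patient is active in the system.
#' @param entry_window integer range of calendar months over which patients
#'   first appear (uniform).
#' @param target_incidence patient-level endpoint incidence the baseline
#'   hazard is calibrated to when `baseline_hazard` is `NULL`.
#' @param baseline_hazard per-month endpoint probability for a reference
#'   patient carrying no planted factors; `NULL` means "calibrate".
#' @param planted_factors `data.frame` with columns `code`, `category`,
#'   `prevalence`, `multiplier` (per-month hazard odds multiplier; > 1 risk,
#'   < 1 protective), `onset_mode` (`"entry"` or `"acquired"`).
#' @param n_null_codes number of null (hazard-irrelevant) codes.
#' @param null_code_categories named numeric vector of category proportions
#'   for null codes.
#' @param null_prevalence_log10 log10 range of the heavy-tailed per-code
#'   emission weights (many rare codes, few common ones).
#' @param codes_per_encounter_month Poisson mean of null codes emitted per
#'   encounter month.
#' @param journey_chains list of chain templates, each a list with `codes`,
#'   `categories`, `prevalence`, `lag_mean` (Poisson month lag between
#'   consecutive chain elements).
#' @param numeric_specs `data.frame` with `name`, `mean`, `sd`,
#'   `measure_prob` (probability a measurement is taken in an encounter
#'   month).
#' @param demographics list of categorical attribute specs
#'   (`levels`, `probs`, `missing`, `change_prob`).
#' @param onset_window for `"acquired"` factors, the onset month is uniform
#'   over `[entry, min(entry + onset_window, n_months)]` (risk conditions
#'   tend to surface early in a patient's record).
#' @param reemission_prob probability a carried factor code is re-entered in
#'   an encounter month after its first emission (EHR codes recur).
#' @param death_prob probability a patient dies during the horizon
#'   (endpoint-free deaths exercise the death policy).
#' @param endpoint_code ICD-like code emitted on the endpoint month.
#' @param age_range age in years at entry (uniform).
#' @param origin calendar date whose month is month index 1.
#' @param master_seed integer master seed; every patient draws from a
#'   deterministic substream derived from it, so growing `n_patients` does
#'   not reshuffle existing patients' structure.
#' @return an object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_patients = 5000L,
                             n_months = 48L,
                             encounter_rate = 0.25,
                             entry_window = c(1L, 18L),
                             target_incidence = 0.03,
                             baseline_hazard = NULL,
                             planted_factors = default_planted_factors(),
                             n_null_codes = 2000L,
                             null_code_categories = c(diagnosis = 0.50, procedure = 0.25,
                                                      medication = 0.10, lab = 0.10,
                                                      chief_complaint = 0.05),
                             null_prevalence_log10 = c(-3.5, -1.3),
                             codes_per_encounter_month = 8,
                             journey_chains = default_journey_chains(),
                             numeric_specs = default_numeric_specs(),
                             demographics = default_demographic_specs(),
                             onset_window = 6L,
                             reemission_prob = 0.3,
                             death_prob = 0.005,
                             endpoint_code = "I63",
                             age_range = c(18, 85),
                             origin = as.Date("2015-04-01"),
                             master_seed = 20150401L) {
  stopifnot(n_patients >= 1, n_months >= 2,
            encounter_rate > 0, encounter_rate <= 1,
            is.null(baseline_hazard) || (baseline_hazard > 0 && baseline_hazard < 1),
            target_incidence > 0, target_incidence < 1,
            all(planted_factors$multiplier > 0),
            all(planted_factors$prevalence >= 0 & planted_factors$prevalence <= 1),
            all(planted_factors$onset_mode %in% c("entry", "acquired")),
            entry_window[1] >= 1, entry_window[2] <= n_months)
  cfg <- list(n_patients = as.integer(n_patients), n_months = as.integer(n_months),
              encounter_rate = encounter_rate, entry_window = as.integer(entry_window),
              target_incidence = target_incidence, baseline_hazard = baseline_hazard,
              planted_factors = as.data.table(planted_factors),
              n_null_codes = as.integer(n_null_codes),
              null_code_categories = null_code_categories,
              null_prevalence_log10 = null_prevalence_log10,
              codes_per_encounter_month = codes_per_encounter_month,
              journey_chains = journey_chains,
              numeric_specs = as.data.table(numeric_specs),
              demographics = demographics,
              onset_window = as.integer(onset_window),
              reemission_prob = reemission_prob, death_prob = death_prob,
              endpoint_code = endpoint_code, age_range = age_range,
              origin = origin, master_seed = as.integer(master_seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @export
default_planted_factors <- function() {
  data.frame(
    code       = c("RISK_DX_A", "RISK_DX_B", "RISK_DX_C", "RISK_MED_A", "RISK_LAB_A",
                   "PROT_MED_A", "PROT_DX_A"),
    category   = c("diagnosis", "diagnosis", "diagnosis", "medication", "lab",
                   "medication", "diagnosis"),
    prevalence = c(0.20, 0.20, 0.20, 0.20, 0.20, 0.08, 0.06),
    multiplier = c(4, 6, 8, 5, 7, 0.001, 0.001),
    onset_mode = c("acquired", "acquired", "acquired", "acquired", "acquired",
                   "entry", "entry"),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_config
#' @export
default_journey_chains <- function() {
  list(
    list(codes = c("LAB_PANEL_A", "DX_CHAIN_A", "MED_CHAIN_A"),
         categories = c("lab", "diagnosis", "medication"),
         prevalence = 0.10, lag_mean = 1),
    list(codes = c("LAB_PANEL_B", "DX_CHAIN_B", "PROC_CHAIN_B"),
         categories = c("lab", "diagnosis", "procedure"),
         prevalence = 0.08, lag_mean = 2)
  )
}

#' @rdname synthetic_config
#' @export
default_numeric_specs <- function() {
  data.frame(name = c("BMI", "SBP", "DBP"),
             mean = c(27.5, 125, 78),
             sd = c(5.2, 15, 10),
             measure_prob = c(0.5, 0.6, 0.6),
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_config
#' @export
default_demographic_specs <- function() {
  list(
    sex = list(levels = c("female", "male"), probs = c(0.5, 0.5),
               missing = 0, change_prob = 0),
    smoking = list(levels = c("current", "past", "never"), probs = c(0.2, 0.25, 0.55),
                   missing = 0.15, change_prob = 0.1)
  )
}

#' Per-month endpoint hazard under the planted-factor model
#'
#' The hazard is log-odds additive: a patient-month's endpoint probability is
#' `plogis(qlogis(baseline) + sum(log(multipliers)))` over the factors the
#' patient actively carries that month. Multipliers > 1 are risk factors,
#' < 1 protective.
#'
#' @param baseline reference per-month endpoint probability.
#' @param multipliers numeric vector of active odds multipliers (possibly
#'   empty).
#' @return a probability.
#' @export
#' @examples
#' monthly_hazard(0.002, 8)   # ~0.0158
#' monthly_hazard(0.002)      # baseline itself
monthly_hazard <- function(baseline, multipliers = numeric(0)) {
  stopifnot(baseline > 0, baseline < 1, all(multipliers > 0))
  plogis(qlogis(baseline) + sum(log(multipliers)))
}

# Phase A: per-patient structural draws from hierarchical substreams.
# Draw order within a stream is fixed; growing n_patients only appends
# streams, it never reshuffles existing patients.
synth_structure <- function(cfg) {
  n <- cfg$n_patients
  pf <- cfg$planted_factors
  nfac <- nrow(pf)
  chains <- cfg$journey_chains
  dem <- cfg$demographics

  entry <- integer(n); age <- numeric(n); death <- rep(NA_integer_, n)
  carry <- matrix(FALSE, n, nfac); onset <- matrix(NA_integer_, n, nfac)
  chain_carry <- matrix(FALSE, n, length(chains))
  chain_months <- vector("list", n)
  dem_vals <- vector("list", n)

  for (i in seq_len(n)) {
    withr::with_seed(derive_seed(cfg$master_seed, i), {
      entry[i] <- sample(cfg$entry_window[1]:cfg$entry_window[2], 1L)
      age[i] <- runif(1, cfg$age_range[1], cfg$age_range[2])
      if (runif(1) < cfg$death_prob)
        death[i] <- sample(entry[i]:cfg$n_months, 1L)
      for (k in seq_len(nfac)) {
        carry[i, k] <- runif(1) < pf$prevalence[k]
        onset[i, k] <- if (pf$onset_mode[k] == "entry") entry[i]
                       else sample(entry[i]:min(entry[i] + cfg$onset_window,
                                                cfg$n_months), 1L)
      }
      cm <- list()
      for (j in seq_along(chains)) {
        ch <- chains[[j]]
        chain_carry[i, j] <- runif(1) < ch$prevalence
        start <- sample(entry[i]:cfg$n_months, 1L)
        lags <- rpois(length(ch$codes) - 1L, ch$lag_mean)
        cm[[j]] <- start + c(0L, cumsum(lags))
      }
      chain_months[[i]] <- cm
      dv <- list()
      for (a in names(dem)) {
        sp <- dem[[a]]
        miss <- runif(1) < sp$missing
        v1 <- sample(sp$levels, 1L, prob = sp$probs)
        chg <- if ((sp$change_prob %||% 0) > 0 && runif(1) < sp$change_prob) {
          list(month = sample(entry[i]:cfg$n_months, 1L),
               value = sample(sp$levels, 1L, prob = sp$probs))
        } else NULL
        dv[[a]] <- list(missing = miss, value = v1, change = chg)
      }
      dem_vals[[i]] <- dv
    })
  }
  list(entry = entry, age = age, death = death, carry = carry, onset = onset,
       chain_carry = chain_carry, chain_months = chain_months, dem_vals = dem_vals)
}

# hazard matrix (patients x months) given structure and a baseline hazard
synth_hazard_matrix <- function(cfg, str, h0) {
  n <- cfg$n_patients; M <- cfg$n_months
  pf <- cfg$planted_factors
  eta <- matrix(qlogis(h0), n, M)
  monthgrid <- matrix(seq_len(M), n, M, byrow = TRUE)
  for (k in seq_len(nrow(pf))) {
    act <- str$carry[, k] & (monthgrid >= str$onset[, k])
    eta <- eta + act * log(pf$multiplier[k])
  }
  H <- plogis(eta)
  # at risk only from entry to death-1 (or horizon)
  atrisk <- monthgrid >= str$entry &
    (is.na(str$death) | monthgrid < str$death)
  H * atrisk
}

synth_expected_incidence <- function(cfg, str, h0) {
  H <- synth_hazard_matrix(cfg, str, h0)
  mean(1 - exp(rowSums(log1p(-H))))
}

#' Generate a synthetic event-level EHR cohort with ground truth
#'
#' Produces the exact event/demographics table schema the time-series module
#' consumes, plus a ground-truth object (per-patient factor carriage,
#' endpoint and death months, and the full per-patient-month hazard matrix)
#' so downstream signal recovery is measurable. When
#' `cfg$baseline_hazard` is `NULL` the baseline is calibrated by root-finding
#' so the expected patient-level incidence matches `cfg$target_incidence`
#' given the realized carriage structure.
#'
#' Output is byte-identical for identical configurations: all randomness is
#' drawn from per-patient substreams derived from `cfg$master_seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_cohort` with elements `events`
#'   (`patient_id`, `category`, `code`, `event_date`, `numeric_value`),
#'   `demographics` (`patient_id`, `attribute`, `value`, `effective_date`),
#'   `truth` (patients table, carriage table, hazard matrix, baseline), and
#'   `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_patients; M <- cfg$n_months
  pf <- cfg$planted_factors
  str <- synth_structure(cfg)

  h0 <- cfg$baseline_hazard
  if (is.null(h0)) {
    h0 <- uniroot(function(h) synth_expected_incidence(cfg, str, h) - cfg$target_incidence,
                  interval = c(1e-7, 0.05), tol = 1e-10)$root
  }
  exp_inc <- synth_expected_incidence(cfg, str, h0)
  if (exp_inc < 1e-6 || exp_inc > 1 - 1e-6)
    warning("configuration implies degenerate patient-level incidence (",
            signif(exp_inc, 3), ")")
  H <- synth_hazard_matrix(cfg, str, h0)

  # null-code catalog: heavy-tailed emission weights, fixed given the catalog
  # stream (independent of n_patients)
  catprop <- cfg$null_code_categories
  ncat <- pmax(0L, round_half_up(catprop * cfg$n_null_codes))
  null_cat <- rep(names(catprop), ncat)[seq_len(cfg$n_null_codes)]
  null_cat[is.na(null_cat)] <- names(catprop)[1]
  null_codes <- sprintf("NULL_%s_%04d", toupper(substr(null_cat, 1, 3)), seq_len(cfg$n_null_codes))
  w <- withr::with_seed(derive_seed(cfg$master_seed, 999983L),
                        10 ^ runif(cfg$n_null_codes, cfg$null_prevalence_log10[1],
                                   cfg$null_prevalence_log10[2]))
  wnorm <- w / sum(w)

  pid <- sprintf("P%06d", seq_len(n))
  ev_list <- vector("list", n)
  demo_list <- vector("list", n)
  endpoint_month <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    withr::with_seed(derive_seed(cfg$master_seed, 1000000L + i), {
      horizon <- if (is.na(str$death[i])) M else str$death[i] - 1L
      active <- seq_len(M) >= str$entry[i] & seq_len(M) <= horizon
      # endpoint: sequential Bernoulli over active months
      u <- runif(M)
      hit <- which(active & u < H[i, ])
      ep <- if (length(hit)) hit[1] else NA_integer_
      endpoint_month[i] <- ep

      enc <- active & (runif(M) < cfg$encounter_rate)
      # forced encounters: endpoint month, chain element months
      if (!is.na(ep)) enc[ep] <- TRUE
      chain_ev <- list()
      for (j in seq_along(cfg$journey_chains)) {
        if (!str$chain_carry[i, j]) next
        ch <- cfg$journey_chains[[j]]
        cm <- str$chain_months[[i]][[j]]
        keep <- cm >= str$entry[i] & cm <= horizon
        if (any(keep)) {
          enc[cm[keep]] <- TRUE
          chain_ev[[j]] <- data.table(month = cm[keep],
                                      category = ch$categories[keep],
                                      code = ch$codes[keep])
        }
      }
      encm <- which(enc)
      if (length(encm) == 0L) {
        ev_list[[i]] <- NULL
      } else {
        parts <- list()
        # encounters (1-3 per encounter month)
        cnt <- 1L + rpois(length(encm), 0.5)
        parts$enc <- data.table(month = rep(encm, cnt), category = "encounter",
                                code = "ENC", numeric_value = NA_real_)
        # planted factor emissions: first encounter month at/after onset always
        # emits; later encounter months re-emit with reemission_prob
        for (k in seq_len(nrow(pf))) {
          if (!str$carry[i, k]) next
          el <- encm[encm >= str$onset[i, k]]
          if (!length(el)) next
          emit <- c(TRUE, runif(length(el) - 1L) < cfg$reemission_prob)
          parts[[paste0("f", k)]] <- data.table(month = el[emit],
                                                category = pf$category[k],
                                                code = pf$code[k],
                                                numeric_value = NA_real_)
        }
        # chain events
        if (length(chain_ev)) {
          cev <- rbindlist(chain_ev)
          cev[, numeric_value := NA_real_]
          parts$chain <- cev
        }
        # null codes: Poisson count per encounter month, heavy-tailed catalog
        kdraw <- rpois(length(encm), cfg$codes_per_encounter_month)
        tot <- sum(kdraw)
        if (tot > 0) {
          idx <- sample.int(cfg$n_null_codes, tot, replace = TRUE, prob = wnorm)
          parts$null <- data.table(month = rep(encm, kdraw),
                                   category = null_cat[idx],
                                   code = null_codes[idx],
                                   numeric_value = NA_real_)
        }
        # numeric measurements (vitals) in encounter months
        for (r in seq_len(nrow(cfg$numeric_specs))) {
          sp <- cfg$numeric_specs[r]
          meas <- encm[runif(length(encm)) < sp$measure_prob]
          if (!length(meas)) next
          # occasionally two measurements in a month (exercises last-value rule)
          dup <- runif(length(meas)) < 0.1
          mm <- c(meas, meas[dup])
          parts[[paste0("num", r)]] <- data.table(month = mm, category = "vital",
                                                  code = sp$name,
                                                  numeric_value = pmax(1, rnorm(length(mm), sp$mean, sp$sd)))
        }
        # endpoint diagnosis code on the endpoint month
        if (!is.na(ep)) {
          parts$ep <- data.table(month = ep, category = "diagnosis",
                                 code = cfg$endpoint_code, numeric_value = NA_real_)
        }
        ev <- rbindlist(parts, fill = TRUE)
        ev[, day := sample.int(28L, .N, replace = TRUE)]
        ev[, patient_id := pid[i]]
        ev_list[[i]] <- ev
      }

      # demographics
      dr <- list(data.table(attribute = "birth_date",
                            value = as.character(month_start(str$entry[i], cfg$origin) -
                                                   round(str$age[i] * 365.25)),
                            effective_month = NA_integer_))
      if (!is.na(str$death[i]))
        dr$death <- data.table(attribute = "death_date",
                               value = as.character(month_start(str$death[i], cfg$origin)),
                               effective_month = NA_integer_)
      for (a in names(cfg$demographics)) {
        dv <- str$dem_vals[[i]][[a]]
        if (dv$missing) next
        dr[[a]] <- data.table(attribute = a, value = dv$value,
                              effective_month = NA_integer_)
        if (!is.null(dv$change))
          dr[[paste0(a, "_chg")]] <- data.table(attribute = a, value = dv$change$value,
                                                effective_month = dv$change$month)
      }
      dd <- rbindlist(dr)
      dd[, patient_id := pid[i]]
      demo_list[[i]] <- dd
    })
  }

  events <- rbindlist(ev_list)
  events[, event_date := month_start(month, cfg$origin) + (day - 1L)]
  events <- events[, .(patient_id, category, code, event_date, numeric_value)]
  setorder(events, patient_id, event_date, category, code)

  demographics <- rbindlist(demo_list)
  demographics[, effective_date := fifelse(is.na(effective_month),
                                           as.Date(NA),
                                           month_start(effective_month, cfg$origin))]
  demographics <- demographics[, .(patient_id, attribute, value, effective_date)]
  setorder(demographics, patient_id, attribute, na.last = TRUE)

  patients <- data.table(patient_id = pid, entry_month = str$entry,
                         age_at_entry = str$age, death_month = str$death,
                         endpoint_month = endpoint_month)
  carr <- list()
  for (k in seq_len(nrow(pf))) {
    who <- which(str$carry[, k])
    if (length(who))
      carr[[k]] <- data.table(patient_id = pid[who], code = pf$code[k],
                              category = pf$category[k],
                              multiplier = pf$multiplier[k],
                              onset_month = str$onset[who, k])
  }
  truth <- list(patients = patients,
                carriage = rbindlist(carr),
                hazard = H,
                baseline_hazard = h0,
                expected_incidence = exp_inc,
                null_codes = null_codes,
                chain_codes = unlist(lapply(cfg$journey_chains, `[[`, "codes")))
  out <- list(events = events, demographics = demographics, truth = truth, config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$config$n_patients, "patients,",
      x$config$n_months, "months;", nrow(x$events), "events;",
      sum(!is.na(x$truth$patients$endpoint_month)), "endpoint patients",
      sprintf("(baseline hazard %.3g)\n", x$truth$baseline_hazard))
  invisible(x)
}

#' Ground-truth outcome probability for patient-month rows
#'
#' For a row at month `m` the true probability of the endpoint within the
#' next `L` months is `1 - prod(1 - h[m+1 .. m+L])` from the generator's
#' hazard matrix. Rows whose window extends past the simulated horizon get
#' `NA`. Used as the Bayes-optimal score in signal-recovery checks.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param rows a patient-month table with `patient_id` and `month_index`.
#' @param followup_months window length `L`.
#' @return numeric vector aligned with `rows`.
#' @export
true_row_probabilities <- function(truth, rows, followup_months = 12L) {
  H <- truth$hazard
  M <- ncol(H)
  idx <- match(rows$patient_id, truth$patients$patient_id)
  vapply(seq_len(nrow(rows)), function(r) {
    m <- rows$month_index[r]
    if (m + followup_months > M) return(NA_real_)
    1 - prod(1 - H[idx[r], (m + 1):(m + followup_months)])
  }, numeric(1))
}

#' Exact patient-level null 2x2 tables for type-I studies
#'
#' Draws the sampling distribution of binary-predictor-by-outcome contingency
#' tables under the null (carriage independent of outcome) without
#' materializing event data: the outcome count is Binomial(n, rate), each
#' code's carrier count is Binomial(n, prevalence) with heavy-tailed
#' prevalences, and the carrier-outcome overlap is hypergeometric. The
#' resulting tables are exactly those `select_predictors()` would compute on
#' an event-level null cohort of the same size.
#'
#' @param n_patients analytic patient count.
#' @param n_codes number of null codes.
#' @param rate patient-level outcome incidence.
#' @param prevalence_log10 log10 range of carrier prevalences.
#' @param seed integer seed.
#' @return `data.table` with `code`, `a`, `b`, `c`, `d`.
#' @export
simulate_null_tables <- function(n_patients, n_codes, rate,
                                 prevalence_log10 = c(-3.3, -1.3), seed = 1L) {
  stopifnot(rate > 0, rate < 1)
  withr::with_seed(as.integer(seed), {
    k_out <- rbinom(1L, n_patients, rate)
    prev <- 10 ^ runif(n_codes, prevalence_log10[1], prevalence_log10[2])
    n_c <- rbinom(n_codes, n_patients, prev)
    a <- vapply(n_c, function(nc) {
      if (nc == 0L) 0L else stats::rhyper(1L, k_out, n_patients - k_out, nc)
    }, integer(1))
  })
  data.table(code = sprintf("NULL_%05d", seq_len(n_codes)),
             a = a, b = n_c - a, c = k_out - a,
             d = n_patients - n_c - (k_out - a))
}

#' Join predictor-retention decisions to synthetic ground truth
#'
#' Measures how well automated retention recovered the generator's planted
#' structure: sensitivity on planted factors, the false-retention rate on
#' null codes, and sign agreement between the classified direction and the
#' planted multiplier.
#'
#' @param decisions the decision table from [select_predictors()].
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return list with `planted` (per-factor detail), `planted_sensitivity`,
#'   `null_false_retention`, `direction_agreement`.
#' @export
recovery_report <- function(decisions, truth) {
  dec <- as.data.table(decisions)
  pf <- unique(truth$carriage[, .(code, multiplier)])
  planted <- merge(pf, dec, by = "code", all.x = TRUE)
  planted[, truth_direction := fifelse(multiplier > 1, "risk", "protective")]
  planted[is.na(retained), retained := FALSE]
  nulls <- dec[code %in% truth$null_codes]
  list(planted = planted[],
       planted_sensitivity = mean(planted$retained),
       null_false_retention = if (nrow(nulls)) mean(nulls$retained) else NA_real_,
       direction_agreement = mean(planted$direction == planted$truth_direction,
                                  na.rm = TRUE))
}
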