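#' Encoding configuration
#'
#' Names the always-retained numeric measurements and demographic attributes
#' and the trimming percentiles. Retained binary predictors come from the
#' selection step; diagnoses use the past-and-present schema (one column),
#' every other binary uses the historical + contemporaneous pair, numeric
#' measurements use a presence/value pair under both schemas, age a single
#' standardized contemporaneous column, and the longitudinal descriptors
#' (`gap_months`, `encounter_count`) standardized value columns without a
#' presence pair (they are always defined).
#'
#' @param numeric_measurements codes of numeric measurements always encoded
#'   (presence/value x now/historical).
#' @param demographic_attributes categorical attributes one-hot encoded with
#'   a missing indicator.
#' @param include_descriptors include `gap_months` / `encounter_count`
#'   columns.
#' @param include_age include the standardized age column (requires
#'   `birth_date` demographics).
#' @param trim_percentiles lower/upper trimming percentiles for numeric
#'   measurements (sample percentiles with linear interpolation).
#' @return object of class `encoding_config`.
#' @export
encoding_config <- function(numeric_measurements = c("BMI", "SBP", "DBP"),
                            demographic_attributes = c("sex", "smoking"),
                            include_descriptors = TRUE,
                            include_age = TRUE,
                            trim_percentiles = c(0.001, 0.999)) {
  stopifnot(length(trim_percentiles) == 2, trim_percentiles[1] < trim_percentiles[2])
  structure(list(numeric_measurements = numeric_measurements,
                 demographic_attributes = demographic_attributes,
                 include_descriptors = include_descriptors,
                 include_age = include_age,
                 trim_percentiles = trim_percentiles),
            class = "encoding_config")
}

# last-in-month numeric value per (patient, month) for one measurement code
monthly_numeric_values <- function(events, name, ids) {
  ev <- as.data.table(events)
  mv <- ev[patient_id %chin% ids & code == name & !is.na(numeric_value)]
  if (nrow(mv) == 0L)
    return(data.table(patient_id = character(), month_index = integer(),
                      value = numeric()))
  setorder(mv, patient_id, month_index, event_date)
  mv[, .(value = numeric_value[.N]), by = .(patient_id, month_index)]
}

numeric_fit <- function(values, trim) {
  lo <- unname(quantile(values, trim[1], type = 7, na.rm = TRUE))
  hi <- unname(quantile(values, trim[2], type = 7, na.rm = TRUE))
  cl <- pmin(pmax(values, lo), hi)
  list(lo = lo, hi = hi, mean = mean(cl), sd = sd(cl))
}

#' Fit the encoding plan on the analytic dataset
#'
#' Computes every constant needed to turn patient-month rows into the dense
#' design matrix: the retained code lists split by schema, trim bounds and
#' standardization constants for each numeric measurement and descriptor,
#' the analytic age mean/sd, and the observed level list per demographic
#' attribute. All constants depend only on the analytic rows passed in --
#' validation months are scored with these frozen values, which is the
#' package's leakage guard.
#'
#' @param analytic_rows labeled analytic patient-month rows (training +
#'   test).
#' @param events prepared event table restricted to the analytic window.
#' @param demographics long demographics table.
#' @param decisions retention decisions from [select_predictors()] (may be
#'   empty).
#' @param cfg an [encoding_config()].
#' @return object of class `encoding_plan`.
#' @export
fit_encoding_plan <- function(analytic_rows, events, demographics, decisions,
                              cfg = encoding_config()) {
  rows <- as.data.table(analytic_rows)
  ev <- as.data.table(events)
  demo <- as.data.table(demographics)
  origin <- attr(ev, "origin")
  if (is.null(origin)) stop("events must carry an 'origin' attribute; run prepare_events()")
  ids <- unique(rows$patient_id)

  dec <- as.data.table(decisions)
  if (nrow(dec) && all(c("code", "category", "retained") %in% names(dec))) {
    kept <- dec[retained == TRUE]
    diag_codes <- sort(kept[category %in% "diagnosis", code])
    other_codes <- sort(setdiff(kept$code, diag_codes))
  } else {
    diag_codes <- character(0)
    other_codes <- character(0)
  }

  num_specs <- list()
  for (nm in cfg$numeric_measurements) {
    mv <- monthly_numeric_values(ev, nm, ids)
    mv <- mv[rows, on = .(patient_id, month_index), nomatch = NULL]
    if (nrow(mv) == 0L) {
      warning("numeric measurement '", nm, "' absent from the analytic dataset; dropped")
      next
    }
    f <- numeric_fit(mv$value, cfg$trim_percentiles)
    if (!is.finite(f$sd) || f$sd <= 0) {
      warning("numeric measurement '", nm, "' has zero analytic variance; dropped")
      next
    }
    num_specs[[nm]] <- c(f, list(name = nm))
  }

  desc_specs <- list()
  if (cfg$include_descriptors) {
    for (nm in c("gap_months", "encounter_count")) {
      f <- numeric_fit(as.numeric(rows[[nm]]), cfg$trim_percentiles)
      if (!is.finite(f$sd) || f$sd <= 0) {
        warning("descriptor '", nm, "' has zero analytic variance; dropped")
        next
      }
      desc_specs[[nm]] <- c(f, list(name = nm))
    }
  }

  age_spec <- NULL
  if (cfg$include_age) {
    birth <- demo[attribute == "birth_date", .(birth_date = as.Date(value[1])),
                  by = patient_id]
    br <- birth[rows, on = "patient_id", x.birth_date]
    if (anyNA(br)) stop("birth_date missing for some analytic patients")
    agev <- as.numeric(month_start(rows$month_index, origin) - br) / 365.25
    age_spec <- list(mean = mean(agev), sd = sd(agev))
    if (!is.finite(age_spec$sd) || age_spec$sd <= 0)
      stop("age has zero analytic variance")
  }

  demo_specs <- list()
  analytic_end <- max(rows$month_index)
  for (at in cfg$demographic_attributes) {
    # only values already effective inside the analytic window may define the
    # level list (a later-dated change must not leak into the plan)
    dv <- demo[attribute == at & patient_id %chin% ids]
    dv <- dv[is.na(effective_date) |
               month_index(as.Date(effective_date), origin) <= analytic_end]
    demo_specs[[at]] <- list(attribute = at, levels = sort(unique(dv$value)))
  }

  structure(list(diagnosis_codes = diag_codes, other_codes = other_codes,
                 numeric_specs = num_specs, descriptor_specs = desc_specs,
                 age_spec = age_spec, demographic_specs = demo_specs,
                 trim_percentiles = cfg$trim_percentiles, origin = origin),
            class = "encoding_plan")
}

#' @export
print.encoding_plan <- function(x, ...) {
  cat("<encoding_plan>", length(x$diagnosis_codes), "diagnoses (past-and-present),",
      length(x$other_codes), "other binaries (hist+now),",
      length(x$numeric_specs), "numeric pairs,",
      length(x$demographic_specs), "demographic attributes\n")
  invisible(x)
}

#' Serialize / restore an encoding plan
#'
#' The plan is persisted alongside the trained model so later validation
#' months are scored with frozen analytic constants.
#'
#' @param plan an `encoding_plan`.
#' @param path JSON file path.
#' @export
write_encoding_plan <- function(plan, path) {
  p <- unclass(plan)
  p$origin <- as.character(p$origin)
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_encoding_plan
#' @export
read_encoding_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$origin <- as.Date(p$origin)
  p$diagnosis_codes <- as.character(p$diagnosis_codes)
  p$other_codes <- as.character(p$other_codes)
  structure(p, class = "encoding_plan")
}

# standalone schema encoders for a single patient series ---------------------

#' Single-code indicator encodings for one patient series
#'
#' `encode_past_present()` marks a code as present from its first occurrence
#' month onward (the diagnosis schema); `encode_historical()` marks months
#' strictly after an occurrence; `encode_contemporaneous()` marks only
#' months with an occurrence. For every month, past-and-present equals
#' historical OR contemporaneous.
#'
#' @param row_months sorted month indices of the patient's rows.
#' @param event_months month indices at which the code occurs.
#' @return integer 0/1 vector aligned with `row_months`.
#' @export
encode_past_present <- function(row_months, event_months) {
  if (!length(event_months)) return(integer(length(row_months)))
  as.integer(row_months >= min(event_months))
}

#' @rdname encode_past_present
#' @export
encode_historical <- function(row_months, event_months) {
  if (!length(event_months)) return(integer(length(row_months)))
  as.integer(row_months > min(event_months))
}

#' @rdname encode_past_present
#' @export
encode_contemporaneous <- function(row_months, event_months) {
  as.integer(row_months %in% event_months)
}

#' Assemble the dense month-level design matrix
#'
#' Applies the frozen [fit_encoding_plan()] constants to a set of
#' patient-month rows. Diagnoses contribute one past-and-present column
#' (`:pp`); other retained binaries a historical/contemporaneous pair
#' (`:hist`, `:now`); each numeric measurement four columns
#' (`:present`, `:value` contemporaneous and `:present_hist`,
#' `:value_hist`, the latter the running maximum of standardized values over
#' strictly earlier rows, 0 while never measured); descriptors a
#' standardized `:value`/`:value_hist` pair; age a single standardized
#' column; demographics one column per analytic level plus a missing
#' indicator. The matrix is dense with no missing cells.
#'
#' Historical encodings are computed over the patient's full row series, so
#' pass complete series and use `score_months` to subset the returned rows
#' (e.g. to a validation month).
#'
#' @param rows patient-month rows (full series for each patient involved).
#' @param events prepared event table covering those patients' history.
#' @param demographics long demographics table.
#' @param plan an `encoding_plan`.
#' @param score_months optional month indices to keep in the output.
#' @return list of class `design_matrix` with `x` (numeric matrix with
#'   column names), `patient_id`, `month_index` and `outcome` (NA when rows
#'   are unlabeled).
#' @export
assemble_design_matrix <- function(rows, events, demographics, plan,
                                   score_months = NULL) {
  rows <- copy(as.data.table(rows))
  setorder(rows, patient_id, month_index)
  rows[, rid := .I]
  n <- nrow(rows)
  ev <- as.data.table(events)
  demo <- as.data.table(demographics)
  ids <- unique(rows$patient_id)

  all_codes <- c(plan$diagnosis_codes, plan$other_codes)
  cols <- list()

  if (length(all_codes)) {
    em <- unique(ev[patient_id %chin% ids & code %chin% all_codes,
                    .(patient_id, code, month_index)])
    fo <- if (nrow(em)) em[, .(first = min(month_index)), by = .(patient_id, code)]
          else data.table(patient_id = character(), code = character(),
                          first = integer())
    # contemporaneous hits: exact (patient, month) matches
    hits_now <- rows[em, on = .(patient_id, month_index), nomatch = NULL,
                     .(rid = x.rid, code = i.code)]
    # any occurrence strictly before the row month
    hits_hist <- fo[rows, on = .(patient_id, first < month_index), nomatch = NULL,
                    allow.cartesian = TRUE, .(rid = i.rid, code = x.code)]
    # any occurrence at or before the row month
    hits_pp <- fo[rows, on = .(patient_id, first <= month_index), nomatch = NULL,
                  allow.cartesian = TRUE, .(rid = i.rid, code = x.code)]
    fill <- function(hits, codes, suffix) {
      m <- matrix(0, n, length(codes), dimnames = list(NULL, paste0(codes, suffix)))
      h <- hits[code %chin% codes]
      if (nrow(h)) m[cbind(h$rid, match(h$code, codes))] <- 1
      m
    }
    if (length(plan$diagnosis_codes))
      cols$pp <- fill(hits_pp, plan$diagnosis_codes, ":pp")
    if (length(plan$other_codes)) {
      cols$hist <- fill(hits_hist, plan$other_codes, ":hist")
      cols$now <- fill(hits_now, plan$other_codes, ":now")
      # interleave hist/now per code for readability
      ord <- as.vector(rbind(seq_along(plan$other_codes),
                             seq_along(plan$other_codes) + length(plan$other_codes)))
      hn <- cbind(cols$hist, cols$now)[, ord, drop = FALSE]
      cols$hist <- NULL; cols$now <- NULL
      cols$hn <- hn
    }
  }

  running_pair <- function(present, val) {
    # historical presence = OR over strictly earlier rows; historical value =
    # running max of standardized values over strictly earlier rows (0 if none)
    dt <- data.table(pid = rows$patient_id, present = present, val = val)
    dt[, `:=`(ph = shift(cummax(present), fill = 0),
              vh = shift(cummax(fifelse(present == 1, val, -Inf)), fill = -Inf)),
       by = pid]
    dt[, vh := fifelse(ph == 1, vh, 0)]
    list(ph = dt$ph, vh = dt$vh)
  }

  for (nm in names(plan$numeric_specs)) {
    sp <- plan$numeric_specs[[nm]]
    mv <- monthly_numeric_values(ev, nm, ids)
    mrg <- mv[rows, on = .(patient_id, month_index)]
    present <- as.integer(!is.na(mrg$value))
    val <- ifelse(present == 1L,
                  (pmin(pmax(mrg$value, sp$lo), sp$hi) - sp$mean) / sp$sd, 0)
    rp <- running_pair(present, val)
    m <- cbind(present, val, rp$ph, rp$vh)
    colnames(m) <- paste0(nm, c(":present", ":value", ":present_hist", ":value_hist"))
    cols[[paste0("num_", nm)]] <- m
  }

  for (nm in names(plan$descriptor_specs)) {
    sp <- plan$descriptor_specs[[nm]]
    raw <- as.numeric(rows[[nm]])
    val <- (pmin(pmax(raw, sp$lo), sp$hi) - sp$mean) / sp$sd
    rp <- running_pair(rep(1L, n), val)
    m <- cbind(val, rp$vh)
    colnames(m) <- paste0(nm, c(":value", ":value_hist"))
    cols[[paste0("desc_", nm)]] <- m
  }

  if (!is.null(plan$age_spec)) {
    birth <- demo[attribute == "birth_date", .(birth_date = as.Date(value[1])),
                  by = patient_id]
    br <- birth[rows, on = "patient_id", x.birth_date]
    if (anyNA(br)) stop("birth_date missing for some patients being encoded")
    agev <- as.numeric(month_start(rows$month_index, plan$origin) - br) / 365.25
    m <- matrix((agev - plan$age_spec$mean) / plan$age_spec$sd, ncol = 1,
                dimnames = list(NULL, "age"))
    cols$age <- m
  }

  for (at in names(plan$demographic_specs)) {
    sp <- plan$demographic_specs[[at]]
    vals <- demo[attribute == at & patient_id %chin% ids,
                 .(patient_id, value,
                   em = fifelse(is.na(effective_date), -1L,
                                month_index(effective_date, plan$origin)))]
    lvl <- rep(NA_character_, n)
    if (nrow(vals)) {
      setkey(vals, patient_id, em)
      vals <- unique(vals, by = c("patient_id", "em"), fromLast = TRUE)
      q <- rows[, .(patient_id, em = month_index, rid)]
      res <- vals[q, on = .(patient_id, em), roll = Inf]
      lvl[res$rid] <- res$value
    }
    unseen <- !is.na(lvl) & !lvl %in% sp$levels
    if (any(unseen)) {
      warning("attribute '", at, "': level(s) ",
              paste(unique(lvl[unseen]), collapse = ", "),
              " unseen in the analytic dataset; mapped to missing")
      lvl[unseen] <- NA_character_
    }
    m <- matrix(0, n, length(sp$levels) + 1L,
                dimnames = list(NULL, c(paste0(at, "=", sp$levels),
                                        paste0(at, "=missing"))))
    hit <- match(lvl, sp$levels)
    ok <- !is.na(hit)
    if (any(ok)) m[cbind(which(ok), hit[ok])] <- 1
    m[!ok, length(sp$levels) + 1L] <- 1
    cols[[paste0("demo_", at)]] <- m
  }

  x <- do.call(cbind, unname(cols))
  if (is.null(x)) x <- matrix(numeric(0), n, 0)
  if (anyDuplicated(colnames(x)))
    stop("duplicate design-matrix column names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("internal error: missing cells in the design matrix")

  keep <- if (is.null(score_months)) rep(TRUE, n) else rows$month_index %in% score_months
  out <- list(x = x[keep, , drop = FALSE],
              patient_id = rows$patient_id[keep],
              month_index = rows$month_index[keep],
              outcome = if ("outcome" %in% names(rows)) rows$outcome[keep]
                        else rep(NA_integer_, sum(keep)))
  rows[, rid := NULL]
  class(out) <- "design_matrix"
  out
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$x), "patient-month rows x", ncol(x$x),
      "predictor encodings\n")
  invisible(x)
}
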