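#' Hyper-parameters of the automated predictor retention criteria
#'
#' PRC-1 is an exact Fisher screen on the patient-level binary-predictor by
#' outcome 2x2 table: a predictor passes when the two-tailed p-value is at
#' most `alpha`, with one tail corresponding to protective factors and the
#' other to risk factors. PRC-2 applies only to risk factors and asks that a
#' random test split of `test_fraction` of the carriers would contain at
#' least one outcome-bearing carrier with probability at least
#' `prc2_threshold` (cumulative binomial).
#'
#' @param alpha two-tailed PRC-1 significance level.
#' @param test_fraction share of carriers expected in the test split
#'   (PRC-2's binomial sample size is `max(1, round-half-up(test_fraction *
#'   carriers))`).
#' @param prc2_threshold minimum probability of at least one outcome-bearing
#'   carrier in the test split.
#' @param asymmetric_alpha optional numeric pair `c(risk_tail,
#'   protective_tail)`; when given, PRC-1 compares each direction's one-tailed
#'   p-value against its own tail budget instead of the symmetric two-tailed
#'   rule.
#' @param convention two-sided Fisher convention used for PRC-1; see
#'   [fisher_two_tailed_p()].
#' @return object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, test_fraction = 0.10,
                             prc2_threshold = 0.95, asymmetric_alpha = NULL,
                             convention = c("central", "minlike")) {
  stopifnot(alpha > 0, alpha < 1, test_fraction > 0, test_fraction < 1,
            prc2_threshold > 0, prc2_threshold < 1,
            is.null(asymmetric_alpha) ||
              (length(asymmetric_alpha) == 2 && all(asymmetric_alpha > 0)))
  structure(list(alpha = alpha, test_fraction = test_fraction,
                 prc2_threshold = prc2_threshold,
                 asymmetric_alpha = asymmetric_alpha,
                 convention = match.arg(convention)),
            class = "selection_config")
}

#' Patient-level 2x2 contingency table for a binary predictor
#'
#' `a` counts patients carrying the predictor with the outcome, `b` carriers
#' without it, `c` non-carriers with the outcome, `d` the remainder; the four
#' cells partition the analytic patient set.
#'
#' @param carrier_ids patient ids carrying the predictor.
#' @param outcome_ids patient ids with the outcome.
#' @param all_ids the full analytic patient set.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
patient_level_contingency <- function(carrier_ids, outcome_ids, all_ids) {
  carrier_ids <- intersect(carrier_ids, all_ids)
  outcome_ids <- intersect(outcome_ids, all_ids)
  a <- length(intersect(carrier_ids, outcome_ids))
  b <- length(carrier_ids) - a
  cc <- length(outcome_ids) - a
  d <- length(all_ids) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Exact two-tailed Fisher p-value for 2x2 tables
#'
#' Vectorized over the four cell counts. Two conventions are offered for the
#' two-sided p-value under the hypergeometric null with fixed margins:
#'
#' * `"central"` (default): twice the smaller tail probability, capped at 1.
#'   This is the convention under which exactly `alpha/2` of the sampling
#'   distribution in each tail is significant, and under which the
#'   closed-form minimum carrier count for complete protective factors
#'   ([min_complete_protective_n()]) is exact.
#' * `"minlike"`: the sum of probabilities of all tables (with the observed
#'   margins) whose point probability does not exceed that of the observed
#'   table -- the convention of `stats::fisher.test()`.
#'
#' Degenerate margins give p = 1.
#'
#' @param a,b,c,d cell counts (vectors recycled to a common length).
#' @param convention `"central"` or `"minlike"`.
#' @return numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisher_two_tailed_p(1, 1, 1, 1)                      # 1
#' fisher_two_tailed_p(10, 0, 0, 10, "minlike")         # 2 / choose(20, 10)
fisher_two_tailed_p <- function(a, b, c, d, convention = c("central", "minlike")) {
  convention <- match.arg(convention)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  m <- a + b          # carriers
  nn <- c + d         # non-carriers
  k <- a + c          # outcome margin
  if (convention == "central") {
    lo <- phyper(a, m, nn, k)
    up <- phyper(a - 1, m, nn, k, lower.tail = FALSE)
    p <- pmin(1, 2 * pmin(lo, up))
  } else {
    p <- vapply(seq_len(n), function(i) {
      supp <- max(0, k[i] - nn[i]):min(k[i], m[i])
      pr <- dhyper(supp, m[i], nn[i], k[i])
      p0 <- dhyper(a[i], m[i], nn[i], k[i])
      sum(pr[pr <= p0 * (1 + 1e-7)])
    }, numeric(1))
  }
  pmin(p, 1)
}

# one-tailed p-values per direction (used for asymmetric alpha budgets)
fisher_tail_p <- function(a, b, c, d, direction) {
  m <- a + b; nn <- c + d; k <- a + c
  ifelse(direction == "risk",
         phyper(a - 1, m, nn, k, lower.tail = FALSE),  # P(A >= a)
         phyper(a, m, nn, k))                          # P(A <= a)
}

#' Classify a predictor's direction of association
#'
#' Risk when the carrier outcome rate exceeds the non-carrier rate,
#' protective when it is lower, and null on exact ties or an empty carrier
#' group.
#'
#' @inheritParams fisher_two_tailed_p
#' @return character vector in `c("risk", "protective", "null")`.
#' @export
classify_direction <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  rate1 <- ifelse(a + b > 0, a / (a + b), NA_real_)
  rate0 <- ifelse(c + d > 0, c / (c + d), NA_real_)
  out <- rep("null", n)
  out[!is.na(rate1) & !is.na(rate0) & rate1 > rate0] <- "risk"
  out[!is.na(rate1) & !is.na(rate0) & rate1 < rate0] <- "protective"
  out
}

#' Minimum carrier count for a complete protective factor
#'
#' A complete protective factor (no carrier experiences the outcome) can only
#' reach two-tailed significance once enough carriers have been observed:
#' `ceiling(log(alpha/2) / log(1 - rate))`, where `rate` is the patient-level
#' outcome incidence in the analytic dataset. Below this count even total
#' protection is indistinguishable from sampling error.
#'
#' @param rate patient-level outcome incidence, in (0, 1).
#' @param alpha two-tailed significance level.
#' @return integer minimum carrier count.
#' @export
#' @examples
#' min_complete_protective_n(0.0228)  # 160
#' min_complete_protective_n(0.0278)  # 131
min_complete_protective_n <- function(rate, alpha = 0.05) {
  if (any(rate <= 0 | rate >= 1)) stop("rate must lie strictly in (0, 1)")
  stopifnot(alpha > 0, alpha < 1)
  as.integer(ceiling(log(alpha / 2) / log(1 - rate)))
}

#' PRC-2: expected generalizability of a risk factor to the test split
#'
#' With `o_carriers / n_carriers` taken as the carrier outcome rate, the
#' probability that a random test split holding `max(1,
#' round-half-up(test_fraction * n_carriers))` carriers contains at least one
#' outcome-bearing carrier is computed from the cumulative binomial
#' distribution; the factor passes when that probability reaches
#' `prc2_threshold`.
#'
#' @param n_carriers carriers of the risk factor in the analytic dataset
#'   (vectorized).
#' @param o_carriers carriers who also have the outcome (vectorized, must be
#'   positive: a factor with no outcome-bearing carriers is not a risk
#'   factor).
#' @param cfg a [selection_config()].
#' @return `data.table` with `n_test`, `prob`, `pass`.
#' @export
#' @examples
#' prc2(50, 25)  # n_test 5, prob 1 - 0.5^5 = 0.96875, pass
#' prc2(40, 20)  # n_test 4, prob 0.9375, fail
prc2 <- function(n_carriers, o_carriers, cfg = selection_config()) {
  n <- max(length(n_carriers), length(o_carriers))
  n_carriers <- rep_len(as.numeric(n_carriers), n)
  o_carriers <- rep_len(as.numeric(o_carriers), n)
  if (any(o_carriers <= 0)) stop("o_carriers must be positive for a risk factor")
  if (any(o_carriers > n_carriers)) stop("o_carriers cannot exceed n_carriers")
  n_test <- pmax(1, round_half_up(cfg$test_fraction * n_carriers))
  p_hit <- o_carriers / n_carriers
  prob <- pbinom(0, size = n_test, prob = p_hit, lower.tail = FALSE)
  data.table(n_test = as.integer(n_test), prob = prob,
             pass = prob >= cfg$prc2_threshold)
}

#' Apply both retention criteria to pre-computed 2x2 tables
#'
#' Table-level core of [select_predictors()], exposed so retention can be
#' studied directly on simulated contingency tables (e.g. the type-I
#' control study over [simulate_null_tables()] draws) without event data.
#'
#' @param tab `data.frame`/`data.table` with columns `a`, `b`, `c`, `d` (and
#'   optionally `code`/`category`, carried through).
#' @param cfg a [selection_config()].
#' @return the table with `direction`, `prc1_p`, `prc1_pass`, `prc2_prob`,
#'   `prc2_pass` and `retained` columns added.
#' @export
apply_retention_criteria <- function(tab, cfg = selection_config()) {
  tab <- copy(as.data.table(tab))
  tab[, direction := classify_direction(a, b, c, d)]
  tab[, prc1_p := fisher_two_tailed_p(a, b, c, d, cfg$convention)]
  if (is.null(cfg$asymmetric_alpha)) {
    tab[, prc1_pass := prc1_p <= cfg$alpha & direction != "null"]
  } else {
    tailp <- fisher_tail_p(tab$a, tab$b, tab$c, tab$d, tab$direction)
    budget <- ifelse(tab$direction == "risk", cfg$asymmetric_alpha[1],
                     cfg$asymmetric_alpha[2])
    tab[, prc1_pass := direction != "null" & tailp <= budget]
  }
  tab[, prc2_prob := NA_real_]
  tab[, prc2_pass := NA]
  risk <- which(tab$direction == "risk" & tab$a > 0)
  if (length(risk)) {
    r2 <- prc2(tab$a[risk] + tab$b[risk], tab$a[risk], cfg)
    tab[risk, `:=`(prc2_prob = r2$prob, prc2_pass = r2$pass)]
  }
  tab[, retained := prc1_pass &
        (direction == "protective" | (direction == "risk" & prc2_pass %in% TRUE))]
  tab[]
}

#' Apply both retention criteria to every candidate binary predictor
#'
#' Works at the patient level on the analytic dataset: a patient "has" a
#' predictor when its code occurs anywhere in their analytic-window events,
#' and "has the outcome" when any of their analytic rows is labeled 1.
#' Protective factors are retained when PRC-1 passes; risk factors need
#' PRC-1 and PRC-2; exact-tie (null-direction) predictors are never
#' retained. A decision row is emitted for every candidate, giving the full
#' PRC-1 x PRC-2 diagnostic plane.
#'
#' @param events prepared event table, already restricted to months up to
#'   the analytic cut-off (see `analytic_end`).
#' @param analytic_rows labeled analytic patient-month rows.
#' @param cfg a [selection_config()].
#' @param candidates candidate codes; default every non-encounter,
#'   non-endpoint code present in the analytic window.
#' @param analytic_end last analytic month; events after it are ignored.
#' @param endpoint_codes codes excluded from candidacy (they define the
#'   outcome).
#' @return `data.table` with `code`, `category`, `a`, `b`, `c`, `d`,
#'   `direction`, `prc1_p`, `prc2_prob`, `retained` (plus the intermediate
#'   pass flags).
#' @export
select_predictors <- function(events, analytic_rows, cfg = selection_config(),
                              candidates = NULL, analytic_end = NULL,
                              endpoint_codes = character(0)) {
  ev <- as.data.table(events)
  rows <- as.data.table(analytic_rows)
  if (is.null(analytic_end)) analytic_end <- max(rows$month_index)
  ids <- unique(rows$patient_id)
  out_ids <- unique(rows[outcome == 1L, patient_id])
  evw <- ev[patient_id %chin% ids & month_index <= analytic_end &
              category != "encounter"]
  if (length(endpoint_codes)) evw <- evw[!is_endpoint_code(code, endpoint_codes)]
  if (!is.null(candidates)) evw <- evw[code %chin% candidates]
  if (nrow(evw) == 0L)
    return(apply_retention_criteria(
      data.table(code = character(), category = character(),
                 a = integer(), b = integer(), c = integer(), d = integer()), cfg))
  carriers <- unique(evw[, .(patient_id, code, category)])
  carriers[, has_outcome := patient_id %chin% out_ids]
  tab <- carriers[, .(category = category[1], a = sum(has_outcome),
                      n_carriers = .N), by = code]
  n_total <- length(ids); n_out <- length(out_ids)
  tab[, `:=`(b = n_carriers - a, c = n_out - a, d = n_total - n_carriers - (n_out - a))]
  tab[, n_carriers := NULL]
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, tab$code)
    if (length(missing))
      tab <- rbind(tab, data.table(code = missing, category = NA_character_,
                                   a = 0L, b = 0L, c = n_out,
                                   d = n_total - n_out))
  }
  setorder(tab, code)
  apply_retention_criteria(tab, cfg)
}
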