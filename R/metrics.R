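#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random outcome-positive
#' score exceeds a random negative one, with ties counted one half.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes (0/1).
#' @return AUROC in `[0, 1]`; `NA` if either class is empty.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) average precision: scores are ranked
#' descending (ties kept in stable input order) and precision-at-k is
#' averaged over the positive positions.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; `NA` if there is no positive.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) == 0) return(NA_real_)
  o <- order(-scores)
  y <- labels[o]
  prec <- cumsum(y) / seq_along(y)
  mean(prec[y == 1])
}

#' Sensitivity and specificity at probability thresholds
#'
#' Classifies score `>= threshold` as high risk.
#'
#' @inheritParams auroc
#' @param thresholds numeric vector of classification thresholds.
#' @return `data.table` with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(scores, labels, thresholds = c(0.05, 0.025)) {
  stopifnot(length(scores) == length(labels))
  rbindlist(lapply(thresholds, function(th) {
    pos <- scores >= th
    data.table(threshold = th,
               sensitivity = if (any(labels == 1)) mean(pos[labels == 1]) else NA_real_,
               specificity = if (any(labels == 0)) mean(!pos[labels == 0]) else NA_real_)
  }))
}

#' Precision within a rank band of highest estimated risk
#'
#' Patients are ranked by descending score; ties at band boundaries are
#' broken by a seeded stable tiebreak so band membership is reproducible.
#' PPV is reported on the percent scale.
#'
#' @inheritParams auroc
#' @param band inclusive 1-based rank range, e.g. `c(1, 100)`.
#' @param tiebreak_seed seed of the tie-breaking draw.
#' @return list with `ppv` (percent), `band_positives`, `band_size`.
#' @export
ppv_at_band <- function(scores, labels, band = c(1L, 100L), tiebreak_seed = 1L) {
  stopifnot(length(scores) == length(labels), band[1] >= 1, band[1] <= band[2])
  if (length(scores) < band[2])
    stop("cohort of ", length(scores), " patients cannot fill rank band ",
         band[1], "-", band[2])
  tb <- withr::with_seed(as.integer(tiebreak_seed), runif(length(scores)))
  o <- order(-scores, tb)
  sel <- o[band[1]:band[2]]
  list(ppv = 100 * mean(labels[sel] == 1),
       band_positives = sum(labels[sel] == 1),
       band_size = length(sel))
}

#' Odds ratio standardizing a band PPV by cohort prevalence
#'
#' The outcome odds inside the rank band divided by the odds among cohort
#' patients outside the band (band excluded from the reference group).
#' Degenerate reference or band rates (0 or 1) make the ratio undefined and
#' return `NA` with an explanatory attribute.
#'
#' @param band_positives outcome patients inside the band.
#' @param band_size band width.
#' @param cohort_positives outcome patients in the whole cohort.
#' @param cohort_size cohort patient count.
#' @return odds ratio (numeric scalar, possibly `NA`).
#' @export
ppv_to_odds_ratio <- function(band_positives, band_size,
                              cohort_positives, cohort_size) {
  rest_pos <- cohort_positives - band_positives
  rest_n <- cohort_size - band_size
  p_band <- band_positives / band_size
  p_rest <- rest_pos / rest_n
  if (band_positives == 0) return(0)
  if (p_rest <= 0 || p_rest >= 1 || p_band >= 1) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate reference or band outcome rate"
    return(out)
  }
  (p_band / (1 - p_band)) / (p_rest / (1 - p_rest))
}

#' Risk-distribution descriptives by outcome group
#'
#' Min, quartiles, mean and max of percent-scale risk, split by outcome.
#'
#' @inheritParams auroc
#' @return `data.table` with one row per outcome group.
#' @export
risk_distribution_descriptives <- function(scores, labels) {
  dt <- data.table(risk = 100 * scores,
                   group = fifelse(labels == 1, "Yes", "No"))
  dt[, .(min = min(risk),
         q1 = unname(quantile(risk, 0.25, type = 7)),
         median = unname(quantile(risk, 0.5, type = 7)),
         mean = mean(risk),
         q3 = unname(quantile(risk, 0.75, type = 7)),
         max = max(risk)),
     keyby = group]
}
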