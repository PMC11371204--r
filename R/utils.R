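#' Calendar-month indexing
#'
#' Patient histories are kept on a month grid indexed from the data system's
#' inception: month 1 is the calendar month of `origin`, month 2 the next
#' calendar month, and so on. All window arithmetic (follow-up, analytic
#' cut-offs, censoring) is done on these integer indices.
#'
#' @param dates a `Date` vector.
#' @param origin a `Date`; its calendar month becomes index 1.
#' @return integer vector of month indices (may be non-positive for dates
#'   before `origin`).
#' @export
#' @examples
#' month_index(as.Date(c("2015-04-15", "2016-03-01")), as.Date("2015-04-01"))
month_index <- function(dates, origin) {
  stopifnot(inherits(dates, "Date"), inherits(origin, "Date"), length(origin) == 1L)
  dl <- as.POSIXlt(dates)
  ol <- as.POSIXlt(origin)
  12L * (dl$year - ol$year) + (dl$mon - ol$mon) + 1L
}

#' First calendar day of a month index
#'
#' Inverse of [month_index()] up to within-month resolution.
#'
#' @param idx integer month indices.
#' @param origin the `Date` whose month is index 1.
#' @return a `Date` vector of month starts.
#' @export
month_start <- function(idx, origin) {
  stopifnot(inherits(origin, "Date"))
  ol <- as.POSIXlt(origin)
  tot <- 12L * ol$year + ol$mon + as.integer(idx) - 1L
  out <- as.Date(rep(NA_character_, length(tot)))
  ok <- !is.na(tot)
  out[ok] <- as.Date(sprintf("%04d-%02d-01", tot[ok] %/% 12L + 1900L,
                             tot[ok] %% 12L + 1L))
  out
}

# round-half-up to an integer (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# deterministic 32-bit sub-seed derivation; keeps derived seeds < 2^31
derive_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binary cross-entropy with probability clamping
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

logit <- function(p) qlogis(p)
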