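# independent brute-force oracles, deliberately naive implementations

# AUROC as the all-pairs probability P(score_pos > score_neg) + half ties
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# average precision from the explicit precision-recall staircase
auprc_brute <- function(scores, labels) {
  o <- order(-scores)
  y <- labels[o]
  npos <- sum(y)
  tp <- 0; fp <- 0; ap <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / (tp + fp)
    } else fp <- fp + 1
  }
  ap / npos
}

# confusion-matrix sensitivity/specificity
threshold_brute <- function(scores, labels, th) {
  pred <- as.integer(scores >= th)
  c(sensitivity = sum(pred == 1 & labels == 1) / sum(labels == 1),
    specificity = sum(pred == 0 & labels == 0) / sum(labels == 0))
}

# exact hypergeometric point probability from binomial coefficients only
hyper_point <- function(a, m, n2, k) {
  exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
}

# minlike two-sided Fisher p by full enumeration of the support
fisher_enum_minlike <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  pr <- vapply(supp, hyper_point, numeric(1), m = m, n2 = n2, k = k)
  p0 <- hyper_point(a, m, n2, k)
  min(1, sum(pr[pr <= p0 * (1 + 1e-9)]))
}

# central two-sided Fisher p from enumerated tail sums
fisher_enum_central <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  pr <- vapply(supp, hyper_point, numeric(1), m = m, n2 = n2, k = k)
  lo <- sum(pr[supp <= a])
  up <- sum(pr[supp >= a])
  min(1, 2 * min(lo, up))
}

# brute-force outcome relabeler: the outcome rules written as one literal loop
relabel_brute <- function(m, endpoint, death, L, horizon) {
  if (!is.na(endpoint) && m >= endpoint) return("censored")
  if (!is.na(endpoint) && endpoint >= m + 1 && endpoint <= m + L) return("1")
  if (m + L <= horizon) return("0")
  if (!is.na(death) && death <= m + L && death <= horizon) return("0")
  "unobservable"
}

# sample quantile (type 7) recomputed from first principles on sorted values
quantile7_brute <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
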