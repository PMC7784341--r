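## Stratified 2x2 statistics: the Mantel-Haenszel common odds ratio (the
## "pausing score"), its chi-squared test, and multiple-testing
## correction.  Strata are genes; cells are a = foreground reads with
## the feature, b = foreground without, c = background with,
## d = background without.
##
## The odds-ratio estimator uses the pure MH weights with no continuity
## correction, so the score stays interpretable as a ratio; the 0.5
## continuity correction enters only the test statistic.  Strata whose
## foreground (a + b) or background (c + d) total is zero carry no
## information about the odds ratio and are dropped from both the
## estimator and the test.

.check_strata <- function(strata) {
  dt <- as.data.table(strata)
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(dt)))
    stop("strata need columns a, b, c, d")
  if (nrow(dt) == 0L) stop("at least one stratum is required")
  if (any(dt$a < 0 | dt$b < 0 | dt$c < 0 | dt$d < 0, na.rm = TRUE) ||
      anyNA(dt[, .(a, b, c, d)]))
    stop("stratum counts must be non-negative and non-missing")
  for (col in need)  # doubles: variance terms overflow integers
    set(dt, j = col, value = as.numeric(dt[[col]]))
  dt
}

#' Mantel-Haenszel common odds ratio
#'
#' `sum_i(a_i d_i / n_i) / sum_i(b_i c_i / n_i)` with `n_i` the stratum
#' total.  Strata with `n_i = 0`, or with an empty foreground or
#' background margin, are skipped.  Returns `+Inf` when the denominator
#' is zero with a positive numerator and `NaN` when no stratum is
#' informative.
#'
#' @param strata `data.frame` with columns `a`, `b`, `c`, `d` (one row
#'   per stratum).
#' @return The common odds ratio.
#' @examples
#' mh_common_or(data.frame(a = 20, b = 80, c = 10, d = 90))  # 2.25
#' @export
mh_common_or <- function(strata) {
  dt <- .check_strata(strata)
  dt <- dt[(a + b) > 0 & (c + d) > 0]
  if (nrow(dt) == 0L) return(NaN)
  n <- dt$a + dt$b + dt$c + dt$d
  num <- sum(dt$a * dt$d / n)
  den <- sum(dt$b * dt$c / n)
  if (den > 0) num / den else if (num > 0) Inf else NaN
}

#' Mantel-Haenszel chi-squared test
#'
#' Two-sided test of common odds ratio 1 with a 0.5 continuity
#' correction: `(|sum a_i - sum E_i| - 0.5)^2 / sum V_i` referred to a
#' 1-df chi-squared distribution, with `E_i` and `V_i` the conditional
#' hypergeometric mean and variance of `a_i`.  Strata with a zero row or
#' column margin (or `n_i <= 1`) contribute nothing; if none is
#' informative the result is `NaN`.
#'
#' @inheritParams mh_common_or
#' @param correct apply the 0.5 continuity correction (default `TRUE`).
#' @return Two-sided p value.
#' @export
mh_test_p <- function(strata, correct = TRUE) {
  dt <- .check_strata(strata)
  dt <- dt[(a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0]
  n <- dt$a + dt$b + dt$c + dt$d
  dt <- dt[n > 1]
  n <- n[n > 1]
  if (nrow(dt) == 0L) return(NaN)
  e <- (dt$a + dt$b) * (dt$a + dt$c) / n
  v <- (dt$a + dt$b) * (dt$c + dt$d) * (dt$a + dt$c) * (dt$b + dt$d) /
    (n^2 * (n - 1))
  sv <- sum(v)
  if (sv == 0) return(NaN)
  dev <- abs(sum(dt$a) - sum(e))
  if (correct) dev <- max(dev - 0.5, 0)
  stat <- dev^2 / sv
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Q values for a family of p values
#'
#' Benjamini-Hochberg step-up by default, or Storey-type q values with
#' the null proportion `pi0` estimated on a lambda grid
#' (0.05, 0.10, ..., 0.95) and smoothed with a cubic spline.  `NA`
#' p values yield `NA` q values and do not count toward the family
#' size.
#'
#' @param pvals numeric vector of p values.
#' @param method `"bh"` (default) or `"storey"`.
#' @return Numeric vector of q values, same length and order as
#'   `pvals`, with attribute `method` (and `pi0` in Storey mode).
#' @export
qvalues <- function(pvals, method = c("bh", "storey")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  p <- pvals[ok]
  q <- rep(NA_real_, length(pvals))
  if (length(p)) {
    if (method == "bh") {
      qv <- stats::p.adjust(p, method = "BH")
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      pi0 <- if (length(p) >= 10L) {
        fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
        stats::predict(fit, x = max(lambda))$y
      } else {
        min(pi0_l)
      }
      pi0 <- min(max(pi0, 0), 1)
      if (pi0 == 0) pi0 <- .Machine$double.eps
      qv <- pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
      attr(q, "pi0") <- pi0
    }
    ## enforce monotone non-decreasing q in sorted-p order
    o <- order(p)
    qv[o] <- cummax(qv[o])
    q[ok] <- pmin(qv, 1)
  }
  attr(q, "method") <- method
  q
}
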