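## Conventional two-sided 95% normal multiplier used by pharmacovigilance
## tools; reproduces published Woolf bounds at their printed precision.
Z_DEFAULT <- 1.96

## Haldane-Anscombe continuity correction: +0.5 on every cell, applied only
## when some cell is zero, so all-positive tables are untouched.
corrected_cells <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  applied <- any(cells == 0)
  if (applied) cells <- cells + 0.5
  list(cells = cells, applied = applied)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' The disproportionality measure: `ROR = (a*d) / (b*c)` with the Woolf
#' log-scale interval `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' If any cell is zero, 0.5 is added to all four cells first
#' (Haldane-Anscombe) and the result is flagged. The result also carries the
#' Yates-corrected chi-squared statistic, the co-report count `n = a`, and
#' the three-part signal verdict (see [evaluate_signal()]).
#'
#' @param t a [contingency_table()].
#' @param z two-sided normal multiplier for the confidence interval;
#'   defaults to the conventional 1.96 (95%).
#' @return an object of class `disprop_result` with fields `ror`, `ci_low`,
#'   `ci_high`, `z`, `chi2_yates`, `n`, `signal`, `correction_applied`, and
#'   the input `table`.
#' @examples
#' ror_estimate(hcq_pemphigus_table())
#' @export
ror_estimate <- function(t, z = Z_DEFAULT) {
  stopifnot(inherits(t, "contingency_table"))
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0) {
    stop_pv("pvsignal_validation_error", "z must be a positive number")
  }
  margins <- c(t$n_event, t$n_noevent, t$n_drug, t$n_nodrug)
  if (sum(margins == 0) >= 2L) {
    stop_pv("pvsignal_stat_error",
            "reporting odds ratio undefined: two or more empty margins")
  }
  cc <- corrected_cells(t)
  k <- cc$cells
  ror <- (k[1] * k[4]) / (k[2] * k[3])
  se <- sqrt(sum(1 / k))
  ci <- exp(log(ror) + c(-1, 1) * z * se)

  chi2 <- tryCatch(chi2_yates(t), pvsignal_stat_error = function(e) NA_real_)
  n <- t$a
  signal <- if (is.na(chi2)) FALSE else evaluate_signal(ci[1], chi2, n)

  structure(list(ror = ror, ci_low = ci[1], ci_high = ci[2], z = z,
                 chi2_yates = chi2, n = n, signal = signal,
                 correction_applied = cc$applied, table = t),
            class = "disprop_result")
}

#' @export
print.disprop_result <- function(x, ...) {
  cat(sprintf("<disprop_result> ROR %.3f (95%% CI %.3f-%.3f)\n",
              x$ror, x$ci_low, x$ci_high))
  cat(sprintf("  chi2 (Yates) %s, n = %d, signal: %s%s\n",
              if (is.na(x$chi2_yates)) "undefined" else
                format(round(x$chi2_yates, 2), big.mark = ","),
              as.integer(x$n), if (x$signal) "YES" else "no",
              if (x$correction_applied) "  [+0.5 zero-cell correction]" else ""))
  invisible(x)
}

#' @export
as.data.frame.disprop_result <- function(x, ...) {
  cbind(as.data.frame(x$table),
        data.frame(ror = x$ror, ci_low = x$ci_low, ci_high = x$ci_high,
                   chi2_yates = x$chi2_yates, n = x$n, signal = x$signal,
                   correction_applied = x$correction_applied))
}

#' Yates-corrected chi-squared statistic for a 2x2 table
#'
#' `N * (max(0, |ad - bc| - N/2))^2 / (n_event * n_noevent * n_drug *
#' n_nodrug)`. The continuity correction floors at zero, so the statistic is
#' exactly 0 when `|ad - bc| <= N/2`.
#'
#' @param t a [contingency_table()] with all four margins positive.
#' @return nonnegative scalar.
#' @export
chi2_yates <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (any(c(t$n_event, t$n_noevent, t$n_drug, t$n_nodrug) == 0)) {
    stop_pv("pvsignal_stat_error",
            "chi-squared undefined: a table margin is zero")
  }
  N <- t$total
  num <- max(0, abs(t$a * t$d - t$b * t$c) - N / 2)
  N * num^2 / (t$n_event * t$n_noevent * t$n_drug * t$n_nodrug)
}

#' Three-part pharmacovigilance signal rule
#'
#' A drug--event pair is flagged as a signal when, simultaneously, the lower
#' bound of the ROR's 95% interval exceeds 1, the Yates chi-squared exceeds
#' 4, and the number of co-reports exceeds 3. All three inequalities are
#' strict.
#'
#' @param ci_low lower Woolf bound of the ROR.
#' @param chi2 Yates-corrected chi-squared.
#' @param n co-report count (cell `a`).
#' @param thresholds the three cutoffs, in that order.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_signal <- function(ci_low, chi2, n, thresholds = c(1, 4, 3)) {
  vals <- c(ci_low, chi2, n)
  if (any(!is.finite(vals))) {
    stop_pv("pvsignal_validation_error",
            "signal rule inputs must be finite")
  }
  isTRUE(ci_low > thresholds[1] && chi2 > thresholds[2] && n > thresholds[3])
}

#' Binomial rate with Jeffreys 95% interval
#'
#' Point estimate `k/n` with the Jeffreys interval: 2.5th and 97.5th
#' quantiles of `Beta(k + 1/2, n - k + 1/2)`. By the usual boundary
#' convention the lower bound is 0 when `k = 0` and the upper bound is 1
#' when `k = n`. Also reports the odds `k / (n - k)` (undefined when
#' `k = n`).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @return an object of class `rate_estimate` with fields `k`, `n`, `rate`,
#'   `ci_low`, `ci_high`, `odds`.
#' @examples
#' jeffreys_rate(1545, 63538)
#' @export
jeffreys_rate <- function(k, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop_pv("pvsignal_validation_error", "n must be a positive integer")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0 || k > n ||
      k != round(k)) {
    stop_pv("pvsignal_validation_error", "k must be an integer in [0, n]")
  }
  ci_low <- if (k == 0) 0 else stats::qbeta(0.025, k + 0.5, n - k + 0.5)
  ci_high <- if (k == n) 1 else stats::qbeta(0.975, k + 0.5, n - k + 0.5)
  structure(list(k = k, n = n, rate = k / n, ci_low = ci_low,
                 ci_high = ci_high,
                 odds = if (k == n) NA_real_ else k / (n - k)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %d/%d = %.2f%% (95%% Jeffreys CI %.2f%%-%.2f%%), odds %s\n",
              x$k, x$n, 100 * x$rate, 100 * x$ci_low, 100 * x$ci_high,
              if (is.na(x$odds)) "undefined" else format(x$odds, digits = 4)))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value at fixed margins: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one
#' (the classical convention, as implemented by [stats::fisher.test()]).
#'
#' @param t a [contingency_table()].
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  stats::fisher.test(as.matrix(t))$p.value
}
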