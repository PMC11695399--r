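#' Compare disproportionality between two strata
#'
#' Tests whether the reporting odds ratio differs between two strata (e.g.
#' female vs male reports). For the saturated 2x2x2 layout the
#' drug-by-stratum interaction coefficient of a logistic model has the
#' closed-form maximum-likelihood estimate `log(OR1 / OR2)` with Wald
#' standard error `sqrt(sum(1/cell))` over the eight cells, so the test is
#' computed directly from the two tables. The zero-cell policy of
#' [ror_estimate()] (add 0.5 to all cells of a table containing a zero)
#' applies per table.
#'
#' @param t1,t2 [contingency_table()]s for the two strata; `t1` is the
#'   numerator stratum.
#' @param z normal multiplier for the per-stratum Woolf intervals.
#' @return an object of class `stratum_comparison`: per-stratum
#'   `disprop_result`s, `ratio_of_ors` (`OR1/OR2`), `log_ratio_se`, the Wald
#'   `z` statistic and two-sided normal `p`.
#' @examples
#' t1 <- contingency_table(10, 10, 10, 10)
#' t2 <- contingency_table(20, 10, 10, 20)
#' compare_strata(t1, t2)
#' @export
compare_strata <- function(t1, t2, z = Z_DEFAULT) {
  stopifnot(inherits(t1, "contingency_table"), inherits(t2, "contingency_table"))
  degenerate <- function(t) sum(c(t$n_event, t$n_noevent, t$n_drug, t$n_nodrug) == 0) >= 2L
  if (degenerate(t1) && degenerate(t2)) {
    stop_pv("pvsignal_stat_error",
            "stratum comparison undefined: both tables degenerate")
  }
  r1 <- ror_estimate(t1, z = z)
  r2 <- ror_estimate(t2, z = z)
  k1 <- corrected_cells(t1)$cells
  k2 <- corrected_cells(t2)$cells
  ratio <- r1$ror / r2$ror
  se <- sqrt(sum(1 / k1) + sum(1 / k2))
  zstat <- log(ratio) / se
  structure(list(strata = list(stratum1 = r1, stratum2 = r2),
                 ratio_of_ors = ratio, log_ratio_se = se, z = zstat,
                 p = 2 * stats::pnorm(-abs(zstat)),
                 correction_applied = r1$correction_applied ||
                   r2$correction_applied),
            class = "stratum_comparison")
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(sprintf("<stratum_comparison> ratio of RORs %.4g (stratum1 %.4g / stratum2 %.4g)\n",
              x$ratio_of_ors, x$strata$stratum1$ror, x$strata$stratum2$ror))
  cat(sprintf("  interaction: log-ratio %.4f, SE %.4f, z = %.3f, p = %.4g%s\n",
              log(x$ratio_of_ors), x$log_ratio_se, x$z, x$p,
              if (x$correction_applied) "  [+0.5 zero-cell correction]" else ""))
  invisible(x)
}

#' Compare drug-exposure rates between two sex strata
#'
#' Per-stratum exposure rates with Jeffreys intervals, the exposure odds
#' ratio (stratum 1 vs stratum 2) with its Woolf interval, and Fisher's
#' exact two-sided p-value on the 2x2 exposure-by-sex table. Exposure means
#' the report lists `drug` (case-insensitive exact match).
#'
#' @param rs a [report_set()].
#' @param drug drug name defining exposure.
#' @param s1,s2 sex strata to contrast (default female vs male).
#' @param z normal multiplier for the odds-ratio interval.
#' @return an object of class `exposure_comparison`: `rates` (a
#'   [jeffreys_rate()] per stratum), `exposure_or`, `or_ci_low`,
#'   `or_ci_high`, `fisher_p`, `correction_applied`.
#' @export
compare_exposure <- function(rs, drug, s1 = "FEMALE", s2 = "MALE",
                             z = Z_DEFAULT) {
  stopifnot(inherits(rs, "report_set"))
  s1 <- match.arg(s1, SEX_LEVELS)
  s2 <- match.arg(s2, SEX_LEVELS)
  drug <- normalize_term(drug)
  exposed_ids <- rs$drugs$report_id[rs$drugs$drug_name == drug]
  exposed <- rs$demo$report_id %in% exposed_ids

  count_stratum <- function(s) {
    sel <- rs$demo$sex == s
    if (!any(sel)) {
      stop_pv("pvsignal_stat_error",
              "exposure rate undefined: stratum %s has no reports", s)
    }
    c(k = sum(exposed & sel), n = sum(sel))
  }
  c1 <- count_stratum(s1)
  c2 <- count_stratum(s2)
  rates <- list(jeffreys_rate(c1[["k"]], c1[["n"]]),
                jeffreys_rate(c2[["k"]], c2[["n"]]))
  names(rates) <- c(s1, s2)

  # exposure-by-stratum 2x2: rows exposed/unexposed, columns s1/s2
  exp_tab <- contingency_table(a = c1[["k"]], b = c2[["k"]],
                               c = c1[["n"]] - c1[["k"]],
                               d = c2[["n"]] - c2[["k"]])
  or_res <- ror_estimate(exp_tab, z = z)
  structure(list(rates = rates,
                 exposure_or = or_res$ror,
                 or_ci_low = or_res$ci_low, or_ci_high = or_res$ci_high,
                 fisher_p = fisher_exact(exp_tab),
                 correction_applied = or_res$correction_applied,
                 table = exp_tab),
            class = "exposure_comparison")
}

#' @export
print.exposure_comparison <- function(x, ...) {
  cat("<exposure_comparison>\n")
  for (s in names(x$rates)) {
    r <- x$rates[[s]]
    cat(sprintf("  %s: %d/%d = %.2f%% (%.2f%%-%.2f%%)\n", s, r$k, r$n,
                100 * r$rate, 100 * r$ci_low, 100 * r$ci_high))
  }
  cat(sprintf("  exposure OR %.3f (95%% CI %.3f-%.3f), Fisher p = %.4g%s\n",
              x$exposure_or, x$or_ci_low, x$or_ci_high, x$fisher_p,
              if (x$correction_applied) "  [+0.5 zero-cell correction]" else ""))
  invisible(x)
}
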