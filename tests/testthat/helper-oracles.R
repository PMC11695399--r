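# Independent oracles and small fixtures used across the suite.

# Naive per-report recount: loop over reports, membership-test the query in
# that report's own drug/event sets. Deliberately independent of the
# vectorized implementation in tabulate_reports().
brute_force_table <- function(rs, q) {
  drug_sets <- split(rs$drugs$drug_name, rs$drugs$report_id)
  event_sets <- split(rs$events$event_pt, rs$events$report_id)
  a <- b <- cc <- d <- 0L
  for (id in rs$demo$report_id) {
    has_drug <- q$drug_name %in% drug_sets[[id]]
    has_event <- q$event_pt %in% event_sets[[id]]
    if (has_drug && has_event) a <- a + 1L
    else if (!has_drug && has_event) b <- b + 1L
    else if (has_drug && !has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Two-sided Fisher p by full hypergeometric enumeration at fixed margins:
# sum P(table) over all tables with P <= P(observed).
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0L, n1 - m2); hi <- min(m1, n1)
  logp <- function(x) {
    lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  }
  p_obs <- logp(a)
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  sum(probs[probs <= exp(p_obs) * (1 + 1e-7)])
}

# Mid-p variant: half the probability of the observed table.
fisher_midp <- function(a, b, c, d) {
  p_obs <- exp(lchoose(a + b, a) + lchoose(c + d, c) -
                 lchoose(a + b + c + d, a + c))
  fisher_enum(a, b, c, d) - 0.5 * p_obs
}

# Iteratively fitted saturated logistic interaction model on two 2x2 tables:
# event ~ drug * stratum on the 8 aggregated cells. Returns the interaction
# MLE, its Wald SE, and the two-sided Wald p.
glm_interaction_oracle <- function(t1, t2) {
  cells <- function(t, s) {
    data.frame(drug = c(1, 0, 1, 0), stratum = s,
               event = c(1, 1, 0, 0), w = c(t$a, t$b, t$c, t$d))
  }
  df <- rbind(cells(t1, 1), cells(t2, 0))
  fit <- suppressWarnings(
    stats::glm(event ~ drug * stratum, family = stats::binomial(),
               data = df, weights = w,
               control = stats::glm.control(epsilon = 1e-14, maxit = 200)))
  est <- stats::coef(fit)[["drug:stratum"]]
  se <- sqrt(stats::vcov(fit)["drug:stratum", "drug:stratum"])
  list(est = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

# Small hand-written report set: r1 drug+event, r2 event only, r3 drug only,
# r4 neither.
tiny_report_set <- function() {
  report_set(
    demo = data.frame(
      report_id = c("r1", "r2", "r3", "r4"),
      sex = c("FEMALE", "MALE", "FEMALE", "UNSPECIFIED"),
      age_group = c("18-64", "65-85", "18-64", "UNSPECIFIED"),
      year = c(2020L, 2021L, 2020L, NA)),
    drugs = data.frame(report_id = c("r1", "r3"),
                       drug_name = c("Hydroxychloroquine", "hydroxychloroquine")),
    events = data.frame(report_id = c("r1", "r2"),
                        event_pt = c("Pemphigus", "nausea")))
}

HCQ_QUERY <- coding_query("hydroxychloroquine", "pemphigus")
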