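## Run expr with a private RNG stream: seed explicitly, restore any global
## state afterwards so generation never perturbs a caller's simulation.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Per-report attachment rates for decoy drugs/events: low, fixed, and
## independent of the index pair so the all-other-reports background is a
## clean null.
DECOY_DRUG_RATE <- 0.02
DECOY_EVENT_RATE <- 0.02

#' Configuration for the synthetic report-database generator
#'
#' Describes a spontaneous-report database with a single planted drug--event
#' association of known reporting odds ratio. Defaults mirror the FAERS
#' hydroxychloroquine setting: an exposure prevalence of 0.56%, a rare
#' background event (about 1 report in 10,000), female-skewed exposure with
#' a female:male odds ratio of 2.82, and receipt years 2003--2023.
#'
#' @param n_reports number of reports to generate.
#' @param p_drug marginal probability that a report lists the index drug.
#' @param p_event_bg probability that a non-exposed report lists the index
#'   event.
#' @param target_ror planted reporting odds ratio: exposed reports carry the
#'   index event with odds `target_ror` times the background odds.
#' @param sex_mix named proportions over `FEMALE`, `MALE`, `UNSPECIFIED`;
#'   must sum to 1.
#' @param sex_exposure_or odds ratio of index-drug exposure, female vs male.
#'   Sex-specific exposure odds are solved so this ratio and the marginal
#'   `p_drug` both hold exactly in expectation; unspecified-sex reports get
#'   the marginal exposure odds.
#' @param year_range inclusive integer interval of receipt years.
#' @param surge_year_weights optional named numeric vector of per-year
#'   multipliers applied to the year distribution of exposed index-event
#'   reports (e.g. `c("2020" = 3)` triples their reporting weight in 2020),
#'   emulating a late-period reporting surge.
#' @param n_decoy_drugs,n_decoy_events number of background drugs/events
#'   attached independently at a low fixed rate.
#' @param index_drug,index_event names given to the planted pair.
#' @param seed integer seed for the generator's private RNG stream.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_reports,
                              p_drug = 0.0056,
                              p_event_bg = 1e-4,
                              target_ror = 1,
                              sex_mix = c(FEMALE = 0.55, MALE = 0.35,
                                          UNSPECIFIED = 0.10),
                              sex_exposure_or = 2.82,
                              year_range = c(2003L, 2023L),
                              surge_year_weights = NULL,
                              n_decoy_drugs = 5L,
                              n_decoy_events = 5L,
                              index_drug = "hydroxychloroquine",
                              index_event = "pemphigus",
                              seed = 1L) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stop_pv("pvsignal_validation_error",
                             "invalid simulation_config field: %s", field)
  }
  chk(is.numeric(n_reports) && length(n_reports) == 1L &&
        n_reports >= 0 && n_reports == round(n_reports), "n_reports")
  chk(is.numeric(p_drug) && length(p_drug) == 1L &&
        p_drug >= 0 && p_drug <= 1, "p_drug")
  chk(is.numeric(p_event_bg) && length(p_event_bg) == 1L &&
        p_event_bg >= 0 && p_event_bg <= 1, "p_event_bg")
  chk(is.numeric(target_ror) && length(target_ror) == 1L &&
        is.finite(target_ror) && target_ror > 0, "target_ror")
  chk(is.numeric(sex_mix) && length(sex_mix) == 3L &&
        setequal(names(sex_mix), SEX_LEVELS) && all(sex_mix >= 0) &&
        abs(sum(sex_mix) - 1) < 1e-8, "sex_mix")
  chk(is.numeric(sex_exposure_or) && length(sex_exposure_or) == 1L &&
        is.finite(sex_exposure_or) && sex_exposure_or > 0, "sex_exposure_or")
  chk(is.numeric(year_range) && length(year_range) == 2L &&
        all(year_range == round(year_range)) &&
        year_range[1] <= year_range[2], "year_range")
  if (!is.null(surge_year_weights)) {
    chk(is.numeric(surge_year_weights) && all(surge_year_weights > 0) &&
          !is.null(names(surge_year_weights)) &&
          all(as.integer(names(surge_year_weights)) >= year_range[1]) &&
          all(as.integer(names(surge_year_weights)) <= year_range[2]),
        "surge_year_weights")
  }
  chk(is.numeric(n_decoy_drugs) && length(n_decoy_drugs) == 1L &&
        n_decoy_drugs >= 1 && n_decoy_drugs == round(n_decoy_drugs),
      "n_decoy_drugs")
  chk(is.numeric(n_decoy_events) && length(n_decoy_events) == 1L &&
        n_decoy_events >= 1 && n_decoy_events == round(n_decoy_events),
      "n_decoy_events")
  chk(is.character(index_drug) && length(index_drug) == 1L &&
        nzchar(index_drug), "index_drug")
  chk(is.character(index_event) && length(index_event) == 1L &&
        nzchar(index_event), "index_event")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed) &&
        seed == round(seed), "seed")

  structure(list(n_reports = as.integer(n_reports), p_drug = p_drug,
                 p_event_bg = p_event_bg, target_ror = target_ror,
                 sex_mix = sex_mix[SEX_LEVELS],
                 sex_exposure_or = sex_exposure_or,
                 year_range = as.integer(year_range),
                 surge_year_weights = surge_year_weights,
                 n_decoy_drugs = as.integer(n_decoy_drugs),
                 n_decoy_events = as.integer(n_decoy_events),
                 index_drug = normalize_term(index_drug),
                 index_event = normalize_term(index_event),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Solve the per-sex exposure odds so that (i) the female:male exposure odds
## ratio equals `or` exactly and (ii) the marginal exposure probability over
## the sex mix equals p_drug. Unspecified-sex reports take the marginal
## odds; the remaining one-dimensional root (male odds) is bracketed on the
## log scale and solved with uniroot.
solve_exposure_odds <- function(p_drug, sex_mix, or) {
  if (p_drug == 0) return(c(FEMALE = 0, MALE = 0, UNSPECIFIED = 0))
  odds_marg <- p_drug / (1 - p_drug)
  odds_u <- odds_marg
  pf <- sex_mix[["FEMALE"]]; pm <- sex_mix[["MALE"]]; pu <- sex_mix[["UNSPECIFIED"]]
  if (pf + pm < 1e-12) {
    return(c(FEMALE = odds_marg, MALE = odds_marg, UNSPECIFIED = odds_u))
  }
  target <- p_drug - pu * odds_u / (1 + odds_u)  # prob mass F+M must supply
  g <- function(log_t) {
    t <- exp(log_t)
    pf * (or * t) / (1 + or * t) + pm * t / (1 + t) - target
  }
  root <- stats::uniroot(g, lower = log(odds_marg) - 40,
                         upper = log(odds_marg) + 40, tol = 1e-14)$root
  t <- exp(root)
  c(FEMALE = or * t, MALE = t, UNSPECIFIED = odds_u)
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` independent reports: sex from `sex_mix`; index-drug
#' exposure with sex-specific odds (female:male odds ratio
#' `sex_exposure_or`, marginal rate `p_drug`); the index event with
#' background probability `p_event_bg` when unexposed and with odds
#' multiplied by `target_ror` when exposed — so the planted effect is
#' defined on the same odds scale the reporting odds ratio estimates; decoy
#' drugs and events attached independently at low fixed rates; receipt year
#' uniform over `year_range`, reweighted by `surge_year_weights` for
#' exposed index-event reports. Identical configs (including seed) produce
#' identical report sets.
#'
#' @param config a [simulation_config()].
#' @return list with elements `reports` (a [report_set()]) and `truth`
#'   (class `simulation_truth`: `expected_table` — expected cell counts
#'   implied by the config —, `true_ror`, and the per-sex exposure odds).
#' @examples
#' sim <- generate_reports(simulation_config(n_reports = 1000, target_ror = 20,
#'                                           p_drug = 0.05, p_event_bg = 0.01,
#'                                           seed = 42))
#' tabulate_reports(sim$reports, coding_query("hydroxychloroquine", "pemphigus"))
#' @export
generate_reports <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_pv("pvsignal_validation_error",
            "config must be created by simulation_config()")
  }
  n <- config$n_reports
  q <- config$p_event_bg
  ror <- config$target_ror
  p_event_exposed <- ror * q / (1 - q + ror * q)
  odds <- solve_exposure_odds(config$p_drug, config$sex_mix,
                              config$sex_exposure_or)
  p_exp <- odds / (1 + odds)

  truth <- structure(list(
    expected_table = c(a = n * config$p_drug * p_event_exposed,
                       b = n * (1 - config$p_drug) * q,
                       c = n * config$p_drug * (1 - p_event_exposed),
                       d = n * (1 - config$p_drug) * (1 - q)),
    true_ror = ror,
    exposure_odds = odds),
    class = "simulation_truth")

  if (n == 0L) {
    rs <- report_set(data.frame(report_id = character(), sex = character(),
                                age_group = character(), year = integer()),
                     provenance = "synthetic: empty")
    return(list(reports = rs, truth = truth))
  }

  out <- with_rng(config$seed, {
    sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_mix)
    exposed <- stats::rbinom(n, 1L, p_exp[sex]) == 1L
    p_ev <- ifelse(exposed, p_event_exposed, q)
    has_event <- stats::rbinom(n, 1L, p_ev) == 1L

    years <- seq(config$year_range[1], config$year_range[2])
    w <- rep(1, length(years))
    year <- sample(years, n, replace = TRUE)
    is_case <- exposed & has_event
    if (!is.null(config$surge_year_weights) && any(is_case)) {
      wc <- w
      idx <- match(as.integer(names(config$surge_year_weights)), years)
      wc[idx] <- wc[idx] * config$surge_year_weights
      year[is_case] <- sample(years, sum(is_case), replace = TRUE, prob = wc)
    }

    ids <- sprintf("s%07d", seq_len(n))
    link_rows <- function(sel_ids, name, col) {
      out <- data.frame(report_id = sel_ids,
                        value = rep_len(name, length(sel_ids)))
      names(out)[2] <- col
      out
    }
    drug_rows <- link_rows(ids[exposed], config$index_drug, "drug_name")
    for (j in seq_len(config$n_decoy_drugs)) {
      pick <- stats::rbinom(n, 1L, DECOY_DRUG_RATE) == 1L
      drug_rows <- rbind(drug_rows,
                         link_rows(ids[pick], sprintf("decoy_drug_%02d", j),
                                   "drug_name"))
    }
    event_rows <- link_rows(ids[has_event], config$index_event, "event_pt")
    for (j in seq_len(config$n_decoy_events)) {
      pick <- stats::rbinom(n, 1L, DECOY_EVENT_RATE) == 1L
      event_rows <- rbind(event_rows,
                          link_rows(ids[pick], sprintf("decoy_event_%02d", j),
                                    "event_pt"))
    }
    age <- sample(AGE_LEVELS, n, replace = TRUE,
                  prob = c(0.05, 0.55, 0.25, 0.05, 0.10))
    list(demo = data.frame(report_id = ids, sex = sex, age_group = age,
                           year = year),
         drugs = drug_rows, events = event_rows)
  })

  rs <- report_set(out$demo, out$drugs, out$events,
                   provenance = sprintf(
                     "synthetic: n=%d p_drug=%g p_event_bg=%g target_ror=%g seed=%d",
                     n, config$p_drug, q, ror, config$seed))
  list(reports = rs, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n  expected cells:",
      paste(sprintf("%s=%.2f", names(x$expected_table), x$expected_table),
            collapse = " "),
      sprintf("\n  true ROR: %g\n", x$true_ror))
  invisible(x)
}

#' Published hydroxychloroquine--pemphigus contingency counts
#'
#' The FAERS-wide 2x2 table for hydroxychloroquine exposure against the
#' MedDRA preferred term "pemphigus" (all-other-reports comparator;
#' OpenVigil 2.1 extract, Q4 2003 -- Q2 2023), shipped as a plain-text
#' fixture: 1,545 co-reports, 1,003 event-only, 61,993 drug-only and
#' 11,375,215 background reports (grand total 11,439,756).
#'
#' @return a [contingency_table()].
#' @examples
#' hcq_pemphigus_table()
#' @export
hcq_pemphigus_table <- function() {
  path <- system.file("extdata", "hcq_pemphigus_counts.tsv",
                      package = "pvsignal", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cnt <- stats::setNames(tab$count, tab$cell)
  contingency_table(cnt[["a"]], cnt[["b"]], cnt[["c"]], cnt[["d"]])
}

#' Materialize a report set from (scaled) contingency counts
#'
#' Scales a 2x2 table's cells by `scale`, rounds them to integers with the
#' largest-remainder (exact multinomial) rule so the rounded cells sum to
#' `round(scale * total)`, and builds a report set realizing those counts
#' for the given drug/event pair. Demographics are left unspecified; report
#' order is shuffled deterministically by `seed`. This turns a printed
#' contingency table into an end-to-end pipeline input at desk scale.
#'
#' @param t a [contingency_table()].
#' @param scale real in (0, 1]; `scale * total` must be at least 1.
#' @param seed integer seed for the order shuffle.
#' @param drug,event names attached to the exposed/event reports.
#' @return a [report_set()] whose [tabulate_reports()] output equals the
#'   scaled, rounded cells.
#' @export
scaled_report_set <- function(t, scale, seed = 1L,
                              drug = "hydroxychloroquine",
                              event = "pemphigus") {
  stopifnot(inherits(t, "contingency_table"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0 || scale > 1 || scale * t$total < 1) {
    stop_pv("pvsignal_validation_error",
            "scale must lie in (0, 1] with scale * total >= 1")
  }
  raw <- c(t$a, t$b, t$c, t$d) * scale
  cells <- largest_remainder_round(raw)

  n <- sum(cells)
  grp <- rep.int(c("a", "b", "c", "d"), cells)
  ids <- sprintf("f%07d", seq_len(n))
  perm <- with_rng(seed, sample.int(n))
  grp <- grp[perm]

  exposed <- grp %in% c("a", "c")
  has_event <- grp %in% c("a", "b")
  report_set(
    data.frame(report_id = ids, sex = "UNSPECIFIED",
               age_group = "UNSPECIFIED", year = NA_integer_),
    drugs = data.frame(report_id = ids[exposed],
                       drug_name = rep_len(drug, sum(exposed))),
    events = data.frame(report_id = ids[has_event],
                        event_pt = rep_len(event, sum(has_event))),
    provenance = sprintf("scaled fixture: scale=%g seed=%d", scale, seed))
}

## Round nonnegative reals to integers summing to round(sum(x)): floor, then
## give the leftover units to the largest fractional remainders (ties to the
## earlier cell).
largest_remainder_round <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  left <- as.integer(total - sum(base))
  if (left > 0) {
    ord <- order(x - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
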