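#' 2x2 drug--event contingency table
#'
#' The unit all disproportionality statistics consume. Cells follow the
#' standard pharmacovigilance layout against the all-other-reports
#' comparator:
#' \describe{
#'   \item{a}{reports with the drug AND the event}
#'   \item{b}{reports with the event, without the drug}
#'   \item{c}{reports with the drug, without the event}
#'   \item{d}{reports with neither}
#' }
#' Margins (`n_event = a+b`, `n_noevent = c+d`, `n_drug = a+c`,
#' `n_nodrug = b+d`) and the grand total are derived and stored.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return an object of class `contingency_table`.
#' @examples
#' contingency_table(1545, 1003, 61993, 11375215)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_pv("pvsignal_validation_error",
            "cells a, b, c, d must be nonnegative integers")
  }
  # store as double: products like a*d overflow 32-bit integers at FAERS scale
  cells <- stats::setNames(as.double(round(cells)), c("a", "b", "c", "d"))
  structure(list(a = cells[["a"]], b = cells[["b"]],
                 c = cells[["c"]], d = cells[["d"]],
                 n_event = cells[["a"]] + cells[["b"]],
                 n_noevent = cells[["c"]] + cells[["d"]],
                 n_drug = cells[["a"]] + cells[["c"]],
                 n_nodrug = cells[["b"]] + cells[["d"]],
                 total = sum(cells)),
            class = "contingency_table")
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(event = c("event", "no_event"),
                         drug = c("drug", "no_drug")))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  m <- as.matrix(x)
  m <- rbind(m, sums = colSums(m))
  m <- cbind(m, sums = rowSums(m))
  print(format(m, big.mark = ","), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, d = x$d,
             n_event = x$n_event, n_noevent = x$n_noevent,
             n_drug = x$n_drug, n_nodrug = x$n_nodrug, total = x$total)
}

## Logical exposure / event indicators per report, in demo-table order.
## A report with no drug rows is unexposed: exposure is evidenced only by a
## drug row carrying the queried name.
match_flags <- function(rs, q) {
  stopifnot(inherits(rs, "report_set"))
  if (!inherits(q, "coding_query")) q <- coding_query(q$drug_name, q$event_pt)
  ids <- rs$demo$report_id
  drug_ids <- rs$drugs$report_id[rs$drugs$drug_name == q$drug_name]
  event_ids <- rs$events$report_id[rs$events$event_pt == q$event_pt]
  list(exposed = ids %in% drug_ids, has_event = ids %in% event_ids)
}

#' Build the 2x2 table for a drug--event query
#'
#' Each report contributes to exactly one cell, so the cells always sum to
#' the number of reports; the comparator is every other report in the set.
#'
#' @param rs a [report_set()].
#' @param q a [coding_query()].
#' @return a [contingency_table()].
#' @examples
#' rs <- report_set(data.frame(report_id = c("r1", "r2"), sex = "FEMALE",
#'                             age_group = "18-64", year = 2022L),
#'                  drugs = data.frame(report_id = "r1",
#'                                     drug_name = "hydroxychloroquine"),
#'                  events = data.frame(report_id = "r1",
#'                                      event_pt = "pemphigus"))
#' tabulate_reports(rs, coding_query("hydroxychloroquine", "pemphigus"))
#' @export
tabulate_reports <- function(rs, q) {
  f <- match_flags(rs, q)
  contingency_table(a = sum(f$exposed & f$has_event),
                    b = sum(!f$exposed & f$has_event),
                    c = sum(f$exposed & !f$has_event),
                    d = sum(!f$exposed & !f$has_event))
}

#' Stratified 2x2 tables
#'
#' Splits the report set by a demographic stratifier and tabulates the query
#' within each stratum. Every enumeration value appears as a key, possibly
#' with an all-zero table, so the stratum tables always sum cellwise to the
#' pooled [tabulate_reports()] table. For `by = "year"` the keys are the
#' observed year span plus `"UNSPECIFIED"`.
#'
#' @param rs a [report_set()].
#' @param q a [coding_query()].
#' @param by one of `"sex"`, `"age_group"`, `"year"`.
#' @return named list of [contingency_table()], one per stratum.
#' @export
stratify_reports <- function(rs, q, by = c("sex", "age_group", "year")) {
  if (length(by) != 1L || !by %in% c("sex", "age_group", "year")) {
    stop_pv("pvsignal_validation_error",
            "stratifier must be one of sex, age_group, year")
  }
  f <- match_flags(rs, q)
  strata <- switch(by,
    sex = factor(rs$demo$sex, levels = SEX_LEVELS),
    age_group = factor(rs$demo$age_group, levels = AGE_LEVELS),
    year = {
      y <- rs$demo$year
      lev <- if (all(is.na(y))) character() else
        as.character(seq(min(y, na.rm = TRUE), max(y, na.rm = TRUE)))
      v <- ifelse(is.na(y), "UNSPECIFIED", as.character(y))
      factor(v, levels = c(lev, "UNSPECIFIED"))
    })
  out <- lapply(levels(strata), function(lv) {
    sel <- !is.na(strata) & strata == lv
    contingency_table(a = sum(f$exposed[sel] & f$has_event[sel]),
                      b = sum(!f$exposed[sel] & f$has_event[sel]),
                      c = sum(f$exposed[sel] & !f$has_event[sel]),
                      d = sum(!f$exposed[sel] & !f$has_event[sel]))
  })
  names(out) <- levels(strata)
  out
}

#' Yearly trend of drug--event co-reports
#'
#' Counts reports carrying both the drug and the event per receipt year.
#' Percentages are taken against the number of matching reports with a
#' specified year (the denominator is carried in the result so it is always
#' printed alongside). Reports with an unspecified year are excluded from
#' the series; years with zero matches inside the observed span are kept.
#'
#' @param rs a [report_set()].
#' @param q a [coding_query()].
#' @return a `trend_series`: data.frame with columns `year`, `count`,
#'   `percent`, plus attributes `denominator` (specified-year matches) and
#'   `n_unspecified_year`.
#' @export
yearly_trend <- function(rs, q) {
  f <- match_flags(rs, q)
  match_years <- rs$demo$year[f$exposed & f$has_event]
  n_unspec <- sum(is.na(match_years))
  y <- match_years[!is.na(match_years)]
  if (length(y) == 0L) {
    out <- data.frame(year = integer(), count = integer(), percent = double())
  } else {
    span <- seq(min(y), max(y))
    cnt <- as.integer(table(factor(y, levels = span)))
    out <- data.frame(year = span, count = cnt,
                      percent = 100 * cnt / length(y))
  }
  structure(out, denominator = length(y), n_unspecified_year = n_unspec,
            class = c("trend_series", "data.frame"))
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> %d year(s), denominator %d matching report(s)",
              nrow(x), attr(x, "denominator")))
  if (attr(x, "n_unspecified_year") > 0L) {
    cat(sprintf(" (+%d with unspecified year, excluded)",
                attr(x, "n_unspecified_year")))
  }
  cat("\n")
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
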