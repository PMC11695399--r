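## Closed enumerations for report demographics. Values outside these map to
## UNSPECIFIED on ingestion; they are never extended at run time.
SEX_LEVELS <- c("FEMALE", "MALE", "UNSPECIFIED")
AGE_LEVELS <- c("0-17", "18-64", "65-85", ">85", "UNSPECIFIED")

DIALECTS <- c(dollar = "$", tab = "\t")

stop_pv <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pvsignal_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Normalize a drug or event term
#'
#' Terms are matched by exact, case-insensitive, whitespace-trimmed string
#' equality throughout the package; this helper applies that normalization
#' (trim + lower-case) once, on ingestion.
#' @param x character vector of terms
#' @return normalized character vector
#' @keywords internal
normalize_term <- function(x) {
  tolower(trimws(as.character(x)))
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | !(x %in% SEX_LEVELS)] <- "UNSPECIFIED"
  x
}

normalize_age <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !(x %in% AGE_LEVELS)] <- "UNSPECIFIED"
  x
}

normalize_year <- function(x) {
  y <- suppressWarnings(as.integer(x))
  y[!is.finite(y)] <- NA_integer_
  y
}

#' Construct a spontaneous-report set
#'
#' A report set is the unit every analysis consumes: one row per spontaneous
#' report (identified by an opaque `report_id`) carrying sex, age group and
#' receipt year, plus two long tables linking report ids to the set of
#' normalized drug names and MedDRA preferred terms (events) on each report.
#' Drug and event entries are deduplicated per report; demographic values
#' outside the closed enumerations become `"UNSPECIFIED"`, and an unknown
#' receipt year is `NA`.
#'
#' @param demo data.frame with columns `report_id`, `sex`, `age_group`,
#'   `year`; one row per report, ids unique.
#' @param drugs data.frame with columns `report_id`, `drug_name` (may be
#'   empty).
#' @param events data.frame with columns `report_id`, `event_pt` (may be
#'   empty).
#' @param provenance free-text description of where the reports came from.
#' @return an object of class `report_set`.
#' @examples
#' rs <- report_set(
#'   demo = data.frame(report_id = c("r1", "r2"), sex = c("FEMALE", "MALE"),
#'                     age_group = "18-64", year = 2022L),
#'   drugs = data.frame(report_id = "r1", drug_name = "Hydroxychloroquine"),
#'   events = data.frame(report_id = c("r1", "r2"),
#'                       event_pt = c("pemphigus", "nausea"))
#' )
#' n_reports(rs)
#' @export
report_set <- function(demo,
                       drugs = data.frame(report_id = character(),
                                          drug_name = character()),
                       events = data.frame(report_id = character(),
                                           event_pt = character()),
                       provenance = "") {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  need <- c("report_id", "sex", "age_group", "year")
  miss <- setdiff(need, names(demo))
  if (length(miss) > 0L) {
    stop_pv("pvsignal_format_error",
            "demo table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  id <- trimws(as.character(demo$report_id))
  if (any(id == "" | is.na(id))) {
    stop_pv("pvsignal_validation_error", "report ids must be nonempty")
  }
  if (anyDuplicated(id)) {
    stop_pv("pvsignal_format_error", "duplicate report_id in demo table: %s",
            paste(unique(id[duplicated(id)])[1:min(3, sum(duplicated(id)))],
                  collapse = ", "))
  }
  demo <- data.frame(report_id = id,
                     sex = normalize_sex(demo$sex),
                     age_group = normalize_age(demo$age_group),
                     year = normalize_year(demo$year),
                     stringsAsFactors = FALSE)

  drugs <- clean_link_table(drugs, "drug_name", id)
  events <- clean_link_table(events, "event_pt", id)

  structure(list(demo = demo, drugs = drugs, events = events,
                 provenance = as.character(provenance)[1]),
            class = "report_set")
}

## Normalize, deduplicate and sort a (report_id, term) link table; rows whose
## id is absent from `ids` are the caller's responsibility (read_reports
## reports them as orphans before calling).
clean_link_table <- function(tab, value_col, ids) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  miss <- setdiff(c("report_id", value_col), names(tab))
  if (length(miss) > 0L) {
    stop_pv("pvsignal_format_error", "link table is missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  out <- data.frame(report_id = trimws(as.character(tab$report_id)),
                    value = normalize_term(tab[[value_col]]),
                    stringsAsFactors = FALSE)
  names(out)[2] <- value_col
  out <- out[out$report_id %in% ids & out[[value_col]] != "", , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$report_id, out[[value_col]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of reports in a report set
#' @param rs a `report_set`
#' @return integer count
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$demo)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug rows, %d event rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$events)))
  sx <- table(factor(x$demo$sex, levels = SEX_LEVELS))
  cat("  sex:", paste(sprintf("%s=%d", names(sx), sx), collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Drug--event query
#'
#' Names the drug of interest and the adverse-event preferred term whose
#' co-reporting is tested against the all-other-reports comparator. Matching
#' is exact, case-insensitive, whitespace-trimmed string equality.
#'
#' @param drug_name nonempty string, e.g. `"hydroxychloroquine"`.
#' @param event_pt nonempty string, e.g. `"pemphigus"`.
#' @return an object of class `coding_query`.
#' @export
coding_query <- function(drug_name, event_pt) {
  drug_name <- normalize_term(drug_name)
  event_pt <- normalize_term(event_pt)
  if (length(drug_name) != 1L || length(event_pt) != 1L ||
      !nzchar(drug_name) || !nzchar(event_pt)) {
    stop_pv("pvsignal_validation_error",
            "coding_query needs one nonempty drug_name and one nonempty event_pt")
  }
  structure(list(drug_name = drug_name, event_pt = event_pt),
            class = "coding_query")
}

resolve_dialect <- function(dialect) {
  if (length(dialect) != 1L || !dialect %in% names(DIALECTS)) {
    stop_pv("pvsignal_validation_error",
            "dialect must be one of: %s", paste(names(DIALECTS), collapse = ", "))
  }
  DIALECTS[[dialect]]
}

read_one_table <- function(path, sep, required) {
  if (!file.exists(path)) {
    stop_pv("pvsignal_input_error", "input file does not exist: %s", path)
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop_pv("pvsignal_format_error", "%s is missing required column(s): %s",
            path, paste(miss, collapse = ", "))
  }
  tab
}

#' Read a report database from delimited tables
#'
#' Reads the three-table layout used by FAERS quarterly extracts:
#' a demographics table (one row per report), a drug table and a reaction
#' table (long format, keyed by report id). One `Report` is created per
#' distinct id in the demographics table; drug and event rows are unioned
#' onto it. Ids present only in the drug or reaction table are counted as
#' orphans, reported via a warning, and skipped — they never create reports.
#'
#' @param demo_path path to the demographics table
#'   (columns `report_id`, `sex`, `age_group`, `year`).
#' @param drug_path path to the drug table (columns `report_id`, `drug_name`).
#' @param reac_path path to the reaction table (columns `report_id`,
#'   `event_pt`).
#' @param dialect `"dollar"` for the FAERS ASCII `$` delimiter, or `"tab"`.
#' @return a [report_set()].
#' @seealso [write_reports()], which this inverts.
#' @export
read_reports <- function(demo_path, drug_path, reac_path,
                         dialect = c("dollar", "tab")) {
  dialect <- match.arg(dialect)
  sep <- resolve_dialect(dialect)
  demo <- read_one_table(demo_path, sep, c("report_id", "sex", "age_group", "year"))
  drugs <- read_one_table(drug_path, sep, c("report_id", "drug_name"))
  reac <- read_one_table(reac_path, sep, c("report_id", "event_pt"))

  ids <- trimws(demo$report_id)
  orphan <- setdiff(trimws(c(drugs$report_id, reac$report_id)), ids)
  if (length(orphan) > 0L) {
    warning(sprintf("%d orphan report id(s) in drug/reaction tables skipped (e.g. %s)",
                    length(orphan), orphan[1]), call. = FALSE)
  }
  report_set(demo, drugs, reac,
             provenance = sprintf("files: %s | %s | %s (dialect=%s)",
                                  demo_path, drug_path, reac_path, dialect))
}

#' Write a report database as delimited tables
#'
#' Emits `demo`, `drug` and `reac` tables into `out_dir` such that
#' [read_reports()] inverts the write exactly (set semantics: per-report drug
#' and event sets, and all demographic fields, are preserved). Unknown years
#' are written as empty fields. Output is byte-stable for identical input:
#' rows of the link tables are sorted by id and term.
#'
#' @param rs a [report_set()].
#' @param out_dir output directory, created if absent.
#' @param dialect `"dollar"` or `"tab"`.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_reports <- function(rs, out_dir, dialect = c("dollar", "tab")) {
  stopifnot(inherits(rs, "report_set"))
  dialect <- match.arg(dialect)
  sep <- resolve_dialect(dialect)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_pv("pvsignal_input_error", "cannot create directory: %s", out_dir)
  }
  ext <- if (dialect == "dollar") "txt" else "tsv"
  paths <- c(demo = file.path(out_dir, paste0("demo.", ext)),
             drug = file.path(out_dir, paste0("drug.", ext)),
             reac = file.path(out_dir, paste0("reac.", ext)))

  demo_out <- rs$demo
  demo_out$year <- ifelse(is.na(demo_out$year), "", as.character(demo_out$year))
  write_delimited(demo_out, paths["demo"], sep)
  write_delimited(rs$drugs, paths["drug"], sep)
  write_delimited(rs$events, paths["reac"], sep)
  invisible(paths)
}

write_delimited <- function(tab, path, sep) {
  ok <- tryCatch({
    utils::write.table(tab, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_pv("pvsignal_input_error", "cannot write file: %s", path)
  invisible(path)
}
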