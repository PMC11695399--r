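#' Configuration for an end-to-end analysis run
#'
#' Bundles exactly one input source — a three-file report database, a
#' [simulation_config()], or the built-in published
#' hydroxychloroquine--pemphigus counts — with the drug--event query,
#' optional stratifier, and output settings consumed by [run_simulate()],
#' [run_signal()] and [run_trend()].
#'
#' @param demo_path,drug_path,reac_path input table paths (all three or none).
#' @param dialect `"dollar"` or `"tab"`.
#' @param sim a [simulation_config()] used as the input source instead of
#'   files.
#' @param builtin_fixture use the published counts from
#'   [hcq_pemphigus_table()] as the input (no report-level data; only
#'   [run_signal()] without a stratifier supports this source).
#' @param drug_name,event_pt the query (required unless simulating only).
#' @param stratify optional stratifier: `"sex"`, `"age_group"` or `"year"`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param format output formats, subset of `c("tsv", "json")`.
#' @param seed integer seed forwarded to simulation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(demo_path = NULL, drug_path = NULL, reac_path = NULL,
                       dialect = "dollar", sim = NULL,
                       builtin_fixture = FALSE,
                       drug_name = NULL, event_pt = NULL, stratify = NULL,
                       out_dir = NULL, format = c("tsv", "json"),
                       seed = 1L) {
  files_given <- !is.null(demo_path) || !is.null(drug_path) || !is.null(reac_path)
  if (files_given &&
      (is.null(demo_path) || is.null(drug_path) || is.null(reac_path))) {
    stop_pv("pvsignal_validation_error",
            "demo_path, drug_path and reac_path must be given together")
  }
  n_sources <- sum(files_given, !is.null(sim), isTRUE(builtin_fixture))
  if (n_sources != 1L) {
    stop_pv("pvsignal_validation_error",
            "exactly one input source required: files, sim, or builtin_fixture")
  }
  if (!is.null(sim) && !inherits(sim, "simulation_config")) {
    stop_pv("pvsignal_validation_error", "sim must be a simulation_config")
  }
  if (!is.null(stratify) &&
      !stratify %in% c("sex", "age_group", "year")) {
    stop_pv("pvsignal_validation_error",
            "stratify must be one of sex, age_group, year")
  }
  format <- match.arg(format, c("tsv", "json"), several.ok = TRUE)
  structure(list(demo_path = demo_path, drug_path = drug_path,
                 reac_path = reac_path, dialect = dialect, sim = sim,
                 builtin_fixture = isTRUE(builtin_fixture),
                 drug_name = drug_name, event_pt = event_pt,
                 stratify = stratify, out_dir = out_dir, format = format,
                 seed = as.integer(seed)),
            class = "run_config")
}

require_query <- function(cfg) {
  if (is.null(cfg$drug_name) || is.null(cfg$event_pt)) {
    stop_pv("pvsignal_validation_error",
            "this command needs drug_name and event_pt")
  }
  coding_query(cfg$drug_name, cfg$event_pt)
}

load_reports <- function(cfg) {
  if (!is.null(cfg$sim)) {
    generate_reports(cfg$sim)$reports
  } else if (cfg$builtin_fixture) {
    stop_pv("pvsignal_validation_error",
            "the builtin fixture carries counts, not reports; use run_signal without a stratifier")
  } else {
    read_reports(cfg$demo_path, cfg$drug_path, cfg$reac_path, cfg$dialect)
  }
}

maybe_write <- function(cfg, stem, df, json_obj = NULL) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  if ("tsv" %in% cfg$format) {
    utils::write.table(df, file.path(cfg$out_dir, paste0(stem, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("json" %in% cfg$format) {
    jsonlite::write_json(if (is.null(json_obj)) df else json_obj,
                         file.path(cfg$out_dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' Simulate a report database and write it to disk
#'
#' Runs the generator in `cfg$sim`, writes the three report tables with
#' [write_reports()], and stores the generator ground truth (expected cell
#' counts, planted ROR, per-sex exposure odds) as a JSON sidecar
#' `truth.json` next to them. Identical configs produce byte-identical
#' output trees.
#'
#' @param cfg a [run_config()] with a `sim` source and an `out_dir`.
#' @return named vector of written paths, invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$sim) || is.null(cfg$out_dir)) {
    stop_pv("pvsignal_validation_error",
            "run_simulate needs a sim source and an out_dir")
  }
  gen <- generate_reports(cfg$sim)
  paths <- write_reports(gen$reports, cfg$out_dir, cfg$dialect)
  truth_path <- file.path(cfg$out_dir, "truth.json")
  jsonlite::write_json(
    list(expected_table = as.list(gen$truth$expected_table),
         true_ror = gen$truth$true_ror,
         exposure_odds = as.list(gen$truth$exposure_odds),
         n_reports = n_reports(gen$reports)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, truth = truth_path))
}

#' Run the disproportionality analysis end to end
#'
#' Loads the configured input, builds the 2x2 table for the query, computes
#' the reporting odds ratio, Yates chi-squared and signal verdict, and —
#' when a stratifier is configured — per-stratum results plus the
#' female-vs-male interaction contrast. With `builtin_fixture = TRUE` the
#' published hydroxychloroquine--pemphigus counts are analyzed directly, so
#' the headline published statistics are reproducible with zero inputs.
#' A query matching no report yields a result row with `n = 0`,
#' `signal = FALSE` and a warning, not an error.
#'
#' @param cfg a [run_config()].
#' @return list with `table`, `result`, and (if stratified) `strata` and
#'   `interaction`; also written to `out_dir` when configured.
#' @export
run_signal <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  q <- require_query(cfg)
  if (cfg$builtin_fixture) {
    if (!is.null(cfg$stratify)) {
      stop_pv("pvsignal_validation_error",
              "the builtin fixture has no report-level strata")
    }
    tab <- hcq_pemphigus_table()
    rs <- NULL
  } else {
    rs <- load_reports(cfg)
    tab <- tabulate_reports(rs, q)
  }
  if (tab$a == 0) {
    warning(sprintf("query %s / %s matches no co-report", q$drug_name,
                    q$event_pt), call. = FALSE)
  }
  # a query matching (almost) nothing yields a degenerate table; report an
  # n = 0 / no-signal row rather than failing the run
  res <- tryCatch(ror_estimate(tab),
                  pvsignal_stat_error = function(e) {
                    structure(list(ror = NA_real_, ci_low = NA_real_,
                                   ci_high = NA_real_, z = NA_real_,
                                   chi2_yates = NA_real_, n = tab$a,
                                   signal = FALSE, correction_applied = FALSE,
                                   table = tab),
                              class = "disprop_result")
                  })
  out <- list(table = tab, result = res)

  rows <- cbind(data.frame(stratum = "ALL"), as.data.frame(res))
  if (!is.null(cfg$stratify)) {
    strat_tabs <- stratify_reports(rs, q, cfg$stratify)
    strat_res <- lapply(strat_tabs, function(t) {
      tryCatch(ror_estimate(t), pvsignal_stat_error = function(e) NULL)
    })
    for (s in names(strat_res)) {
      if (!is.null(strat_res[[s]])) {
        rows <- rbind(rows, cbind(data.frame(stratum = s),
                                  as.data.frame(strat_res[[s]])))
      }
    }
    out$strata <- strat_res
    if (cfg$stratify == "sex" &&
        !is.null(strat_res$FEMALE) && !is.null(strat_res$MALE)) {
      out$interaction <- compare_strata(strat_tabs$FEMALE, strat_tabs$MALE)
    }
  }
  json <- list(query = unclass(q), rows = rows)
  if (!is.null(out$interaction)) {
    json$interaction <- list(ratio_of_ors = out$interaction$ratio_of_ors,
                             log_ratio_se = out$interaction$log_ratio_se,
                             z = out$interaction$z, p = out$interaction$p)
  }
  maybe_write(cfg, "signal", rows, json)
  out
}

#' Yearly trend of the queried drug--event pair
#'
#' @param cfg a [run_config()] with a report-level source.
#' @return the [yearly_trend()] series; when `out_dir` is set, a table with
#'   an explicit `denominator` column is written alongside.
#' @export
run_trend <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  q <- require_query(cfg)
  rs <- load_reports(cfg)
  tr <- yearly_trend(rs, q)
  df <- as.data.frame(tr)
  df$denominator <- rep(attr(tr, "denominator"), nrow(df))
  maybe_write(cfg, "trend", df)
  tr
}
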