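# Single-command orchestration: configuration in, Table-1/Table-2/forest-plot
# style CSV outputs and a run log out.

#' Assemble a pipeline run configuration
#'
#' Either `input_dir` + `quarters` (FAERS ASCII files on disk) or `synthetic`
#' (a [synthetic_config()]) must be supplied.
#'
#' @param input_dir directory holding quarterly files (see [load_quarters()]).
#' @param quarters quarter labels to load.
#' @param synthetic a [synthetic_config()] generating the input instead.
#' @param synonyms drug synonyms of interest.
#' @param roles suspect role codes (default `"PS"`).
#' @param strata age strata to analyze (default pediatric and adult).
#' @param mapping PT-to-SOC mapping `data.table`, or a path readable by
#'   [read_soc_mapping()]; `NULL` with synthetic input uses the vocabulary's
#'   own mapping.
#' @param criteria a [signal_criteria()].
#' @param match_policy name matching policy (see [match_drug_reports()]).
#' @param top_k top-k size for descriptive summaries.
#' @param out_dir output directory for CSVs and `run.log`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, synonyms = c("SEVOFLURANE", "ULTANE",
                                             "SEVORANE"),
                       input_dir = NULL, quarters = NULL, synthetic = NULL,
                       roles = "PS", strata = c("pediatric", "adult"),
                       mapping = NULL, criteria = signal_criteria(),
                       match_policy = "exact", top_k = 10) {
  if (is.null(synthetic) && (is.null(input_dir) || is.null(quarters))) {
    stop("run_config(): supply either input_dir + quarters or a synthetic",
         " config", call. = FALSE)
  }
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- read_soc_mapping(mapping)
  }
  structure(list(out_dir = out_dir, synonyms = synonyms,
                 input_dir = input_dir, quarters = quarters,
                 synthetic = synthetic, roles = roles, strata = strata,
                 mapping = mapping, criteria = criteria,
                 match_policy = match_policy, top_k = top_k),
            class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes load (or synthetic generation), deduplication, per-stratum cohort
#' construction, descriptive summaries, PT- and SOC-level signal evaluation,
#' and — when both pediatric and adult strata are requested — the
#' child-versus-adult comparison. Writes `descriptive_summary_<stratum>.csv`,
#' `signals_pt_<stratum>.csv`, `signals_soc_<stratum>.csv` (ratios printed
#' with 2 decimals, full precision in parallel `*_full.csv` files),
#' `comparison.csv`, `flowchart_counts.csv` and `run.log` under
#' `config$out_dir`. On error, partial outputs are removed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the per-stratum cohorts, summaries and
#'   signal tables, the comparison table, and the flowchart counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  emit <- function(dt, name, round_cols = NULL) {
    path <- file.path(out_dir, name)
    if (!is.null(round_cols)) {
      full_path <- sub("\\.csv$", "_full.csv", path)
      data.table::fwrite(dt, full_path)
      written <<- c(written, full_path)
      dt <- data.table::copy(dt)
      for (cc in intersect(round_cols, names(dt))) {
        dt[, (cc) := round_half_up(get(cc), 2)]
      }
    }
    data.table::fwrite(dt, path)
    written <<- c(written, path)
  }

  ok <- FALSE
  on.exit(if (!ok) {
    unlink(written)
    message("run_pipeline(): failed; partial outputs removed")
  })

  if (!is.null(config$synthetic)) {
    logit("generating synthetic bundle (seed ", config$synthetic$seed, ")")
    gen <- generate_bundle(config$synthetic)
    bundle <- gen$bundle
    if (is.null(config$mapping)) {
      config$mapping <- soc_mapping(config$synthetic$pt_vocabulary)
    }
  } else {
    logit("loading quarters: ", paste(config$quarters, collapse = ", "))
    bundle <- load_quarters(config$input_dir, config$quarters)
  }
  if (is.null(config$mapping)) {
    stop("run_pipeline(): no PT->SOC mapping available", call. = FALSE)
  }
  for (k in c("demo", "drug", "reac", "outc", "indi")) {
    logit(toupper(k), " rows: ", nrow(bundle[[k]]))
  }

  dedup <- deduplicate_reports(bundle$demo)
  logit("deduplication: ", nrow(bundle$demo), " -> ", nrow(dedup),
        " (removed ", attr(dedup, "removed"), ")")

  ratio_cols <- c("ror", "ror_lower", "ror_upper", "prr", "chi2", "ic",
                  "ic025", "ebgm", "ebgm05")
  cohorts <- list(); summaries <- list(); signals <- list()
  flow_rows <- list()
  for (s in config$strata) {
    logit("stratum ", s, ": building cohort")
    coh <- build_cohort(bundle, config$synonyms, config$roles, s,
                        config$match_policy)
    cohorts[[s]] <- coh
    flow_rows[[s]] <- data.table::data.table(
      stratum = s, stage = names(coh$flow), n = as.integer(coh$flow))
    logit("stratum ", s, ": ", coh$n_reports, " reports, ",
          coh$n_report_pt_pairs, " report-PT pairs")
    if (coh$n_reports == 0) next
    summ <- summarize_cohort(coh, k = config$top_k)
    summaries[[s]] <- summ
    emit(summ, paste0("descriptive_summary_", s, ".csv"))
    bg <- stratum_pairs(bundle, s)
    sig <- evaluate_signals(coh, bg, config$mapping, config$criteria)
    signals[[s]] <- sig
    emit(sig[level == "PT"], paste0("signals_pt_", s, ".csv"), ratio_cols)
    emit(sig[level == "SOC"], paste0("signals_soc_", s, ".csv"), ratio_cols)
    logit("stratum ", s, ": ", sum(sig[level == "PT"]$overall_signal),
          " PT signal(s), ", sum(sig[level == "SOC"]$overall_signal),
          " SOC signal(s)")
  }
  emit(data.table::rbindlist(flow_rows), "flowchart_counts.csv")

  comparison <- NULL
  if (all(c("pediatric", "adult") %in% names(cohorts)) &&
      cohorts$pediatric$n_reports > 0 && cohorts$adult$n_reports > 0) {
    comparison <- compare_populations(
      cohorts$pediatric, cohorts$adult,
      signals = list(child = signals$pediatric, adult = signals$adult))
    emit(comparison, "comparison.csv",
         c("ror", "ci_low", "ci_high"))
    logit("comparison: ", nrow(comparison), " PT(s), ",
          sum(comparison$direction != "indeterminate"), " directional")
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(list(cohorts = cohorts, summaries = summaries, signals = signals,
                 comparison = comparison,
                 flow = data.table::rbindlist(flow_rows)))
}
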