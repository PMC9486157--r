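# End-to-end pipeline: read -> dedup -> cohort -> signals -> descriptive.

#' Run the full analysis pipeline over one or more FAERS quarters
#'
#' Executes every stage in order -- archive parsing, FDA-rule
#' deduplication, primary-suspect cohort extraction, unstratified and
#' stratified signal screens, clinical characteristics, serious outcomes,
#' and time-to-onset -- and writes the report tables as CSV plus a
#' flow-count summary (rows read, after dedup, cohort sizes per drug and
#' event) and a metadata record of every threshold and formula variant
#' used. Re-running on the same inputs gives identical outputs.
#'
#' @param quarters character vector of archive directories (one per
#'   quarter), or a list of `"quarter_bundle"` objects.
#' @param labels quarter tags matching `quarters` when directories are
#'   given (e.g. `c("2016Q1", "2016Q2")`).
#' @param out_dir directory for the report bundle (created if needed).
#' @param lexicon,events reference tables, see [load_lexicon()] and
#'   [load_target_events()].
#' @param window optional length-2 `Date` study window applied to `fda_dt`.
#' @param strata stratum specs for the subgroup screen; default: sex (F/M),
#'   age (18-65 / >65) and route (oral / intravenous).
#' @param thresholds signal criteria, see [default_thresholds()].
#' @param histogram_edges day-range edges of the onset histogram.
#' @return invisibly, a list with every computed object (`dedup`,
#'   `cohort`, `universe`, `signals`, `characteristics`, `outcomes`,
#'   `onset`, `onset_summary`, `histogram`, `flow`).
#' @export
run_pipeline <- function(quarters, labels = NULL, out_dir,
                         lexicon = load_lexicon(),
                         events = load_target_events(),
                         window = NULL,
                         strata = default_strata(),
                         thresholds = default_thresholds(),
                         histogram_edges = c(0, 30, 60, 90, 180, 360, Inf)) {
  bundles <- if (is.character(quarters)) {
    if (is.null(labels)) stop("labels required when reading archives")
    Map(function(p, l) {
      tryCatch(read_quarter(p, l),
               error = function(e) stop("stage ingest [", l, "]: ",
                                        conditionMessage(e), call. = FALSE))
    }, quarters, labels)
  } else if (inherits(quarters, "quarter_bundle")) list(quarters)
  else quarters

  merged <- merge_bundles(bundles)
  n_raw <- nrow(merged$demo)
  dd <- tryCatch(dedup_bundle(merged), error = function(e)
    stop("stage dedup: ", conditionMessage(e), call. = FALSE))
  cohort <- tryCatch(
    extract_cohort(dd$bundle, lexicon, events, window),
    error = function(e) stop("stage cohort: ", conditionMessage(e),
                             call. = FALSE))
  universe <- build_universe(dd$bundle, lexicon, events)
  signals <- signal_screen(universe, strata = strata,
                           thresholds = thresholds)
  characteristics <- summarize_characteristics(cohort)
  outcomes <- summarize_outcomes(cohort)
  onset <- compute_onset(cohort)
  pairs_present <- unique(onset$onsets[c("drug", "event")])
  onset_summary <- do.call(rbind, c(lapply(seq_len(nrow(pairs_present)),
    function(i) {
      s <- summarize_onset(onset$onsets, pairs_present$drug[i],
                           pairs_present$event[i])
      cbind(pairs_present[i, , drop = FALSE], as.data.frame(t(s)))
    }), list(make.row.names = FALSE)))
  histogram <- onset_histogram(onset$onsets, histogram_edges)

  cohort_sizes <- lapply(cohort$event_keys, function(ek) {
    p <- cohort_pairs(cohort)
    stats::setNames(
      lapply(cohort$drug_keys, function(dk)
        sum(p$drug == dk & p$event == ek)), cohort$drug_keys)
  })
  names(cohort_sizes) <- cohort$event_keys
  flow <- list(rows_read = n_raw,
               after_dedup = nrow(dd$bundle$demo),
               removed_duplicates = dd$dedup$removed_duplicates,
               removed_deleted = dd$dedup$removed_deleted,
               removed_invalid_date = dd$dedup$removed_invalid_date,
               cohort_reports = nrow(cohort$cases),
               cohort_sizes = cohort_sizes,
               onset_valid = nrow(onset$onsets),
               onset_excluded = as.list(onset$exclusions))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(out_dir, f)
  write_table(characteristics, outp("table1_characteristics.csv"))
  sig <- as.data.frame(signals)
  write_table(sig[sig$stratum_axis == "none", , drop = FALSE],
              outp("table2_signals.csv"))
  write_table(sig[sig$stratum_axis == "route", , drop = FALSE],
              outp("table3_route_signals.csv"))
  write_table(sig, outp("signals_all_strata.csv"))
  write_table(onset_summary, outp("table4_onset.csv"))
  write_table(histogram, outp("figure2_histogram.csv"))
  write_table(outcomes, outp("outcomes.csv"))
  jsonlite::write_json(flow, outp("flowchart_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(thresholds = thresholds, method = .method_metadata(),
         strata = strata,
         window = if (is.null(window)) NULL else as.character(window),
         quarters = vapply(bundles, `[[`, "", "label"),
         quartile_rule = "median-of-halves",
         histogram_edges = histogram_edges),
    outp("metadata.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA,
    null = "null")

  invisible(list(dedup = dd$dedup, bundle = dd$bundle, cohort = cohort,
                 universe = universe, signals = signals,
                 characteristics = characteristics, outcomes = outcomes,
                 onset = onset, onset_summary = onset_summary,
                 histogram = histogram, flow = flow))
}

#' Default subgroup strata
#'
#' Sex (female/male), age bands 18-65 and over-65, and oral/intravenous
#' administration route.
#'
#' @return list of stratum specs for [signal_screen()].
#' @export
default_strata <- function() {
  list(list(axis = "route", level = "oral"),
       list(axis = "route", level = "intravenous"),
       list(axis = "sex", level = "F"),
       list(axis = "sex", level = "M"),
       list(axis = "age_group", level = "18-65"),
       list(axis = "age_group", level = ">65"))
}
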