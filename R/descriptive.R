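# Descriptive surfaces: clinical characteristics, serious outcomes,
# time-to-onset quartiles and histograms.

#' Compute time-to-onset per (report, drug, event)
#'
#' Onset is the calendar-day difference between the adverse-event date
#' (EVENT_DT) and the matched drug's therapy start (START_DT). A record is
#' retained only when both dates parse at day precision and the difference
#' is non-negative; same-day onset is kept as 0 days (only strictly negative
#' intervals are input errors). Exclusions are tallied by reason.
#'
#' @param cohort a `"faers_cohort"` (or a [cohort_pairs()] data.frame).
#' @return list: `onsets` (data.frame caseid, drug, event, onset_days) and
#'   `exclusions` (named counts: `missing`, `partial_precision`,
#'   `negative`). Retained + excluded rows equal the input pair rows.
#' @export
compute_onset <- function(cohort) {
  pairs <- if (inherits(cohort, "faers_cohort")) cohort_pairs(cohort)
           else cohort
  ev <- parse_partial_date(pairs$event_dt)
  st <- parse_partial_date(pairs$start_dt)
  missing <- !nzchar(pairs$event_dt) | !nzchar(pairs$start_dt)
  partial <- !missing & (ev$precision != "day" | st$precision != "day")
  days <- as.integer(ev$date - st$date)
  negative <- !missing & !partial & days < 0L
  keep <- !missing & !partial & !negative
  onsets <- data.frame(caseid = pairs$caseid[keep], drug = pairs$drug[keep],
                       event = pairs$event[keep],
                       onset_days = days[keep], stringsAsFactors = FALSE)
  rownames(onsets) <- NULL
  list(onsets = onsets,
       exclusions = c(missing = sum(missing),
                      partial_precision = sum(partial),
                      negative = sum(negative)))
}

# quartiles by the median-of-halves rule: the lower/upper halves exclude the
# middle element when n is odd, so even-sized halves give half-integer
# quartiles on integer data
.quartiles_moh <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(c(q1 = x, median = x, q3 = x))
  med <- stats::median(x)
  half <- floor(n / 2)
  lower <- x[seq_len(half)]
  upper <- x[seq.int(n - half + 1L, n)]
  c(q1 = stats::median(lower), median = med, q3 = stats::median(upper))
}

#' Summarize onset times for one drug-event pair
#'
#' Quartiles use the median-of-halves rule (median of the lower and upper
#' halves, halves excluding the middle element for odd n), which yields
#' half-integer values on even-sized halves of integer day counts.
#'
#' @param onsets data.frame from [compute_onset()]`$onsets` (or a bare
#'   numeric vector of onset days).
#' @param drug,event optional keys to filter on.
#' @return named numeric vector `n_valid`, `q1`, `median`, `q3`.
#' @examples
#' summarize_onset(c(1, 2, 3, 4))   # q1 1.5, median 2.5, q3 3.5
#' @export
summarize_onset <- function(onsets, drug = NULL, event = NULL) {
  x <- if (is.data.frame(onsets)) {
    keep <- rep(TRUE, nrow(onsets))
    if (!is.null(drug)) keep <- keep & onsets$drug == drug
    if (!is.null(event)) keep <- keep & onsets$event == event
    onsets$onset_days[keep]
  } else as.numeric(onsets)
  if (length(x) == 0L) stop("no valid onset records")
  q <- .quartiles_moh(x)
  c(n_valid = length(x), q)
}

#' Bin onset times into day-range histograms
#'
#' Left-closed, right-open binning: a value t falls in bin i iff
#' `edges[i] <= t < edges[i+1]`. Values outside `[edges[1], edges[last])`
#' are not counted, so choose a final edge (e.g. `Inf`) covering the range
#' when conservation is wanted.
#'
#' @param onsets data.frame from [compute_onset()]`$onsets`.
#' @param edges strictly increasing numeric bin edges.
#' @return data.frame drug, event, bin (label), bin_lo, bin_hi, count.
#' @export
onset_histogram <- function(onsets,
                            edges = c(0, 30, 60, 90, 180, 360, Inf)) {
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  nb <- length(edges) - 1L
  labels <- sprintf("[%s,%s)", edges[-length(edges)], edges[-1L])
  combos <- unique(onsets[c("drug", "event")])
  combos <- combos[order(combos$drug, combos$event), , drop = FALSE]
  if (nrow(combos) == 0L)
    return(data.frame(drug = character(), event = character(),
                      bin = character(), bin_lo = numeric(),
                      bin_hi = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    x <- onsets$onset_days[onsets$drug == combos$drug[i] &
                             onsets$event == combos$event[i]]
    idx <- findInterval(x, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1L & idx <= nb & x < edges[length(edges)]]
    cnt <- tabulate(idx, nbins = nb)
    out[[i]] <- data.frame(drug = combos$drug[i], event = combos$event[i],
                           bin = labels, bin_lo = edges[-length(edges)],
                           bin_hi = edges[-1L], count = cnt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.pct <- function(count, total) {
  if (total == 0) return(rep(0, length(count)))
  round(100 * count / total, 2)
}

.block_counts <- function(values, levels, total, block) {
  cnt <- vapply(levels, function(l) sum(values == l), 0L)
  data.frame(block = block, level = levels, count = as.integer(cnt),
             pct = .pct(cnt, total), stringsAsFactors = FALSE)
}

#' Clinical-characteristics table
#'
#' Per (drug, event) group -- and pooled over all study drugs -- counts and
#' percentages for sex, age bands (with mean harmonized age), indication
#' classes, serious-outcome codes, reporting regions, reporter occupation
#' classes and reporting years. Percentages are `100 * count / group total`
#' rounded to 2 decimals; outcome percentages may sum above 100 because a
#' report can carry several outcome codes. Mean age is computed over
#' harmonized ages only (no imputation).
#'
#' @param cohort a `"faers_cohort"`.
#' @return data.frame of class `"characteristics_table"`: drug, event,
#'   block, level, count, pct (the pooled group uses drug key `"all"`).
#' @export
summarize_characteristics <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  pairs <- cohort_pairs(cohort)
  outc <- cohort$outcomes
  groups <- unique(pairs[c("drug", "event")])
  groups <- groups[order(groups$drug, groups$event), , drop = FALSE]
  pooled <- unique(pairs["event"])
  groups <- rbind(groups,
                  data.frame(drug = "all", event = pooled$event,
                             stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- pairs[pairs$event == groups$event[i] &
                 (groups$drug[i] == "all" | pairs$drug == groups$drug[i]), ,
               drop = FALSE]
    total <- nrow(g)
    blocks <- list(
      data.frame(block = "total", level = "reports", count = total,
                 pct = 100, stringsAsFactors = FALSE),
      .block_counts(g$sex, c("F", "M", "UNK"), total, "sex"),
      .block_counts(g$age_group, c("<18", "18-65", ">65", "unknown"),
                    total, "age_group"),
      data.frame(block = "age", level = "mean_years",
                 count = sum(!is.na(g$age_years)),
                 pct = round(mean(g$age_years, na.rm = TRUE), 2),
                 stringsAsFactors = FALSE),
      .block_counts(g$indication_class,
                    c("infections", "other", "unknown-indication"),
                    total, "indication"),
      {
        oc <- outc[outc$caseid %in% g$caseid, , drop = FALSE]
        .block_counts(oc$outc_cod, .outcome_codes, total, "outcome")
      },
      .block_counts(g$region,
                    c("Africa", "Asia", "Europe", "North America",
                      "Oceania", "South America", "Unknown"),
                    total, "region"),
      .block_counts(g$reporter_class,
                    c("MD", "PH", "HP", "OT", "CN", "LW", "Unknown"),
                    total, "reporter"),
      .block_counts(g$reporting_year, sort(unique(pairs$reporting_year)),
                    total, "reporting_year"))
    blk <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
    out[[i]] <- cbind(data.frame(drug = groups$drug[i],
                                 event = groups$event[i],
                                 stringsAsFactors = FALSE), blk)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("characteristics_table", "data.frame")
  res
}

#' Serious-outcome proportions per drug-event group
#'
#' One count per outcome code (DE, LT, HO, DS, CA, RI, OT) per group; a
#' report carrying several codes contributes to each. The proportion is the
#' count divided by the group's total report count (so proportions can sum
#' above 100%).
#'
#' @param cohort a `"faers_cohort"`.
#' @return data.frame drug, event, outc_cod, count, pct.
#' @export
summarize_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  pairs <- cohort_pairs(cohort)
  outc <- cohort$outcomes
  groups <- unique(pairs[c("drug", "event")])
  groups <- groups[order(groups$drug, groups$event), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- pairs[pairs$drug == groups$drug[i] &
                 pairs$event == groups$event[i], , drop = FALSE]
    oc <- outc[outc$caseid %in% g$caseid, , drop = FALSE]
    cnt <- vapply(.outcome_codes, function(code)
      sum(oc$outc_cod == code), 0L)
    out[[i]] <- data.frame(drug = groups$drug[i], event = groups$event[i],
                           outc_cod = .outcome_codes,
                           count = as.integer(cnt),
                           pct = .pct(cnt, nrow(g)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Most frequent concomitant drugs per drug-event group
#'
#' Simple frequency count of co-reported non-primary-suspect drug names
#' among cohort reports (descriptive only).
#'
#' @param cohort a `"faers_cohort"`.
#' @param bundle the deduplicated `"quarter_bundle"` the cohort came from.
#' @param top number of names to keep per group.
#' @return data.frame drug, event, conc_drugname, count.
#' @export
concomitant_top <- function(cohort, bundle, top = 5L) {
  pairs <- cohort_pairs(cohort)
  dr <- bundle$drug[bundle$drug$role_cod != "PS", , drop = FALSE]
  groups <- unique(pairs[c("drug", "event")])
  groups <- groups[order(groups$drug, groups$event), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(groups))) {
    ids <- pairs$caseid[pairs$drug == groups$drug[i] &
                          pairs$event == groups$event[i]]
    nm <- .norm_drugname(dr$drugname[dr$caseid %in% ids])
    nm <- nm[nzchar(nm)]
    if (length(nm) == 0L) next
    tab <- sort(table(nm), decreasing = TRUE)
    k <- min(top, length(tab))
    out[[length(out) + 1L]] <-
      data.frame(drug = groups$drug[i], event = groups$event[i],
                 conc_drugname = names(tab)[seq_len(k)],
                 count = as.integer(tab[seq_len(k)]),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
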