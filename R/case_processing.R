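# Report deduplication and cohort extraction.
#
# FAERS carries several versions of the same case (one PRIMARYID per
# version). The FDA-recommended rule retains, per CASEID, the version with
# the latest FDA receipt date, breaking ties by the higher PRIMARYID;
# case IDs on the quarterly deleted list are removed afterwards.

# sort key for raw partial dates: pad year/month precision to the period start
.fda_dt_key <- function(raw) {
  p <- parse_partial_date(raw)
  key <- as.numeric(format(p$date, "%Y%m%d"))
  key[p$precision == "invalid"] <- NA_real_
  key
}

#' Deduplicate FAERS reports
#'
#' Applies the FDA-recommended rule on the case level: one retained row per
#' `caseid`, namely the row with the latest `fda_dt` (ties broken by the
#' numerically higher `primaryid`); rows whose `caseid` appears on the
#' deleted-case list are removed last. Rows whose `fda_dt` cannot be parsed
#' to at least year precision are dropped up front and counted. All
#' anomalies are counted outcomes, never errors.
#'
#' @param demo_rows data.frame with at least `primaryid`, `caseid`,
#'   `fda_dt` columns (as from [read_quarter()]; rows from several quarters
#'   may be concatenated before deduplicating).
#' @param deleted character vector of deleted caseids.
#' @return list of class `"dedup_result"`: `kept` (data.frame, one row per
#'   surviving caseid), `removed_duplicates`, `removed_deleted`,
#'   `removed_invalid_date`. Counts and `nrow(kept)` sum to the input rows.
#' @export
deduplicate <- function(demo_rows, deleted = character(0)) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo_rows)))
  n_in <- nrow(demo_rows)
  key <- .fda_dt_key(demo_rows$fda_dt)
  valid <- !is.na(key)
  removed_invalid <- sum(!valid)
  d <- demo_rows[valid, , drop = FALSE]
  key <- key[valid]
  pid <- suppressWarnings(as.numeric(d$primaryid))
  ord <- order(d$caseid, -key, -pid)
  d <- d[ord, , drop = FALSE]
  first <- !duplicated(d$caseid)
  removed_dup <- sum(!first)
  d <- d[first, , drop = FALSE]
  is_deleted <- d$caseid %in% deleted
  removed_deleted <- sum(is_deleted)
  kept <- d[!is_deleted, , drop = FALSE]
  kept <- kept[order(kept$caseid), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(kept = kept,
                 removed_duplicates = removed_dup,
                 removed_deleted = removed_deleted,
                 removed_invalid_date = removed_invalid,
                 n_input = n_in),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(paste0("FAERS deduplication: %d rows in, %d kept ",
                     "(%d duplicate versions, %d deleted cases, ",
                     "%d unparseable dates removed)\n"),
              x$n_input, nrow(x$kept), x$removed_duplicates,
              x$removed_deleted, x$removed_invalid_date))
  invisible(x)
}

# normalize a verbatim drug name: uppercase, trim, strip trailing punctuation
.norm_drugname <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  gsub("[[:space:]]+", " ", x)
}

#' Match a verbatim drug name against the lexicon
#'
#' Matching is exact-token based: the normalized name (uppercased, trimmed,
#' trailing punctuation stripped) must equal a lexicon name, or start with a
#' lexicon name at a word boundary so that dose decorations after the name
#' are ignored (`"CIPRO 500MG TAB"` matches `CIPRO`) while substrings never
#' match (`"CIPROFIBRATE"` does not match `CIPRO`). When `drugname` fails,
#' `prod_ai` (active ingredient) is tried the same way. Deterministic;
#' longer lexicon names take precedence.
#'
#' @param drugname character vector of verbatim drug names.
#' @param prod_ai character vector of active-ingredient strings (same
#'   length, or empty strings).
#' @param lexicon a [load_lexicon()] result.
#' @return character vector of drug keys, `NA` where nothing matches.
#' @export
match_drug <- function(drugname, prod_ai = rep("", length(drugname)),
                       lexicon = load_lexicon()) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  names_flat <- unlist(lexicon, use.names = FALSE)
  keys_flat <- rep(names(lexicon), lengths(lexicon))
  ord <- order(-nchar(names_flat))           # prefer longest name
  names_flat <- names_flat[ord]
  keys_flat <- keys_flat[ord]
  match_one_vec <- function(x) {
    x <- .norm_drugname(x)
    out <- rep(NA_character_, length(x))
    for (i in seq_along(names_flat)) {
      nm <- names_flat[i]
      todo <- is.na(out) & startsWith(x, nm)
      if (!any(todo)) next
      nxt <- substr(x[todo], nchar(nm) + 1L, nchar(nm) + 1L)
      hit <- nxt == "" | !grepl("[A-Z0-9]", nxt)
      out[todo][hit] <- keys_flat[i]
    }
    out
  }
  res <- match_one_vec(drugname)
  miss <- is.na(res) & nzchar(prod_ai)
  if (any(miss)) res[miss] <- match_one_vec(prod_ai[miss])
  res
}

#' Classify a verbatim administration route
#'
#' @param route character vector of verbatim FAERS route strings.
#' @return character vector with levels `oral`, `intravenous`, `other`,
#'   `unknown` (empty input).
#' @export
classify_route <- function(route) {
  r <- tolower(trimws(route))
  iv <- c("intravenous", "intravenous (not otherwise specified)",
          "intravenous drip", "intravenous bolus")
  out <- rep("other", length(r))
  out[r == "oral"] <- "oral"
  out[r %in% iv] <- "intravenous"
  out[!nzchar(r)] <- "unknown"
  out
}

# precedence for conflicting routes across a report's matched PS rows
.route_precedence <- c(oral = 1L, intravenous = 2L, other = 3L, unknown = 4L)

#' Harmonize reported age to years
#'
#' FAERS ages carry a unit code: years (YR), decades (DEC), months (MON),
#' weeks (WK), days (DY) or hours (HR). A present value with a missing or
#' unknown unit is treated as years; results outside \[0, 120\] years are
#' set missing.
#'
#' @param age numeric vector (or character coercible to numeric).
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years (`NA` = missing).
#' @export
harmonize_age <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(age_cod))
  fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.143,
           DY = 1 / 365.25, HR = 1 / 8766)
  f <- ifelse(unit %in% names(fac), fac[unit], 1)   # unknown unit -> years
  yrs <- a * f
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

#' Assign age bands
#'
#' Bands follow the study's reporting convention: under 18, 18 to 65
#' inclusive, over 65, unknown.
#'
#' @param age_years numeric vector of harmonized ages.
#' @return character vector with levels `<18`, `18-65`, `>65`, `unknown`.
#' @export
age_group <- function(age_years) {
  out <- rep("unknown", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years <= 65] <- "18-65"
  out[!is.na(age_years) & age_years > 65] <- ">65"
  out
}

#' Map reporter country to reporting region
#'
#' @param country character vector of verbatim FAERS country strings
#'   (ISO-3166 two-letter codes or spelled-out names).
#' @param table country/region lookup, default [country_region_table()].
#' @return character vector of regions (`Africa`, `Asia`, `Europe`,
#'   `North America`, `Oceania`, `South America`, `Unknown`).
#' @export
map_region <- function(country, table = country_region_table()) {
  key <- toupper(trimws(country))
  idx <- match(key, toupper(table$country))
  out <- table$region[idx]
  out[is.na(out) | !nzchar(key)] <- "Unknown"
  out
}

#' Classify a drug indication PT
#'
#' @param indi_pt character vector of indication Preferred Terms.
#' @param infection_pts uppercase PT names counted as infections in addition
#'   to any PT containing the token INFECTION.
#' @return character vector with levels `infections`, `other`,
#'   `unknown-indication`.
#' @export
classify_indication <- function(indi_pt, infection_pts = infection_pt_list()) {
  pt <- toupper(trimws(indi_pt))
  out <- rep("other", length(pt))
  out[grepl("INFECTION", pt) | pt %in% infection_pts] <- "infections"
  out[pt == "PRODUCT USED FOR UNKNOWN INDICATION" | !nzchar(pt)] <-
    "unknown-indication"
  out
}

#' Apply deduplication to a whole quarter bundle
#'
#' Deduplicates the DEMO table (see [deduplicate()]) and restricts the other
#' five tables to the retained report versions.
#'
#' @param bundle a `"quarter_bundle"` (or several bundles merged with
#'   [merge_bundles()]).
#' @return list: `bundle` (the filtered `"quarter_bundle"`) and `dedup`
#'   (the `"dedup_result"`).
#' @export
dedup_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  dd <- deduplicate(bundle$demo, bundle$deleted_caseids)
  keep_ids <- dd$kept$primaryid
  out <- bundle
  out$demo <- dd$kept
  for (type in c("drug", "reac", "outc", "ther", "indi"))
    out[[type]] <- out[[type]][out[[type]]$primaryid %in% keep_ids, ,
                               drop = FALSE]
  list(bundle = out, dedup = dd)
}

#' Merge several quarter bundles into one
#'
#' @param bundles list of `"quarter_bundle"` objects.
#' @return one `"quarter_bundle"` whose tables are the row-concatenation of
#'   the inputs (deduplication across quarters is then done by
#'   [dedup_bundle()]).
#' @export
merge_bundles <- function(bundles) {
  if (inherits(bundles, "quarter_bundle")) return(bundles)
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, inherits, TRUE, "quarter_bundle")))
  out <- bundles[[1L]]
  for (type in c("demo", "drug", "reac", "outc", "ther", "indi"))
    out[[type]] <- do.call(rbind, c(lapply(bundles, `[[`, type),
                                    list(make.row.names = FALSE)))
  out$deleted_caseids <- unique(unlist(lapply(bundles, `[[`,
                                              "deleted_caseids")))
  out$label <- paste(vapply(bundles, `[[`, "", "label"), collapse = "+")
  out$log <- do.call(rbind, c(lapply(bundles, `[[`, "log"),
                              list(make.row.names = FALSE)))
  out
}

# per-report study-drug flags and route classes on the deduplicated universe
.report_drug_flags <- function(drug_tab, keep_ids, lexicon) {
  d <- drug_tab[drug_tab$primaryid %in% keep_ids & drug_tab$role_cod == "PS", ,
                drop = FALSE]
  d$drug_key <- match_drug(d$drugname, d$prod_ai, lexicon)
  d <- d[!is.na(d$drug_key), , drop = FALSE]
  d$route_class <- classify_route(d$route)
  d
}

#' Extract the analysis cohort
#'
#' A report enters the cohort iff (i) at least one of its DRUG rows has role
#' code PS (primary suspect) and matches the study-drug lexicon, and (ii) at
#' least one REAC Preferred Term equals a target-event PT (name equality,
#' case-insensitive). One case record is emitted per report; a report with
#' both target PTs carries both event keys, and a report with several
#' matched PS drugs carries one drug row per matched drug key.
#'
#' Therapy start for a matched drug is taken from the THER row whose
#' `dsg_drug_seq` equals that drug's `drug_seq` (the earliest start when
#' several PS rows match). Conflicting routes across a drug's PS rows are
#' resolved by the precedence oral > intravenous > other > unknown. The
#' indication class comes from the INDI row of the matched drug.
#'
#' @param bundle a deduplicated `"quarter_bundle"` (from [dedup_bundle()]).
#' @param lexicon a [load_lexicon()] result.
#' @param events a [load_target_events()] result.
#' @param window optional length-2 `Date` vector; reports whose `fda_dt`
#'   falls outside it are excluded.
#' @return object of class `"faers_cohort"`: list with
#'   \describe{
#'     \item{cases}{one row per report: caseid, primaryid, sex, age_years,
#'       age_group, region, reporter_class, reporting_year, event_dt raw,
#'       plus one logical `has_<event_key>` column per target event.}
#'     \item{drugs}{one row per (report, matched drug key): caseid, drug,
#'       route, drug_seq, start_dt raw, indication_class.}
#'     \item{outcomes}{caseid, outc_cod (one row per code per report).}
#'     \item{event_keys, drug_keys}{the key sets screened.}
#'   }
#' @export
extract_cohort <- function(bundle, lexicon = load_lexicon(),
                           events = load_target_events(), window = NULL) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  demo <- bundle$demo
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    fd <- parse_partial_date(demo$fda_dt)$date
    demo <- demo[!is.na(fd) & fd >= window[1L] & fd <= window[2L], ,
                 drop = FALSE]
  }
  keep_ids <- demo$primaryid

  ps <- .report_drug_flags(bundle$drug, keep_ids, lexicon)

  reac <- bundle$reac[bundle$reac$primaryid %in% keep_ids, , drop = FALSE]
  reac$event_key <- events$event_key[match(toupper(trimws(reac$pt)),
                                           toupper(events$pt_name))]
  reac <- reac[!is.na(reac$event_key), , drop = FALSE]

  hit_ids <- intersect(unique(ps$primaryid), unique(reac$primaryid))
  demo <- demo[demo$primaryid %in% hit_ids, , drop = FALSE]

  # per-report event flags
  cases <- data.frame(caseid = demo$caseid, primaryid = demo$primaryid,
                      sex = ifelse(nzchar(demo$sex), demo$sex, "UNK"),
                      stringsAsFactors = FALSE)
  cases$age_years <- harmonize_age(demo$age, demo$age_cod)
  cases$age_group <- age_group(cases$age_years)
  country <- ifelse(nzchar(demo$occr_country), demo$occr_country,
                    demo$reporter_country)
  cases$region <- map_region(country)
  cases$reporter_class <- ifelse(nzchar(demo$occp_cod), demo$occp_cod,
                                 "Unknown")
  cases$event_dt <- demo$event_dt
  cases$fda_dt <- demo$fda_dt
  cases$reporting_year <- substr(demo$fda_dt, 1L, 4L)
  for (ek in events$event_key)
    cases[[paste0("has_", ek)]] <-
      cases$primaryid %in% reac$primaryid[reac$event_key == ek]

  # per-(report, drug key) rows with route precedence + earliest therapy start
  ps <- ps[ps$primaryid %in% hit_ids, , drop = FALSE]
  ther <- bundle$ther[bundle$ther$primaryid %in% hit_ids, , drop = FALSE]
  ps$start_dt <- ther$start_dt[match(paste(ps$primaryid, ps$drug_seq),
                                     paste(ther$primaryid,
                                           ther$dsg_drug_seq))]
  ps$start_dt[is.na(ps$start_dt)] <- ""
  indi <- bundle$indi[bundle$indi$primaryid %in% hit_ids, , drop = FALSE]
  ps$indi_pt <- indi$indi_pt[match(paste(ps$primaryid, ps$drug_seq),
                                   paste(indi$primaryid,
                                         indi$indi_drug_seq))]
  ps$indi_pt[is.na(ps$indi_pt)] <- ""

  grp <- paste(ps$caseid, ps$drug_key, sep = "\r")
  ord <- order(grp, .route_precedence[ps$route_class],
               .fda_dt_key(ps$start_dt), suppressWarnings(as.integer(ps$drug_seq)))
  ps_o <- ps[ord, , drop = FALSE]
  grp_o <- grp[ord]
  first <- !duplicated(grp_o)
  # earliest parseable therapy start across the group's rows
  start_key <- .fda_dt_key(ps_o$start_dt)
  best_start <- tapply(seq_len(nrow(ps_o)), grp_o, function(ii) {
    k <- start_key[ii]
    if (all(is.na(k))) ps_o$start_dt[ii[1L]] else ps_o$start_dt[ii[which.min(k)]]
  })
  drugs <- data.frame(caseid = ps_o$caseid[first],
                      drug = ps_o$drug_key[first],
                      route = ps_o$route_class[first],
                      drug_seq = ps_o$drug_seq[first],
                      stringsAsFactors = FALSE)
  drugs$start_dt <- as.character(best_start[grp_o[first]])
  drugs$indication_class <- classify_indication(ps_o$indi_pt[first])
  drugs <- drugs[order(drugs$caseid, drugs$drug), , drop = FALSE]
  rownames(drugs) <- NULL
  cases <- cases[order(cases$caseid), , drop = FALSE]
  rownames(cases) <- NULL

  outc <- bundle$outc[bundle$outc$primaryid %in% hit_ids,
                      c("caseid", "outc_cod"), drop = FALSE]
  outc <- unique(outc)
  rownames(outc) <- NULL

  structure(list(cases = cases, drugs = drugs, outcomes = outc,
                 event_keys = events$event_key,
                 drug_keys = names(lexicon)),
            class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("FAERS cohort: %d reports, %d (report, drug) pairs\n",
              nrow(x$cases), nrow(x$drugs)))
  for (ek in x$event_keys)
    cat(sprintf("  %-15s %d reports\n", ek,
                sum(x$cases[[paste0("has_", ek)]])))
  invisible(x)
}

#' Expand a cohort to (report, drug, event) rows
#'
#' Convenience long view used by the descriptive and onset analyses: one row
#' per report, matched drug key and target event carried by the report, with
#' the case-level demographics joined on.
#'
#' @param cohort a `"faers_cohort"`.
#' @return data.frame with columns caseid, drug, event, route, start_dt,
#'   indication_class plus the case columns.
#' @export
cohort_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  out <- list()
  for (ek in cohort$event_keys) {
    has <- cohort$cases[[paste0("has_", ek)]]
    ca <- cohort$cases[has, c("caseid", "sex", "age_years", "age_group",
                              "region", "reporter_class", "event_dt",
                              "reporting_year"), drop = FALSE]
    dr <- cohort$drugs[cohort$drugs$caseid %in% ca$caseid, , drop = FALSE]
    m <- merge(dr, ca, by = "caseid")
    if (nrow(m) > 0L) m$event <- ek
    out[[ek]] <- m
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$drug, out$event, out$caseid), , drop = FALSE]
}
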