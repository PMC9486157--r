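# Synthetic FAERS quarter generator.
#
# Emulates the relational structure of a FAERS quarterly package -- reports
# keyed by PRIMARYID/CASEID, multiple drug rows with role codes and routes,
# multiple reaction PTs, outcome codes, therapy start dates, cross-CASEID
# duplicates, partial dates -- with controlled statistical structure:
# background drug/event marginals (Zipf), planted disproportionality
# signals with a relative reporting rate lambda, and a log-normal
# time-to-onset model. Every report samples its own drug and event sets,
# so dedup, PS-role logic and onset analysis see realistic report-level
# structure.
#
# Sampling scheme (the basis of expected_contingency): each report draws
# one primary-suspect drug from the pool marginal p_drug; each target event
# e is then included independently with probability min(1, lambda * p_e),
# where lambda > 1 only for the report's PS drug's planted pairs; background
# events are drawn separately (1-3 per report, Zipf marginal), so target-
# pair cell expectations are exact closed forms.

.study_drugs <- c("ciprofloxacin", "levofloxacin", "moxifloxacin")
.study_names <- list(
  ciprofloxacin = c("CIPROFLOXACIN", "CIPRO", "CIPROFLOXACIN HYDROCHLORIDE"),
  levofloxacin = c("LEVOFLOXACIN", "LEVAQUIN"),
  moxifloxacin = c("MOXIFLOXACIN", "AVELOX", "VIGAMOX"))
.target_pts <- c(tendonitis = "Tendonitis", tendon_rupture = "Tendon rupture")

#' Describe one planted disproportionality signal
#'
#' @param drug study-drug key.
#' @param event target-event key.
#' @param lambda relative reporting-rate multiplier (>= 1) applied to the
#'   event's background probability among reports exposed to `drug`.
#' @param route_bias fraction of exposed reports administered orally
#'   (the remainder is mostly intravenous).
#' @param onset_median_days,onset_sdlog log-normal time-to-onset model for
#'   the exposed reports (median in days, dispersion on the log scale).
#' @return list of class `"planted_signal"`.
#' @export
planted_signal <- function(drug, event, lambda, route_bias = 0.9,
                           onset_median_days = 5, onset_sdlog = 1.2) {
  stopifnot(lambda >= 1, route_bias >= 0, route_bias <= 1,
            onset_median_days > 0, onset_sdlog > 0)
  structure(list(drug = drug, event = event, lambda = lambda,
                 route_bias = route_bias,
                 onset_median_days = onset_median_days,
                 onset_sdlog = onset_sdlog),
            class = "planted_signal")
}

# defaults emulate the study conditions: three fluoroquinolones with strong
# planted tendon signals, onset medians per the reported quartile table
.default_planted <- function() list(
  planted_signal("ciprofloxacin", "tendonitis", 50, 0.9, 3, 1.2),
  planted_signal("ciprofloxacin", "tendon_rupture", 30, 0.9, 5.5, 1.2),
  planted_signal("levofloxacin", "tendonitis", 45, 0.9, 4, 1.2),
  planted_signal("levofloxacin", "tendon_rupture", 40, 0.9, 3, 1.2),
  planted_signal("moxifloxacin", "tendonitis", 25, 0.9, 16.5, 1.2),
  planted_signal("moxifloxacin", "tendon_rupture", 15, 0.9, 18, 1.2))

#' Configuration of the synthetic quarter generator
#'
#' Defaults are chosen once to mirror the study's reporting structure:
#' study-drug exposure of a few per thousand reports, tendon-event
#' background rates of a few per thousand, ~54% female, age bands
#' 1/60/20/19% (under 18 / 18-65 / over 65 / unknown), ~90% oral routes on
#' exposed reports, a 10% duplicate-version rate resolvable by the FDA
#' dedup rule, and 15% of event dates truncated to month precision to
#' exercise the onset exclusion rules.
#'
#' @param n_reports number of distinct cases to generate.
#' @param n_background_drugs,n_background_events background pool sizes.
#' @param zipf_exponent exponent of the Zipf frequency marginals of the
#'   background pools.
#' @param drug_probs named per-report primary-suspect probabilities of the
#'   study drugs; background drugs share the remaining mass by Zipf weight.
#' @param event_probs named background inclusion probabilities of the
#'   target events.
#' @param planted list of [planted_signal()] objects.
#' @param duplicate_rate fraction of cases emitted twice (same caseid,
#'   later fda_dt, higher primaryid).
#' @param deleted_rate fraction of caseids put on the deleted-case list.
#' @param partial_date_rate fraction of event dates truncated to month
#'   precision.
#' @param missing_event_dt,missing_start_dt fractions of reports with the
#'   respective date absent.
#' @param sex_probs,age_band_probs,country_probs,occp_probs demographic
#'   mixtures (named probability vectors).
#' @param outcome_probs named per-code outcome probabilities applied to
#'   reports carrying a target event (others get a sparser default).
#' @param seed RNG seed (integer below 2^31).
#' @return validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_reports = 5000,
                         n_background_drugs = 20,
                         n_background_events = 60,
                         zipf_exponent = 1.2,
                         drug_probs = c(ciprofloxacin = 0.010,
                                        levofloxacin = 0.009,
                                        moxifloxacin = 0.004),
                         event_probs = c(tendonitis = 0.004,
                                         tendon_rupture = 0.0025),
                         planted = .default_planted(),
                         duplicate_rate = 0.10,
                         deleted_rate = 0.005,
                         partial_date_rate = 0.15,
                         missing_event_dt = 0.20,
                         missing_start_dt = 0.20,
                         sex_probs = c(F = 0.54, M = 0.37, UNK = 0.09),
                         age_band_probs = c("<18" = 0.01, "18-65" = 0.60,
                                            ">65" = 0.20, unknown = 0.19),
                         country_probs = c(US = 0.45, FR = 0.12, GB = 0.09,
                                           DE = 0.08, CA = 0.05, IT = 0.04,
                                           ES = 0.04, JP = 0.04, AU = 0.03,
                                           BR = 0.03, CN = 0.02, ZA = 0.01),
                         occp_probs = c(CN = 0.56, MD = 0.12, OT = 0.14,
                                        HP = 0.06, PH = 0.04, LW = 0.003,
                                        Unknown = 0.077),
                         outcome_probs = c(DS = 0.45, HO = 0.20, OT = 0.55,
                                           LT = 0.02, DE = 0.005,
                                           RI = 0.01, CA = 0.001),
                         seed = 20160101) {
  rates <- c(duplicate_rate, deleted_rate, partial_date_rate,
             missing_event_dt, missing_start_dt)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_reports < 1) stop("n_reports must be >= 1")
  stopifnot(all(drug_probs >= 0), sum(drug_probs) < 1,
            all(event_probs > 0), all(event_probs < 1),
            all(vapply(planted, inherits, TRUE, "planted_signal")))
  for (p in planted)
    if (!(p$event %in% names(event_probs)))
      stop("planted event has no background probability: ", p$event)
  structure(list(
    n_reports = as.integer(n_reports),
    n_background_drugs = as.integer(n_background_drugs),
    n_background_events = as.integer(n_background_events),
    zipf_exponent = zipf_exponent, drug_probs = drug_probs,
    event_probs = event_probs, planted = planted,
    duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
    partial_date_rate = partial_date_rate,
    missing_event_dt = missing_event_dt,
    missing_start_dt = missing_start_dt,
    sex_probs = sex_probs, age_band_probs = age_band_probs,
    country_probs = country_probs, occp_probs = occp_probs,
    outcome_probs = outcome_probs, seed = as.integer(seed)),
    class = "synth_config")
}

# full PS-drug marginal: study drugs + Zipf background pool
.drug_marginal <- function(config) {
  bg_w <- (seq_len(config$n_background_drugs))^(-config$zipf_exponent)
  bg_p <- bg_w / sum(bg_w) * (1 - sum(config$drug_probs))
  names(bg_p) <- sprintf("bg_drug_%02d", seq_len(config$n_background_drugs))
  c(config$drug_probs, bg_p)
}

.lambda_for <- function(config, drug, event) {
  for (p in config$planted)
    if (p$drug == drug && p$event == event) return(p$lambda)
  1
}

.planted_for <- function(config, drug, event) {
  for (p in config$planted)
    if (p$drug == drug && p$event == event) return(p)
  NULL
}

#' Closed-form expected contingency cells under the generator
#'
#' For a (pool drug, target event) pair: with per-report PS probability
#' `p_d` and effective event probability `q_e(d') = min(1, lambda(d', e)
#' p_e)`, the deduplicated universe of `N = n_reports` cases has
#' `E[a] = N p_d q_e(d)`, `E[b] = N p_d (1 - q_e(d))`,
#' `E[c] = N sum_{d' != d} p_d' q_e(d')` and `E[d] = N - E[a+b+c]`.
#' Used by the generator's calibration tests.
#'
#' @param config a [synth_config()].
#' @param drug a study-drug or background-drug key (`bg_drug_01`...).
#' @param event a target-event key.
#' @return named numeric vector `a`, `b`, `c`, `d`.
#' @export
expected_contingency <- function(config, drug, event) {
  stopifnot(inherits(config, "synth_config"))
  pd <- .drug_marginal(config)
  if (!(drug %in% names(pd))) stop("unknown drug key: ", drug)
  if (!(event %in% names(config$event_probs)))
    stop("expected_contingency covers target events only, not: ", event)
  pe <- config$event_probs[[event]]
  q <- vapply(names(pd), function(d2)
    min(1, .lambda_for(config, d2, event) * pe), 0)
  N <- config$n_reports
  a <- N * pd[[drug]] * q[[drug]]
  b <- N * pd[[drug]] * (1 - q[[drug]])
  cc <- N * sum(pd[names(pd) != drug] * q[names(pd) != drug])
  c(a = a, b = b, c = cc, d = N - a - b - cc)
}

.quarter_dates <- function(label) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", label))
  yr <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", yr, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

.sample_cat <- function(n, probs) {
  probs <- probs / sum(probs)
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

.fmt_dt <- function(d) format(d, "%Y%m%d")

#' Generate one synthetic FAERS quarter
#'
#' Draws `n_reports` cases under the scheme described in
#' [expected_contingency()], emits duplicate report versions and a
#' deleted-case list, assembles the six FAERS tables in memory, and (when
#' `out_dir` is given) writes them in the exact `$`-delimited dialect that
#' [read_quarter()] parses (`DEMO16Q1.txt`, ..., `DELETED16Q1.txt`).
#' Identical config and seed give byte-identical files.
#'
#' @param config a [synth_config()].
#' @param label quarter tag, e.g. `"2016Q1"` (sets the date window).
#' @param out_dir optional directory to write the archive into (created if
#'   needed).
#' @return the `"quarter_bundle"`, invisibly when `out_dir` is given.
#' @export
generate_quarter <- function(config, label, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  qd <- .quarter_dates(label)
  n_days <- as.integer(qd[2] - qd[1]) + 1L
  N <- config$n_reports
  pd <- .drug_marginal(config)
  bg_events <- sprintf("Background PT %03d", seq_len(config$n_background_events))
  bg_w <- (seq_len(config$n_background_events))^(-config$zipf_exponent)
  bg_drug_names <- toupper(gsub("_", " ", names(pd)[-seq_along(config$drug_probs)]))
  names(bg_drug_names) <- names(pd)[-seq_along(config$drug_probs)]

  # caseids are unique across quarters (prefix from the quarter tag), as in
  # FAERS itself; versions of one case share the caseid
  caseid <- sprintf("%s%s%07d", substr(label, 3, 4), substr(label, 6, 6),
                    seq_len(N))
  primaryid <- paste0(caseid, "1")
  fda_off <- sample.int(n_days, N, replace = TRUE) - 1L
  fda_dt <- .fmt_dt(qd[1] + fda_off)
  sex <- .sample_cat(N, config$sex_probs)
  band <- .sample_cat(N, config$age_band_probs)
  age <- character(N); age_cod <- character(N)
  b1 <- band == "<18"
  age[b1] <- as.character(sample.int(17, sum(b1), replace = TRUE))
  b2 <- band == "18-65"
  age[b2] <- as.character(17 + sample.int(48, sum(b2), replace = TRUE))
  b3 <- band == ">65"
  age[b3] <- as.character(65 + sample.int(35, sum(b3), replace = TRUE))
  age_cod[band != "unknown"] <- "YR"
  # a few infant ages reported in months to exercise unit harmonization
  inf_mon <- b1 & stats::runif(N) < 0.2
  age[inf_mon] <- as.character(sample.int(17, sum(inf_mon), replace = TRUE))
  age_cod[inf_mon] <- "MON"
  country <- .sample_cat(N, config$country_probs)
  occp <- .sample_cat(N, config$occp_probs)
  occp[occp == "Unknown"] <- ""

  ps_drug <- .sample_cat(N, pd)
  is_study <- ps_drug %in% .study_drugs

  # target-event inclusion: independent Bernoulli with planted lambda boost
  has_ev <- matrix(FALSE, N, length(config$event_probs),
                   dimnames = list(NULL, names(config$event_probs)))
  for (ek in names(config$event_probs)) {
    q <- vapply(names(pd), function(d2)
      min(1, .lambda_for(config, d2, ek) * config$event_probs[[ek]]), 0)
    has_ev[, ek] <- stats::runif(N) < q[ps_drug]
  }
  any_target <- rowSums(has_ev) > 0

  # therapy start and event dates; log-normal onset for target-event reports
  start_date <- qd[1] + (sample.int(n_days, N, replace = TRUE) - 1L)
  start_dt <- .fmt_dt(start_date)
  start_dt[stats::runif(N) < config$missing_start_dt] <- ""
  onset_med <- rep(5, N); onset_sd <- rep(1.2, N)
  for (p in config$planted) {
    hit <- ps_drug == p$drug & has_ev[, p$event]
    onset_med[hit] <- p$onset_median_days
    onset_sd[hit] <- p$onset_sdlog
  }
  delay <- round(stats::rlnorm(N, log(onset_med), onset_sd))
  event_date <- start_date + delay
  event_dt <- ifelse(any_target, .fmt_dt(event_date),
                     ifelse(stats::runif(N) < 0.5,
                            .fmt_dt(qd[1] + (sample.int(n_days, N,
                                                        replace = TRUE) - 1L)),
                            ""))
  event_dt[stats::runif(N) < config$missing_event_dt] <- ""
  trunc6 <- nzchar(event_dt) & stats::runif(N) < config$partial_date_rate
  event_dt[trunc6] <- substr(event_dt[trunc6], 1, 6)

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fda_dt, event_dt = event_dt, age = age,
                     age_cod = age_cod, sex = sex, occp_cod = occp,
                     reporter_country = country, occr_country = country,
                     rept_dt = fda_dt, stringsAsFactors = FALSE)

  # DRUG rows: PS row (seq 1) + 0-2 concomitants
  route <- rep("", N)
  study_route <- .sample_cat(N, c(oral = 0.85, iv = 0.10, other = 0.03,
                                  unknown = 0.02))
  for (p in config$planted) {
    hit <- ps_drug == p$drug & has_ev[, p$event]
    study_route[hit] <- ifelse(stats::runif(sum(hit)) < p$route_bias,
                               "oral", "iv")
  }
  route[is_study] <- c(oral = "Oral", iv = "Intravenous drip",
                       other = "Topical",
                       unknown = "")[study_route[is_study]]
  route[!is_study] <- .sample_cat(sum(!is_study),
                                  stats::setNames(c(0.5, 0.3, 0.2),
                                                  c("Oral", "", "Topical")))
  ps_name <- character(N)
  for (dk in .study_drugs) {
    idx <- which(ps_drug == dk)
    nm <- sample(.study_names[[dk]], length(idx), replace = TRUE)
    dec <- stats::runif(length(idx)) < 0.3
    nm[dec] <- paste(nm[dec], "500MG TABLET")
    ps_name[idx] <- nm
  }
  ps_name[!is_study] <- bg_drug_names[ps_drug[!is_study]]
  prod_ai <- ifelse(is_study, toupper(ps_drug), "")

  n_conc <- sample(0:2, N, replace = TRUE)
  conc_rep <- rep(seq_len(N), n_conc)
  conc_drug <- .sample_cat(length(conc_rep), pd)
  conc_name <- ifelse(conc_drug %in% .study_drugs,
                      toupper(conc_drug), bg_drug_names[conc_drug])
  drug <- rbind(
    data.frame(primaryid = primaryid, caseid = caseid, drug_seq = "1",
               role_cod = "PS", drugname = ps_name, prod_ai = prod_ai,
               route = route, dose_vbm = "", dechal = "", rechal = "",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[conc_rep], caseid = caseid[conc_rep],
               drug_seq = as.character(1L + sequence(n_conc[n_conc > 0])),
               role_cod = "C", drugname = conc_name, prod_ai = "",
               route = "", dose_vbm = "", dechal = "", rechal = "",
               stringsAsFactors = FALSE))
  drug <- drug[order(as.integer(drug$caseid),
                     as.integer(drug$drug_seq)), , drop = FALSE]

  # REAC rows: target events + 1-3 background PTs
  n_bg_ev <- sample(1:3, N, replace = TRUE)
  reac_list <- vector("list", N)
  for (i in seq_len(N)) {
    pts <- .target_pts[has_ev[i, ]]
    bg <- sample(bg_events, n_bg_ev[i], prob = bg_w)
    reac_list[[i]] <- c(pts, bg)
  }
  n_pts <- lengths(reac_list)
  reac <- data.frame(primaryid = rep(primaryid, n_pts),
                     caseid = rep(caseid, n_pts),
                     pt = unlist(reac_list, use.names = FALSE),
                     stringsAsFactors = FALSE)

  # OUTC rows: richer code set on target-event reports
  bg_outc <- c(OT = 0.30, HO = 0.15, DE = 0.01)
  outc_list <- vector("list", N)
  for (i in seq_len(N)) {
    pr <- if (any_target[i]) config$outcome_probs else bg_outc
    codes <- names(pr)[stats::runif(length(pr)) < pr]
    outc_list[[i]] <- codes
  }
  n_oc <- lengths(outc_list)
  outc <- data.frame(primaryid = rep(primaryid, n_oc),
                     caseid = rep(caseid, n_oc),
                     outc_cod = unlist(outc_list, use.names = FALSE),
                     stringsAsFactors = FALSE)

  ther <- data.frame(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = "1", start_dt = start_dt, end_dt = "",
                     stringsAsFactors = FALSE)
  ther <- ther[nzchar(ther$start_dt), , drop = FALSE]

  indi_pool_study <- c("Urinary tract infection" = 0.5, "Pneumonia" = 0.2,
                       "Product used for unknown indication" = 0.15,
                       "Osteoarthritis" = 0.15)
  indi_pool_bg <- c("Hypertension" = 0.4, "Pneumonia" = 0.2,
                    "Product used for unknown indication" = 0.4)
  indi_pt <- character(N)
  indi_pt[is_study] <- .sample_cat(sum(is_study), indi_pool_study)
  indi_pt[!is_study] <- .sample_cat(sum(!is_study), indi_pool_bg)
  indi <- data.frame(primaryid = primaryid, caseid = caseid,
                     indi_drug_seq = "1", indi_pt = indi_pt,
                     stringsAsFactors = FALSE)

  # duplicate versions: same caseid, higher primaryid, later fda_dt;
  # all child-table rows are re-emitted under the new primaryid
  dup <- stats::runif(N) < config$duplicate_rate
  if (any(dup)) {
    di <- which(dup)
    demo2 <- demo[di, , drop = FALSE]
    demo2$primaryid <- paste0(caseid[di], "2")
    demo2$fda_dt <- .fmt_dt(qd[1] + fda_off[di] +
                              sample.int(60, length(di), replace = TRUE))
    demo2$rept_dt <- demo2$fda_dt
    clone <- function(tab) {
      t2 <- tab[tab$primaryid %in% primaryid[di], , drop = FALSE]
      t2$primaryid <- paste0(t2$caseid, "2")
      t2
    }
    demo <- rbind(demo, demo2)
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    ther <- rbind(ther, clone(ther))
    indi <- rbind(indi, clone(indi))
  }
  ord_tab <- function(tab) {
    tab <- tab[order(tab$primaryid), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  demo <- ord_tab(demo); drug <- ord_tab(drug); reac <- ord_tab(reac)
  outc <- ord_tab(outc); ther <- ord_tab(ther); indi <- ord_tab(indi)

  deleted <- caseid[stats::runif(N) < config$deleted_rate]

  bundle <- structure(list(demo = demo, drug = drug, reac = reac,
                           outc = outc, ther = ther, indi = indi,
                           deleted_caseids = deleted, label = label,
                           log = NULL),
                      class = "quarter_bundle")
  if (!is.null(out_dir)) {
    .write_quarter_files(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

# write the six tables + deleted list in the FAERS "$" dialect
.write_quarter_files <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- paste0(substr(bundle$label, 3, 4), substr(bundle$label, 5, 6))
  for (type in names(.faers_schema)) {
    tab <- bundle[[type]]
    path <- file.path(out_dir, paste0(toupper(type), suffix, ".txt"))
    lines <- c(paste(names(tab), collapse = "$"),
               do.call(paste, c(unname(as.list(tab)), list(sep = "$"))))
    writeLines(lines, path, useBytes = TRUE)
  }
  writeLines(c("caseid", bundle$deleted_caseids),
             file.path(out_dir, paste0("DELETED", suffix, ".txt")),
             useBytes = TRUE)
  invisible(out_dir)
}

#' Read a generator configuration from JSON
#'
#' The JSON mirrors the [synth_config()] fields; absent fields keep their
#' defaults, and `planted` is a list of objects with the
#' [planted_signal()] fields.
#'
#' @param path JSON file path.
#' @return a `"synth_config"`.
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$planted)) {
    pl <- raw$planted
    raw$planted <- lapply(seq_len(nrow(pl)), function(i)
      do.call(planted_signal, as.list(pl[i, ])))
  }
  for (nm in c("drug_probs", "event_probs", "sex_probs", "age_band_probs",
               "country_probs", "occp_probs", "outcome_probs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(synth_config, raw)
}
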