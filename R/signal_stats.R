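# Disproportionality statistics on drug-event 2x2 tables.
#
# For one drug-event pair against the deduplicated reporting background:
#       a = reports with drug and event      b = drug, other events
#       c = other drugs, event               d = other drugs, other events
# with N = a+b+c+d and expected count E = (a+b)(a+c)/N under independence.
#
# Four statistics are computed in their standard published forms:
#   ROR  = ad/bc, 95% CI by the log-normal approximation (z = 1.96);
#   PRR  = [a/(a+b)]/[c/(c+d)] with the Yates-corrected chi-square;
#   IC   = log2((a+0.5)/(E+0.5)) with Noren's lower-bound approximation
#          IC025 = IC - 3.3 (a+0.5)^-1/2 - 2.0 (a+0.5)^-3/2;
#   EBGM = a/E (closed form, no MGPS prior fitting) with
#          EBGM05 = EBGM * exp(-1.64 sqrt(1/a+1/b+1/c+1/d)).
# Zero cells yield an "undefined" (NA) state rather than a continuity
# correction, and undefined statistics can never flag positive.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer cell counts (see module header).
#' @return object of class `"contingency"`: list with the four cells,
#'   `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`.
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(!is.na(cells)), all(cells >= 0))
  N <- a + b + c + d
  if (N == 0) stop("empty contingency table")
  structure(list(a = a, b = b, c = c, d = d, N = N,
                 E = (a + b) * (a + c) / N),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  cat(sprintf("N = %d, E = %.4g\n", x$N, x$E))
  invisible(x)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`; the two-sided 95% CI is
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the statistic undefined (`NA`); no continuity correction is applied.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `ror`, `ror_lo95`, `ror_hi95`.
#' @examples
#' compute_ror(contingency(10, 90, 100, 9800))
#' @export
compute_ror <- function(t) {
  stopifnot(inherits(t, "contingency"))
  und <- c(ror = NA_real_, ror_lo95 = NA_real_, ror_hi95 = NA_real_)
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0) return(und)
  ror <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  c(ror = ror, ror_lo95 = exp(log(ror) - 1.96 * se),
    ror_hi95 = exp(log(ror) + 1.96 * se))
}

#' Proportional reporting ratio with Yates-corrected chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square is the Yates-corrected
#' Pearson statistic `sum((|O - E_cell| - 0.5)^2 / E_cell)` over the four
#' cells with marginal-product expecteds, each cell's correction floored at
#' zero. Undefined (`NA`) when `c = 0` or a margin is empty.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `prr`, `chi2`.
#' @examples
#' compute_prr(contingency(10, 90, 100, 9800))
#' @export
compute_prr <- function(t) {
  stopifnot(inherits(t, "contingency"))
  if (t$c == 0 || (t$a + t$b) == 0 || (t$c + t$d) == 0)
    return(c(prr = NA_real_, chi2 = NA_real_))
  prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  O <- c(t$a, t$b, t$c, t$d)
  E <- c((t$a + t$b) * (t$a + t$c), (t$a + t$b) * (t$b + t$d),
         (t$c + t$d) * (t$a + t$c), (t$c + t$d) * (t$b + t$d)) / t$N
  chi2 <- if (any(E == 0)) NA_real_ else
    sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  c(prr = prr, chi2 = chi2)
}

#' Information component with lower credibility bound
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` (bits); the one-sided lower 2.5%
#' credibility bound uses the shrinkage-observed approximation
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2.0 (a+0.5)^(-3/2)`. The 0.5
#' smoothing makes every table admissible, so the statistic is total.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `ic`, `ic025`.
#' @examples
#' compute_ic(contingency(10, 90, 100, 9800))
#' @export
compute_ic <- function(t) {
  stopifnot(inherits(t, "contingency"))
  ic <- log2((t$a + 0.5) / (t$E + 0.5))
  ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2.0 * (t$a + 0.5)^(-1.5)
  c(ic = ic, ic025 = ic025)
}

#' Empirical Bayes geometric mean, closed form
#'
#' The relative reporting ratio `EBGM = a N / ((a+b)(a+c)) = a/E` with the
#' lower one-sided 5% bound `EBGM05 = EBGM exp(-1.64 sqrt(1/a+1/b+1/c+1/d))`.
#' This is the shrinkage-free closed form: no gamma-mixture (MGPS) prior is
#' fitted, and the method variant is recorded in screen metadata. The point
#' estimate is returned whenever `E > 0`; the bound is undefined (`NA`) when
#' any cell is zero.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `ebgm`, `ebgm05`.
#' @examples
#' compute_ebgm(contingency(10, 90, 100, 9800))
#' @export
compute_ebgm <- function(t) {
  stopifnot(inherits(t, "contingency"))
  ebgm <- if (t$E > 0) t$a / t$E else NA_real_
  ebgm05 <- if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0) NA_real_ else
    ebgm * exp(-1.64 * sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d))
  c(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Default signal-positivity thresholds
#'
#' ROR: at least 3 reports and 95% CI lower bound above 1. PRR: at least 3
#' reports, PRR >= 2 and chi-square >= 4. IC: IC025 > 0. EBGM: EBGM05 > 2.
#' A pair is a combined positive signal when any one algorithm flags it.
#'
#' @return named list of thresholds; pass a modified copy to
#'   [evaluate_criteria()] or [signal_screen()] to change the criteria.
#' @export
default_thresholds <- function() {
  list(n_min = 3, ror_lo95_min = 1, prr_min = 2, chi2_min = 4,
       ic025_min = 0, ebgm05_min = 2)
}

#' Evaluate signal-positivity criteria
#'
#' @param s named numeric vector (or 1-row data.frame) holding
#'   `ror_lo95`, `prr`, `chi2`, `ic025`, `ebgm05`.
#' @param n the observed report count (cell a).
#' @param thresholds see [default_thresholds()].
#' @return named logical vector `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm`, `flag_any`; an undefined statistic gives `FALSE`.
#' @export
evaluate_criteria <- function(s, n, thresholds = default_thresholds()) {
  s <- unlist(s)
  th <- thresholds
  pos <- function(x) !is.na(x) & x
  f_ror <- pos(n >= th$n_min & s[["ror_lo95"]] > th$ror_lo95_min)
  f_prr <- pos(n >= th$n_min & s[["prr"]] >= th$prr_min &
                 s[["chi2"]] >= th$chi2_min)
  f_ic <- pos(s[["ic025"]] > th$ic025_min)
  f_ebgm <- pos(s[["ebgm05"]] > th$ebgm05_min)
  c(flag_ror = f_ror, flag_prr = f_prr, flag_ic = f_ic, flag_ebgm = f_ebgm,
    flag_any = f_ror || f_prr || f_ic || f_ebgm)
}

#' Disproportionality analysis of one 2x2 table
#'
#' The central estimator: computes all four disproportionality statistics
#' with their interval bounds and positivity flags for one drug-event
#' contingency table.
#'
#' @param a,b,c,d cell counts, or a single [contingency()] table as `a`.
#' @param thresholds see [default_thresholds()].
#' @return object of class `"disprop"`: list with `table` (the
#'   contingency), `stats` (named numeric vector of the ten statistics),
#'   `flags`, `thresholds` and `method` metadata (formula variants and
#'   constants used).
#' @examples
#' d <- disproportionality(905, 15000, 1200, 7210000)
#' print(d)
#' @export
disproportionality <- function(a, b = NULL, c = NULL, d = NULL,
                               thresholds = default_thresholds()) {
  t <- if (inherits(a, "contingency")) a else contingency(a, b, c, d)
  stats <- c(n = t$a, compute_ror(t), compute_prr(t), compute_ic(t),
             compute_ebgm(t))
  flags <- evaluate_criteria(stats, t$a, thresholds)
  structure(list(table = t, stats = stats, flags = flags,
                 thresholds = thresholds, method = .method_metadata()),
            class = "disprop")
}

.method_metadata <- function() {
  list(ror_ci = "log-normal approximation, z = 1.96",
       chi2 = "Pearson with Yates correction floored at 0 per cell",
       ic = "log2((a+0.5)/(E+0.5)); IC025 = IC - 3.3(a+0.5)^-1/2 - 2.0(a+0.5)^-3/2",
       ebgm = "closed form a/E (no MGPS prior); EBGM05 = EBGM*exp(-1.64*se_log)",
       zero_cells = "undefined (NA), no continuity correction")
}

#' @export
print.disprop <- function(x, ...) {
  s <- x$stats
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  cat(sprintf("Disproportionality (a=%d, b=%d, c=%d, d=%d, N=%d)\n",
              x$table$a, x$table$b, x$table$c, x$table$d, x$table$N))
  cat(sprintf("  ROR  %s (%s-%s)%s\n", fmt(s[["ror"]]), fmt(s[["ror_lo95"]]),
              fmt(s[["ror_hi95"]]), if (x$flags[["flag_ror"]]) " *" else ""))
  cat(sprintf("  PRR  %s (chi2 %s)%s\n", fmt(s[["prr"]]), fmt(s[["chi2"]]),
              if (x$flags[["flag_prr"]]) " *" else ""))
  cat(sprintf("  IC   %s (IC025 %s)%s\n", fmt(s[["ic"]]), fmt(s[["ic025"]]),
              if (x$flags[["flag_ic"]]) " *" else ""))
  cat(sprintf("  EBGM %s (EBGM05 %s)%s\n", fmt(s[["ebgm"]]),
              fmt(s[["ebgm05"]]), if (x$flags[["flag_ebgm"]]) " *" else ""))
  cat(if (x$flags[["flag_any"]]) "  => positive signal\n"
      else "  => no signal\n")
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  out <- as.data.frame(t(object$stats))
  out <- cbind(out, as.data.frame(t(object$flags)))
  class(out) <- c("summary.disprop", "data.frame")
  out
}

#' Build the per-report flag universe for signal screening
#'
#' For every retained (deduplicated) report: one logical drug flag per
#' study-drug key (some PS DRUG row matches the lexicon), the route class of
#' that matched drug (precedence oral > intravenous > other > unknown across
#' conflicting PS rows), one logical event flag per target event, and the
#' sex / age-group stratification variables.
#'
#' @param bundle a deduplicated `"quarter_bundle"` (from [dedup_bundle()]).
#' @param lexicon,events as in [extract_cohort()].
#' @return data.frame, one row per report, with columns `caseid`, `sex`,
#'   `age_group`, `has_<drug>`, `route_<drug>`, `has_<event>`.
#' @export
build_universe <- function(bundle, lexicon = load_lexicon(),
                           events = load_target_events()) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  demo <- bundle$demo
  uni <- data.frame(caseid = demo$caseid, stringsAsFactors = FALSE)
  uni$sex <- ifelse(nzchar(demo$sex), demo$sex, "UNK")
  uni$age_group <- age_group(harmonize_age(demo$age, demo$age_cod))
  ps <- .report_drug_flags(bundle$drug, demo$primaryid, lexicon)
  for (dk in names(lexicon)) {
    rows <- ps[ps$drug_key == dk, , drop = FALSE]
    uni[[paste0("has_", dk)]] <- uni$caseid %in% rows$caseid
    best <- tapply(.route_precedence[rows$route_class], rows$caseid, min)
    route <- rep(NA_character_, nrow(uni))
    idx <- match(names(best), uni$caseid)
    route[idx] <- names(.route_precedence)[best]
    uni[[paste0("route_", dk)]] <- route
  }
  reac <- bundle$reac[bundle$reac$primaryid %in% demo$primaryid, ,
                      drop = FALSE]
  key <- events$event_key[match(toupper(trimws(reac$pt)),
                                toupper(events$pt_name))]
  for (ek in events$event_key)
    uni[[paste0("has_", ek)]] <- uni$caseid %in% reac$caseid[!is.na(key) &
                                                               key == ek]
  uni
}

#' Build one drug-event contingency table, optionally within a stratum
#'
#' Cells are exhaustive counts over the report universe:
#' `a = |drug & event|`, `b = |drug & !event|`, `c = |!drug & event|`,
#' `d = |!drug & !event|`. Sex and age strata restrict the universe to the
#' stratum (so b, c, d are recomputed against the stratum's own background);
#' a route stratum instead restricts the drug flag to reports where the
#' matched primary-suspect drug has that route class.
#'
#' @param universe a [build_universe()] data.frame.
#' @param drug,event drug key and event key to cross.
#' @param stratum `NULL`, or `list(axis =, level =)` with axis one of
#'   `"sex"`, `"age_group"`, `"route"`.
#' @return a [contingency()] table.
#' @export
build_contingency <- function(universe, drug, event, stratum = NULL) {
  if (nrow(universe) == 0L) stop("empty report universe")
  has_drug <- universe[[paste0("has_", drug)]]
  has_event <- universe[[paste0("has_", event)]]
  if (is.null(has_drug) || is.null(has_event))
    stop("universe lacks flags for ", drug, " / ", event)
  if (!is.null(stratum) && !identical(stratum$axis, "none")) {
    if (stratum$axis == "route") {
      has_drug <- has_drug &
        !is.na(universe[[paste0("route_", drug)]]) &
        universe[[paste0("route_", drug)]] == stratum$level
    } else if (stratum$axis %in% c("sex", "age_group")) {
      keep <- universe[[stratum$axis]] == stratum$level
      has_drug <- has_drug[keep]
      has_event <- has_event[keep]
      if (length(has_drug) == 0L) stop("empty stratum: ", stratum$level)
    } else stop("unknown stratum axis: ", stratum$axis)
  }
  contingency(sum(has_drug & has_event), sum(has_drug & !has_event),
              sum(!has_drug & has_event), sum(!has_drug & !has_event))
}

#' Screen drug-event pairs for disproportionality signals
#'
#' Runs [disproportionality()] for every requested (drug, event, stratum)
#' combination against the deduplicated report universe and returns one row
#' per combination with the four statistics, interval bounds and positivity
#' flags -- the layout of a published signal table, with route-stratified
#' rows as the oral/intravenous comparison.
#'
#' @param universe a [build_universe()] data.frame.
#' @param drugs,events key vectors (default: every flag in the universe).
#' @param strata list of `list(axis =, level =)` stratum specs to append
#'   after the unstratified rows (e.g.
#'   `list(list(axis = "route", level = "oral"))`).
#' @param thresholds see [default_thresholds()].
#' @return data.frame of class `"signal_screen"`, deterministically ordered
#'   (strata in given order, then drug, then event), with attribute
#'   `method` recording the formula variants. Statistics are kept at full
#'   precision; `print()` rounds to 2 decimals.
#' @export
signal_screen <- function(universe, drugs = NULL, events = NULL,
                          strata = NULL,
                          thresholds = default_thresholds()) {
  drug_keys <- sub("^route_", "", grep("^route_", names(universe),
                                       value = TRUE))
  if (is.null(drugs)) drugs <- drug_keys
  if (is.null(events))
    events <- setdiff(sub("^has_", "", grep("^has_", names(universe),
                                            value = TRUE)), drug_keys)
  specs <- c(list(list(axis = "none", level = "all")), strata)
  rows <- list()
  for (sp in specs) for (dk in drugs) for (ek in events) {
    res <- tryCatch({
      t <- build_contingency(universe, dk, ek, sp)
      d <- disproportionality(t, thresholds = thresholds)
      c(as.list(d$stats), as.list(d$flags))
    }, error = function(e) {
      c(list(n = 0, ror = NA_real_, ror_lo95 = NA_real_,
             ror_hi95 = NA_real_, prr = NA_real_, chi2 = NA_real_,
             ic = NA_real_, ic025 = NA_real_, ebgm = NA_real_,
             ebgm05 = NA_real_),
        as.list(stats::setNames(rep(FALSE, 5),
                                c("flag_ror", "flag_prr", "flag_ic",
                                  "flag_ebgm", "flag_any"))))
    })
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(drug = dk, event = ek, stratum_axis = sp$axis,
                       stratum_level = sp$level, stringsAsFactors = FALSE),
            as.data.frame(res))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "method") <- .method_metadata()
  attr(out, "thresholds") <- thresholds
  class(out) <- c("signal_screen", "data.frame")
  out
}

#' @export
print.signal_screen <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE) & names(y) != "n"
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
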