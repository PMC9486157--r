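# Reading and writing FAERS ASCII quarterly archives.
#
# FAERS quarterly packages ship "$"-delimited text files (DEMO/DRUG/REAC/
# OUTC/THER/INDI plus an optional deleted-case list). The dialect has no
# quoting and "$" cannot occur inside a field, so naive per-line splitting
# is exact. Only the 2016+ (PRIMARYID-era) layout is supported.

# canonical columns retained per table; all are FAERS header names, lowercased
.faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country", "occr_country", "rept_dt"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai", "route", "dose_vbm", "dechal", "rechal"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.age_unit_codes <- c("YR", "MON", "WK", "DY", "HR", "DEC")

#' Parse one FAERS "$"-delimited table file
#'
#' Splits each data line on `$` (the FAERS ASCII dialect has no quoting),
#' lowercases the header, and drops -- with a tally -- rows whose field count
#' disagrees with the header. Columns not in the canonical schema for `type`
#' are discarded; missing mandatory columns are a fatal error.
#'
#' @param path path to a `$`-delimited text file with a header line.
#' @param type one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`,
#'   `"indi"`; selects the mandatory column set.
#' @return list with `data` (data.frame, character columns in canonical
#'   order), `n_raw` (data lines in the file), `n_dropped_malformed`.
#' @keywords internal
read_faers_file <- function(path, type) {
  type <- match.arg(type, names(.faers_schema))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty FAERS file: ", path)
  header <- tolower(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  need <- .faers_schema[[type]]
  missing_cols <- setdiff(need, header)
  if (length(missing_cols) > 0L)
    stop(sprintf("file %s lacks mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n_raw <- length(body)
  if (n_raw == 0L) stop("no data rows in FAERS file: ", path)
  parts <- strsplit(body, "$", fixed = TRUE)
  # a line ending in "$" drops the trailing empty field in strsplit; pad
  nf <- lengths(parts)
  pad <- nf == length(header) - 1L & endsWith(body, "$")
  parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
  nf[pad] <- nf[pad] + 1L
  ok <- nf == length(header)
  parts <- parts[ok]
  dat <- as.data.frame(
    lapply(seq_along(header), function(j) vapply(parts, `[[`, "", j)),
    stringsAsFactors = FALSE)
  names(dat) <- header
  dat <- dat[, need, drop = FALSE]
  list(data = dat, n_raw = n_raw, n_dropped_malformed = sum(!ok))
}

.find_faers_file <- function(dir, stem) {
  hits <- list.files(dir, pattern = paste0("(?i)^", stem, ".*\\.txt$"),
                     full.names = TRUE)
  if (length(hits) > 1L)
    stop(sprintf("multiple %s files in %s", toupper(stem), dir))
  if (length(hits) == 1L) hits else NULL
}

#' Read one FAERS quarterly archive
#'
#' Parses the six mandatory `$`-delimited tables (DEMO, DRUG, REAC, OUTC,
#' THER, INDI) plus an optional deleted-case list from a directory, validates
#' enumerated codes and key presence, drops orphan rows (non-DEMO rows whose
#' `primaryid` has no DEMO row), and tallies every dropped row by reason.
#' Dates are kept as raw 4/6/8-digit strings; validity rules differ per
#' downstream analysis, so parsing is deferred (see [parse_partial_date()]).
#'
#' @param archive_path directory holding the quarter's files, e.g. containing
#'   `DEMO16Q1.txt`, `DRUG16Q1.txt`, ... A file whose name starts with
#'   `DELET` is read as the deleted-case list (one caseid per line after the
#'   header); the list is treated as optional and empty when absent.
#' @param label quarter tag carried on the result, e.g. `"2016Q1"`.
#' @return an object of class `"quarter_bundle"`: a list with the six tables
#'   (`demo`, `drug`, `reac`, `outc`, `ther`, `indi` -- character-column
#'   data.frames), `deleted_caseids`, `label`, and a `log` data.frame of
#'   per-file row counts (raw, parsed, dropped by reason).
#' @examples
#' dir <- tempfile(); cfg <- synth_config(n_reports = 50, seed = 1)
#' generate_quarter(cfg, "2016Q1", dir)
#' b <- read_quarter(dir, "2016Q1")
#' nrow(b$demo)
#' @export
read_quarter <- function(archive_path, label) {
  stopifnot(dir.exists(archive_path))
  tabs <- list()
  log <- list()
  for (type in names(.faers_schema)) {
    path <- .find_faers_file(archive_path, type)
    if (is.null(path))
      stop(sprintf("mandatory FAERS file %s* not found in %s",
                   toupper(type), archive_path))
    parsed <- read_faers_file(path, type)
    dat <- parsed$data
    # key presence + enumerated-code invariants; violating rows are dropped
    keep <- nzchar(dat$primaryid) & nzchar(dat$caseid)
    if (type == "drug")
      keep <- keep & (!nzchar(dat$role_cod) | dat$role_cod %in% .role_codes)
    if (type == "reac") keep <- keep & nzchar(dat$pt)
    if (type == "outc") keep <- keep & dat$outc_cod %in% .outcome_codes
    if (type == "demo")
      keep <- keep &
        (!nzchar(dat$age_cod) | toupper(dat$age_cod) %in% .age_unit_codes)
    n_invalid <- sum(!keep)
    dat <- dat[keep, , drop = FALSE]
    tabs[[type]] <- dat
    log[[type]] <- data.frame(
      file = basename(path), n_raw = parsed$n_raw,
      n_dropped_malformed = parsed$n_dropped_malformed,
      n_dropped_invalid = n_invalid, n_dropped_orphan = 0L,
      stringsAsFactors = FALSE)
  }
  # orphans: every non-DEMO row must reference a DEMO primaryid
  demo_ids <- unique(tabs$demo$primaryid)
  for (type in setdiff(names(tabs), "demo")) {
    orphan <- !(tabs[[type]]$primaryid %in% demo_ids)
    log[[type]]$n_dropped_orphan <- sum(orphan)
    tabs[[type]] <- tabs[[type]][!orphan, , drop = FALSE]
  }
  log <- do.call(rbind, c(log, list(make.row.names = FALSE)))
  log$n_parsed <- log$n_raw - log$n_dropped_malformed -
    log$n_dropped_invalid - log$n_dropped_orphan
  del_path <- .find_faers_file(archive_path, "delet")
  deleted <- character(0)
  if (!is.null(del_path)) {
    del <- readLines(del_path, warn = FALSE)
    del <- trimws(del[-1L])             # first line is a header
    deleted <- unique(del[nzchar(del)])
  }
  rownames(log) <- NULL
  for (type in names(tabs)) rownames(tabs[[type]]) <- NULL
  structure(c(tabs, list(deleted_caseids = deleted, label = label,
                         log = log)),
            class = "quarter_bundle")
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat(sprintf("FAERS quarter bundle %s\n", x$label))
  for (type in names(.faers_schema))
    cat(sprintf("  %-5s %7d rows\n", toupper(type), nrow(x[[type]])))
  cat(sprintf("  deleted caseids: %d\n", length(x$deleted_caseids)))
  invisible(x)
}

#' Parse FAERS partial dates
#'
#' FAERS date fields are raw digit strings with 8 (day), 6 (month) or 4
#' (year) digits; entries may be empty, truncated, or calendar-impossible.
#' This parser is total: every input maps to exactly one of the precision
#' states `day`, `month`, `year`, `invalid` and it never throws. Month- and
#' year-precision values are anchored to the first day of the period.
#'
#' @param raw character vector of raw date strings.
#' @return data.frame with columns `date` (class `Date`, `NA` when invalid)
#'   and `precision` (character: `"day"`, `"month"`, `"year"`, `"invalid"`).
#' @examples
#' parse_partial_date(c("20180105", "201801", "2018", "20180230", ""))
#' @export
parse_partial_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  date <- rep(as.Date(NA), n)
  prec <- rep("invalid", n)
  digits <- grepl("^[0-9]+$", raw)

  is8 <- digits & nchar(raw) == 8L
  if (any(is8)) {
    d <- as.Date(raw[is8], format = "%Y%m%d")
    # as.Date(format=) yields NA for impossible days such as 20180230
    date[is8] <- d
    prec[is8][!is.na(d)] <- "day"
  }
  is6 <- digits & nchar(raw) == 6L
  if (any(is6)) {
    mon <- as.integer(substr(raw[is6], 5L, 6L))
    ok <- mon >= 1L & mon <= 12L
    d <- as.Date(paste0(raw[is6], "01"), format = "%Y%m%d")
    d[!ok] <- NA
    date[is6] <- d
    prec[is6][!is.na(d)] <- "month"
  }
  is4 <- digits & nchar(raw) == 4L
  if (any(is4)) {
    yr <- as.integer(raw[is4])
    ok <- yr >= 1900L & yr <= 2100L
    d <- as.Date(paste0(raw[is4], "0101"), format = "%Y%m%d")
    d[!ok] <- NA
    date[is4] <- d
    prec[is4][!is.na(d)] <- "year"
  }
  data.frame(date = date, precision = prec, stringsAsFactors = FALSE)
}

#' Write a pipeline table as RFC-4180 CSV
#'
#' @param rows data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE, na = "")
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
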