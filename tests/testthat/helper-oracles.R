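# Independent oracles and small fixture builders shared across tests.

# Brute-force evaluation of the four disproportionality formulas, coded
# independently of the package internals (plain arithmetic, no shared
# helpers). Returns NA where the package defines an undefined state.
oracle_disprop <- function(a, b, c, d) {
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  any0 <- a == 0 || b == 0 || c == 0 || d == 0
  selog <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- if (any0) NA_real_ else (a / b) / (c / d)
  ror_lo <- if (any0) NA_real_ else ror * exp(-1.96 * selog)
  ror_hi <- if (any0) NA_real_ else ror * exp(1.96 * selog)
  prr <- if (c == 0) NA_real_ else (a * (c + d)) / ((a + b) * c)
  chi2 <- if (c == 0) NA_real_ else {
    obs <- c(a, b, c, d)
    exps <- c((a + b) * (a + c), (a + b) * (b + d),
              (c + d) * (a + c), (c + d) * (b + d)) / N
    tot <- 0
    for (k in 1:4) {
      dev <- abs(obs[k] - exps[k]) - 0.5
      if (dev < 0) dev <- 0
      tot <- tot + dev^2 / exps[k]
    }
    tot
  }
  ic <- log((a + 0.5) / (E + 0.5)) / log(2)
  ic025 <- ic - 3.3 / sqrt(a + 0.5) - 2.0 / sqrt(a + 0.5)^3
  ebgm <- a / E
  ebgm05 <- if (any0) NA_real_ else ebgm * exp(-1.64 * selog)
  c(ror = ror, ror_lo95 = ror_lo, ror_hi95 = ror_hi, prr = prr,
    chi2 = chi2, ic = ic, ic025 = ic025, ebgm = ebgm, ebgm05 = ebgm05)
}

# Sort-and-index quartiles: explicit positional medians of the lower and
# upper halves (middle element excluded for odd n).
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  pos_median <- function(v) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  if (n == 1) return(c(q1 = x, median = x, q3 = x))
  h <- n %/% 2
  c(q1 = pos_median(x[1:h]), median = pos_median(x),
    q3 = pos_median(x[(n - h + 1):n]))
}

# Minimal in-memory quarter bundle from row lists; all tables optional.
make_bundle <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                        ther = NULL, indi = NULL,
                        deleted = character(0), label = "2016Q1") {
  empty <- list(
    drug = data.frame(primaryid = character(), caseid = character(),
                      drug_seq = character(), role_cod = character(),
                      drugname = character(), prod_ai = character(),
                      route = character(), dose_vbm = character(),
                      dechal = character(), rechal = character(),
                      stringsAsFactors = FALSE),
    reac = data.frame(primaryid = character(), caseid = character(),
                      pt = character(), stringsAsFactors = FALSE),
    outc = data.frame(primaryid = character(), caseid = character(),
                      outc_cod = character(), stringsAsFactors = FALSE),
    ther = data.frame(primaryid = character(), caseid = character(),
                      dsg_drug_seq = character(), start_dt = character(),
                      end_dt = character(), stringsAsFactors = FALSE),
    indi = data.frame(primaryid = character(), caseid = character(),
                      indi_drug_seq = character(), indi_pt = character(),
                      stringsAsFactors = FALSE))
  structure(list(demo = demo,
                 drug = if (is.null(drug)) empty$drug else drug,
                 reac = if (is.null(reac)) empty$reac else reac,
                 outc = if (is.null(outc)) empty$outc else outc,
                 ther = if (is.null(ther)) empty$ther else ther,
                 indi = if (is.null(indi)) empty$indi else indi,
                 deleted_caseids = deleted, label = label, log = NULL),
            class = "quarter_bundle")
}

demo_row <- function(primaryid, caseid, fda_dt = "20180101",
                     event_dt = "", age = "", age_cod = "", sex = "F",
                     occp_cod = "MD", reporter_country = "US",
                     occr_country = "US") {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
             occp_cod = occp_cod, reporter_country = reporter_country,
             occr_country = occr_country, rept_dt = fda_dt,
             stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, caseid, drug_seq = "1", role_cod = "PS",
                     drugname = "CIPROFLOXACIN", prod_ai = "",
                     route = "Oral") {
  data.frame(primaryid = primaryid, caseid = caseid, drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname, prod_ai = prod_ai,
             route = route, dose_vbm = "", dechal = "", rechal = "",
             stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, caseid, pt) {
  data.frame(primaryid = primaryid, caseid = caseid, pt = pt,
             stringsAsFactors = FALSE)
}

ther_row <- function(primaryid, caseid, dsg_drug_seq = "1",
                     start_dt = "", end_dt = "") {
  data.frame(primaryid = primaryid, caseid = caseid,
             dsg_drug_seq = dsg_drug_seq, start_dt = start_dt,
             end_dt = end_dt, stringsAsFactors = FALSE)
}

# Build a cohort object directly (bypassing extraction) with given group
# structure; used for descriptive-arithmetic checks where the printed
# counts are the input.
make_cohort <- function(cases, drugs, outcomes,
                        event_keys = c("tendonitis", "tendon_rupture"),
                        drug_keys = c("ciprofloxacin", "levofloxacin",
                                      "moxifloxacin")) {
  structure(list(cases = cases, drugs = drugs, outcomes = outcomes,
                 event_keys = event_keys, drug_keys = drug_keys),
            class = "faers_cohort")
}

# Write a bundle's tables to disk in the FAERS "$" dialect via the
# package's own writer (exercised through generate_quarter elsewhere; here
# for handcrafted archives).
write_faers_dialect <- function(dir, type, tab, suffix = "16Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(toupper(type), suffix, ".txt"))
  lines <- c(paste(names(tab), collapse = "$"),
             do.call(paste, c(unname(as.list(tab)), list(sep = "$"))))
  writeLines(lines, path)
  path
}
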