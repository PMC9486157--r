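# Packaged reference tables: drug lexicon, target-event PT list,
# country -> continent mapping, infection-indication PT list.

.pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fqsignal")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Load a study-drug lexicon
#'
#' The lexicon maps each study-drug key to its set of generic and trade
#' names (uppercase). The packaged default covers ciprofloxacin,
#' levofloxacin and moxifloxacin with their US trade names (CIPRO, CILOXAN,
#' LEVAQUIN, QUIXIN, AVELOX, MOXEZA, VIGAMOX, ...). Name sets must be
#' disjoint across drug keys; a name listed under two keys is a fatal
#' lexicon error.
#'
#' @param path CSV with columns `drug_key,name`; default: packaged lexicon.
#' @return named list of class `"drug_lexicon"`: one uppercase character
#'   vector of names per drug key.
#' @export
load_lexicon <- function(path = .pkg_extdata("fq_lexicon.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_key", "name") %in% names(tab)))
  tab$name <- toupper(trimws(tab$name))
  if (anyDuplicated(tab$name))
    stop("lexicon name(s) mapped to more than one drug key: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  lex <- split(tab$name, tab$drug_key)
  structure(lex, class = "drug_lexicon")
}

#' Load the target adverse-event set
#'
#' Target events are MedDRA Preferred Terms; FAERS REAC files store PT
#' names, so matching is by name (case-insensitive) with the PT code kept
#' as metadata. The packaged default holds Tendonitis (10043255) and
#' Tendon rupture (10043248).
#'
#' @param path CSV with columns `event_key,pt_name,pt_code`.
#' @return data.frame of class `"target_events"` with those columns.
#' @export
load_target_events <- function(path = .pkg_extdata("target_events.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(pt_code = "character"))
  stopifnot(all(c("event_key", "pt_name", "pt_code") %in% names(tab)))
  if (!all(grepl("^[0-9]{8}$", tab$pt_code)))
    stop("PT codes must be 8-digit integers")
  structure(tab, class = c("target_events", "data.frame"))
}

#' Country to reporting-region lookup table
#' @return data.frame `country,region`; regions are the six continents plus
#'   Unknown.
#' @export
country_region_table <- function() {
  utils::read.csv(.pkg_extdata("country_regions.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged list of infection-indication Preferred Terms
#' @return uppercase character vector of PT names.
#' @export
infection_pt_list <- function() {
  toupper(utils::read.csv(.pkg_extdata("infection_pts.csv"),
                          stringsAsFactors = FALSE)$indi_pt)
}
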