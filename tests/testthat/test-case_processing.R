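test_that("deduplication keeps the latest FDA_DT, then the higher PRIMARYID", {
  demo <- rbind(demo_row("1001", "100", fda_dt = "20200101"),
                demo_row("1002", "100", fda_dt = "20200301"))
  expect_equal(deduplicate(demo)$kept$primaryid, "1002")

  demo <- rbind(demo_row("1002", "100", fda_dt = "20200301"),
                demo_row("1003", "100", fda_dt = "20200301"))
  expect_equal(deduplicate(demo)$kept$primaryid, "1003")

  # all-distinct caseids pass through unchanged
  demo <- rbind(demo_row("1001", "100"), demo_row("1011", "101"),
                demo_row("1021", "102"))
  dd <- deduplicate(demo)
  expect_equal(sort(dd$kept$primaryid), sort(demo$primaryid))
  expect_equal(dd$removed_duplicates, 0)
})

test_that("deduplication removes deleted cases and conserves row counts", {
  demo <- rbind(demo_row("1001", "100", fda_dt = "20200101"),
                demo_row("1002", "100", fda_dt = "20200301"),
                demo_row("1011", "101"),
                demo_row("1021", "102", fda_dt = "2020XX"))
  dd <- deduplicate(demo, deleted = "101")
  expect_equal(dd$kept$caseid, "100")
  expect_equal(dd$removed_duplicates, 1)
  expect_equal(dd$removed_deleted, 1)
  expect_equal(dd$removed_invalid_date, 1)
  expect_equal(nrow(dd$kept) + dd$removed_duplicates + dd$removed_deleted +
                 dd$removed_invalid_date, nrow(demo))
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(5)
  n <- 120
  demo <- do.call(rbind, lapply(seq_len(n), function(i)
    demo_row(primaryid = as.character(10000 + i),
             caseid = as.character(sample(40, 1)),
             fda_dt = format(as.Date("2019-01-01") + sample(0:300, 1),
                             "%Y%m%d"))))
  dd <- deduplicate(demo)
  expect_equal(anyDuplicated(dd$kept$caseid), 0)
  expect_identical(deduplicate(dd$kept)$kept, dd$kept)   # idempotence
  for (rep in 1:5) {
    perm <- demo[sample(nrow(demo)), , drop = FALSE]
    expect_identical(deduplicate(perm)$kept, dd$kept)    # permutation
  }
})

test_that("drug names match the lexicon exactly, never by substring", {
  lex <- load_lexicon()
  expect_equal(match_drug("CIPRO"), "ciprofloxacin")
  expect_equal(match_drug("LEVOFLOXACIN."), "levofloxacin")
  expect_equal(match_drug("AMOXICILLIN"), NA_character_)
  expect_equal(match_drug("CIPROFIBRATE"), NA_character_)
  expect_equal(match_drug("CIPRO 500MG TABLET"), "ciprofloxacin")
  expect_equal(match_drug("  avelox  "), "moxifloxacin")
  expect_equal(match_drug("UNKNOWN BLUE PILL", "LEVOFLOXACIN"),
               "levofloxacin")                 # prod_ai fallback
  expect_equal(match_drug(c("CIPRO", "LEVAQUIN", "ASPIRIN")),
               c("ciprofloxacin", "levofloxacin", NA))
})

test_that("a name under two drug keys is a fatal lexicon error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_key,name", "ciprofloxacin,CIPRO", "levofloxacin,CIPRO"),
             path)
  expect_error(load_lexicon(path), "more than one drug key")
})

test_that("routes classify against the packaged mapping", {
  expect_equal(classify_route(c("Oral", "Intravenous drip", "Intravenous",
                                "INTRAVENOUS BOLUS",
                                "Intravenous (not otherwise specified)",
                                "Topical", "")),
               c("oral", "intravenous", "intravenous", "intravenous",
                 "intravenous", "other", "unknown"))
})

test_that("ages harmonize by unit with the band bounds inclusive", {
  expect_equal(harmonize_age(6, "MON"), 0.5)
  expect_equal(age_group(harmonize_age(6, "MON")), "<18")
  expect_equal(harmonize_age(65, "YR"), 65)
  expect_equal(age_group(65), "18-65")          # inclusive upper bound
  expect_equal(age_group(18), "18-65")
  expect_equal(age_group(65.5), ">65")
  expect_true(is.na(harmonize_age(-5, "YR")))
  expect_true(is.na(harmonize_age(130, "YR")))
  expect_equal(harmonize_age(6, "DEC"), 60)
  expect_equal(harmonize_age(730.5, "DY"), 2)
  expect_equal(harmonize_age(40, ""), 40)       # missing unit = years
  expect_equal(age_group(NA_real_), "unknown")
})

test_that("countries map to continents with Unknown fallback", {
  expect_equal(map_region(c("FR", "US", "", "XXQ", "JAPAN")),
               c("Europe", "North America", "Unknown", "Unknown", "Asia"))
})

test_that("indications class as infections / other / unknown", {
  expect_equal(
    classify_indication(c("Urinary tract infection", "Infection",
                          "Pneumonia", "Osteoarthritis",
                          "Product used for unknown indication", "")),
    c("infections", "infections", "infections", "other",
      "unknown-indication", "unknown-indication"))
})

test_that("cohort extraction enforces the PS-role and target-PT gates", {
  demo <- rbind(demo_row("1001", "100", event_dt = "20180110"),
                demo_row("1011", "101"),
                demo_row("1021", "102"))
  drug <- rbind(drug_row("1001", "100", drugname = "CIPRO", route = "Oral"),
                drug_row("1011", "101", role_cod = "SS",
                         drugname = "LEVOFLOXACIN"),
                drug_row("1021", "102", drugname = "CIPROFLOXACIN"))
  reac <- rbind(reac_row("1001", "100", "Tendonitis"),
                reac_row("1011", "101", "Tendon rupture"),
                reac_row("1021", "102", "Tendonitis"),
                reac_row("1021", "102", "Tendon rupture"))
  ther <- ther_row("1001", "100", start_dt = "20180105")
  b <- make_bundle(demo, drug, reac, ther = ther)
  coh <- extract_cohort(b)

  expect_equal(sort(coh$cases$caseid), c("100", "102"))  # 101 is SS only
  expect_true(coh$cases$has_tendonitis[coh$cases$caseid == "100"])
  expect_false(coh$cases$has_tendon_rupture[coh$cases$caseid == "100"])
  both <- coh$cases[coh$cases$caseid == "102", ]
  expect_true(both$has_tendonitis && both$has_tendon_rupture)
  expect_equal(nrow(both), 1)                   # one record, two event keys
  expect_equal(anyDuplicated(coh$cases$caseid), 0)
  expect_equal(coh$drugs$start_dt[coh$drugs$caseid == "100"], "20180105")
})

test_that("enlarging the lexicon never shrinks the cohort", {
  set.seed(9)
  b <- generate_quarter(synth_config(n_reports = 800, seed = 31), "2017Q2")
  dd <- dedup_bundle(b)$bundle
  full <- extract_cohort(dd)
  small_path <- withr::local_tempfile(fileext = ".csv")
  lex <- utils::read.csv(system.file("extdata", "fq_lexicon.csv",
                                     package = "fqsignal"))
  utils::write.csv(lex[lex$drug_key != "moxifloxacin", ], small_path,
                   row.names = FALSE)
  small <- extract_cohort(dd, lexicon = load_lexicon(small_path))
  expect_true(all(small$cases$caseid %in% full$cases$caseid))
  expect_gte(nrow(full$cases), nrow(small$cases))
})

test_that("conflicting PS routes resolve by the documented precedence", {
  demo <- demo_row("1001", "100")
  drug <- rbind(drug_row("1001", "100", drug_seq = "1",
                         drugname = "CIPRO", route = "Topical"),
                drug_row("1001", "100", drug_seq = "2",
                         drugname = "CIPROFLOXACIN", route = "Oral"))
  reac <- reac_row("1001", "100", "Tendonitis")
  coh <- extract_cohort(make_bundle(demo, drug, reac))
  expect_equal(nrow(coh$drugs), 1)              # report-level counting
  expect_equal(coh$drugs$route, "oral")
})
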