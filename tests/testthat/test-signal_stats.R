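test_that("contingency cells enumerate the flag universe", {
  uni <- data.frame(caseid = as.character(1:4),
                    sex = "F", age_group = "18-65",
                    has_ciprofloxacin = c(TRUE, TRUE, FALSE, FALSE),
                    route_ciprofloxacin = c("oral", "oral", NA, NA),
                    has_tendonitis = c(TRUE, FALSE, TRUE, FALSE))
  t <- build_contingency(uni, "ciprofloxacin", "tendonitis")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  uni$has_ciprofloxacin <- FALSE
  t0 <- build_contingency(uni, "ciprofloxacin", "tendonitis")
  expect_equal(c(t0$a, t0$b), c(0, 0))
  expect_error(build_contingency(uni[0, ], "ciprofloxacin", "tendonitis"),
               "empty")
})

test_that("universe cells match brute-force counts over a synthetic quarter", {
  b <- generate_quarter(synth_config(n_reports = 4000, seed = 13), "2019Q2")
  dd <- dedup_bundle(b)$bundle
  uni <- build_universe(dd)
  t <- build_contingency(uni, "ciprofloxacin", "tendonitis")
  # oracle: exhaustive count straight off the raw tables
  lex <- load_lexicon()
  ps <- dd$drug[dd$drug$role_cod == "PS", ]
  ps_cipro <- ps$caseid[!is.na(match_drug(ps$drugname, ps$prod_ai, lex)) &
                          match_drug(ps$drugname, ps$prod_ai, lex) ==
                            "ciprofloxacin"]
  has_d <- dd$demo$caseid %in% ps_cipro
  has_e <- dd$demo$caseid %in% dd$reac$caseid[dd$reac$pt == "Tendonitis"]
  expect_equal(c(t$a, t$b, t$c, t$d),
               c(sum(has_d & has_e), sum(has_d & !has_e),
                 sum(!has_d & has_e), sum(!has_d & !has_e)))
  expect_equal(t$N, nrow(dd$demo))
})

test_that("statistics equal an independent brute-force oracle on a grid", {
  cells <- c(1, 2, 3, 5, 9, 17, 30)
  grid <- expand.grid(a = cells, b = cells, c = cells, d = cells)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; c <- grid$c[i]; d <- grid$d[i]
    t <- contingency(a, b, c, d)
    got <- c(compute_ror(t), compute_prr(t), compute_ic(t), compute_ebgm(t))
    expect_equal(got, oracle_disprop(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("Yates chi-square agrees with stats::chisq.test", {
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(sample(1:400, 4, replace = TRUE), 2)
    t <- contingency(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(unname(compute_prr(t)[["chi2"]]),
                 unname(stats::chisq.test(m, correct = TRUE)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("worked 2x2 example reproduces hand-derived values", {
  t <- contingency(10, 90, 100, 9800)
  expect_equal(compute_ror(t)[["ror"]], 10.8889, tolerance = 1e-4)
  expect_equal(compute_ror(t)[["ror_lo95"]], 5.503, tolerance = 1e-3)
  expect_equal(compute_ror(t)[["ror_hi95"]], 21.546, tolerance = 1e-3)
  expect_equal(compute_prr(t)[["prr"]], 9.9, tolerance = 1e-9)
  expect_equal(compute_prr(t)[["chi2"]], 65.51, tolerance = 1e-3)
  expect_equal(compute_ic(t)[["ic"]], 2.714, tolerance = 1e-3)
  expect_equal(compute_ic(t)[["ic025"]], 1.637, tolerance = 1e-3)
  expect_equal(compute_ebgm(t)[["ebgm"]], 9.0909, tolerance = 1e-4)
  expect_equal(compute_ebgm(t)[["ebgm05"]], 5.136, tolerance = 1e-3)
})

test_that("sign and ordering properties hold across random tables", {
  set.seed(31)
  for (i in 1:200) {
    cl <- sample(1:60, 4, replace = TRUE)
    t <- contingency(cl[1], cl[2], cl[3], cl[4])
    ror <- compute_ror(t)[["ror"]]
    prr <- compute_prr(t)[["prr"]]
    expect_equal(ror > 1, prr > 1)
    expect_equal(ror > 1, cl[1] * cl[4] > cl[2] * cl[3])
    if (cl[1] * cl[4] > cl[2] * cl[3]) expect_gt(ror, prr)
  }
})

test_that("ror and ebgm increase strictly in a with b, c, d fixed", {
  rors <- vapply(1:40, function(a)
    compute_ror(contingency(a, 50, 60, 5000))[["ror"]], 0)
  ebgms <- vapply(1:40, function(a)
    compute_ebgm(contingency(a, 50, 60, 5000))[["ebgm"]], 0)
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(ebgms) > 0))
})

test_that("proportional rows give the exact independence limit", {
  for (k in c(1, 3, 7)) {
    t <- contingency(5 * k, 45 * k, 50 * k, 450 * k)  # rows proportional
    expect_equal(compute_ror(t)[["ror"]], 1)
    expect_equal(compute_prr(t)[["prr"]], 1)
    expect_equal(compute_ebgm(t)[["ebgm"]], 1)
    expect_equal(compute_ic(t)[["ic"]], 0)      # smoothing cancels at E = a
  }
})

test_that("zero cells yield the undefined state, never a corrected value", {
  t <- contingency(0, 50, 60, 5000)
  expect_true(all(is.na(compute_ror(t))))
  expect_true(is.na(compute_ebgm(t)[["ebgm05"]]))
  expect_equal(compute_ebgm(t)[["ebgm"]], 0)    # E > 0 so the point stands
  expect_true(is.na(compute_prr(contingency(5, 5, 0, 100))[["prr"]]))
  # IC is total thanks to smoothing
  expect_true(is.finite(compute_ic(t)[["ic"]]))
})

test_that("positivity criteria gate on count and bounds", {
  # large clear signal: all four algorithms fire
  d <- disproportionality(905, 15000, 1200, 7210000)
  expect_true(all(d$flags))
  # n = 2 with a huge ror: ROR and PRR flags are count-gated off
  t <- contingency(2, 1, 1, 10000)
  s <- c(compute_ror(t), compute_prr(t), compute_ic(t), compute_ebgm(t))
  f <- evaluate_criteria(s, 2)
  expect_false(f[["flag_ror"]])
  expect_false(f[["flag_prr"]])
  # independence: nothing fires
  f0 <- evaluate_criteria(c(compute_ror(contingency(5, 5, 5, 5)),
                            compute_prr(contingency(5, 5, 5, 5)),
                            compute_ic(contingency(5, 5, 5, 5)),
                            compute_ebgm(contingency(5, 5, 5, 5))), 5)
  expect_false(f0[["flag_any"]])
  # undefined statistics can never flag positive
  und <- c(ror_lo95 = NA_real_, prr = NA_real_, chi2 = NA_real_,
           ic025 = NA_real_, ebgm05 = NA_real_)
  expect_false(evaluate_criteria(und, 100)[["flag_any"]])
})

test_that("screens produce one deterministic row per combination", {
  b <- generate_quarter(synth_config(n_reports = 3000, seed = 17), "2018Q1")
  uni <- build_universe(dedup_bundle(b)$bundle)
  scr <- signal_screen(uni)
  expect_equal(nrow(scr), 6)                    # 3 drugs x 2 events
  scr2 <- signal_screen(uni, strata = list(
    list(axis = "route", level = "oral"),
    list(axis = "route", level = "intravenous")))
  expect_equal(nrow(scr2), 18)                  # + 12 route rows
  expect_equal(as.data.frame(scr2[scr2$stratum_axis == "none", ]),
               as.data.frame(scr), ignore_attr = TRUE)  # deterministic
  # route strata restrict the drug flag, not the universe
  oral_row <- scr2[scr2$stratum_level == "oral" &
                     scr2$drug == "ciprofloxacin" &
                     scr2$event == "tendonitis", ]
  all_row <- scr[scr$drug == "ciprofloxacin" & scr$event == "tendonitis", ]
  expect_lte(oral_row$n, all_row$n)
})

test_that("an empty stratum yields undefined markers with false flags", {
  uni <- data.frame(caseid = as.character(1:6), sex = "M",
                    age_group = "18-65",
                    has_ciprofloxacin = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                          FALSE),
                    route_ciprofloxacin = "oral",
                    has_tendonitis = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                       FALSE))
  scr <- signal_screen(uni, strata = list(list(axis = "sex", level = "F")))
  f <- scr[scr$stratum_level == "F", ]
  expect_true(all(is.na(f$ror)))
  expect_false(any(f$flag_any))
})

test_that("sex and age strata recompute the background within the stratum", {
  uni <- data.frame(caseid = as.character(1:12),
                    sex = rep(c("F", "M"), each = 6),
                    age_group = "18-65",
                    has_ciprofloxacin = rep(c(TRUE, TRUE, FALSE), 4),
                    route_ciprofloxacin = "oral",
                    has_tendonitis = rep(c(TRUE, FALSE), 6))
  tF <- build_contingency(uni, "ciprofloxacin", "tendonitis",
                          list(axis = "sex", level = "F"))
  expect_equal(tF$N, 6)                         # stratum's own background
  sub <- uni[uni$sex == "F", ]
  expect_equal(tF$a, sum(sub$has_ciprofloxacin & sub$has_tendonitis))
})
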