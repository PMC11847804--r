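test_that("deduplication keeps the most recent FDA date, then primaryid", {
  demo <- rbind(make_demo("1001", "100", fda_dt = "20200101"),
                make_demo("1002", "100", fda_dt = "20210101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "1002")

  demo <- rbind(make_demo("1002", "100", fda_dt = "20210101"),
                make_demo("1003", "100", fda_dt = "20210101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "1003")

  # numeric, not lexicographic, comparison when primaryids parse as numbers
  demo <- rbind(make_demo("999", "100", fda_dt = "20210101"),
                make_demo("1003", "100", fda_dt = "20210101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "1003")
})

test_that("deduplication is total, idempotent, and keeps singletons", {
  demo <- make_demo(as.character(1:5), as.character(1:5))
  d1 <- deduplicate_reports(demo)
  expect_equal(nrow(d1), 5)
  expect_equal(attr(d1, "removed"), 0L)
  # missing caseid records survive as primaryid-keyed singletons
  demo2 <- rbind(demo, make_demo("6", NA_character_),
                 make_demo("7", NA_character_))
  d2 <- deduplicate_reports(demo2)
  expect_equal(nrow(d2), 7)
  d3 <- deduplicate_reports(d2)
  expect_equal(data.table::as.data.table(d3)[order(primaryid)],
               data.table::as.data.table(d2)[order(primaryid)])
  expect_false(any(duplicated(stats::na.omit(d2$caseid))))
})

test_that("age conversion handles every unit code and bad input", {
  expect_equal(convert_age_to_years(6, "YR"), 6)
  expect_equal(convert_age_to_years(18, "MON"), 1.5)
  expect_equal(convert_age_to_years(36, "WK"), 36 * 7 / 365.25)
  expect_equal(convert_age_to_years(730.5, "DY"), 2)
  expect_equal(convert_age_to_years(8766, "HR"), 1)
  expect_equal(convert_age_to_years(1.5, "DEC"), 15)
  expect_equal(convert_age_to_years(7, NA), 7)     # missing unit: years
  expect_true(is.na(convert_age_to_years(NA, "YR")))
  expect_true(is.na(convert_age_to_years(-1, "YR")))
  expect_true(is.na(convert_age_to_years(5, "XX"))) # unknown unit code
})

test_that("drug matching respects case, role and the match policy", {
  drug <- rbind(make_drug("1", "Sevoflurane"),
                make_drug("2", "SEVOFLURANE", role_code = "C"),
                make_drug("3", "ULTANE (SEVOFLURANE)"),
                make_drug("4", "sevoflurane  "),
                make_drug("5", "NOTSEVOFLURANEX"))
  syn <- c("SEVOFLURANE", "ULTANE")
  expect_setequal(match_drug_reports(drug, syn, roles = "PS"), c("1", "4"))
  expect_setequal(match_drug_reports(drug, syn, roles = c("PS", "C")),
                  c("1", "2", "4"))
  expect_setequal(match_drug_reports(drug, syn, roles = "PS",
                                     policy = "substring"),
                  c("1", "3", "4"))
  # prod_ai matches too
  drug2 <- make_drug("9", "BRANDX", prod_ai = "SEVOFLURANE")
  expect_equal(match_drug_reports(drug2, syn), "9")
})

test_that("build_cohort follows the fixed pipeline order on the tiny fixture", {
  b <- tiny_bundle()
  coh <- build_cohort(b, c("SEVOFLURANE", "ULTANE"), stratum = "pediatric")
  # reports 1 (6y), 2 (18 mo), 3 (17y) qualify; 4 is concomitant-only,
  # 8 matches the drug but has no age
  expect_setequal(coh$report_ids, c("1", "2", "3"))
  expect_equal(coh$n_reports, 3)
  # report 1 PTs [Cough, Cough, Tachycardia] -> 2 pairs after dedup
  expect_equal(coh$n_report_pt_pairs, 2 + 1 + 2)
  expect_equal(coh$flow[["drug_role_matched"]], 4) # 1,2,3,8
  # concomitants: propofol + fentanyl rows
  expect_setequal(toupper(coh$concomitants$drugname),
                  c("PROPOFOL", "FENTANYL"))
})

test_that("empty stratum yields an empty cohort with a warning", {
  b <- faers_bundle(
    demo = rbind(make_demo("1", age_value = 5, age_unit = "YR"),
                 make_demo("2", age_value = 10, age_unit = "YR")),
    drug = rbind(make_drug("1", "SEVOFLURANE"),
                 make_drug("2", "SEVOFLURANE")),
    reac = make_reac(c("1", "2"), "Cough"))
  expect_warning(
    coh <- build_cohort(b, "SEVOFLURANE", stratum = "adult"),
    "empty cohort")
  expect_equal(coh$n_reports, 0)
})

test_that("cohort is monotone in synonyms and stratum width", {
  b <- tiny_bundle()
  narrow <- build_cohort(b, "SEVOFLURANE", stratum = "pediatric")
  wide_syn <- build_cohort(b, c("SEVOFLURANE", "ULTANE"),
                           stratum = "pediatric")
  wide_str <- build_cohort(b, "SEVOFLURANE", stratum = "all")
  expect_true(all(narrow$report_ids %in% wide_syn$report_ids))
  expect_true(all(narrow$report_ids %in% wide_str$report_ids))
})

test_that("cohorts equal a brute-force row-scanning oracle on small bundles", {
  for (seed in c(2, 9)) {
    cfg <- synthetic_config(n_reports = 50, p_target_drug = 0.3,
                            child_fraction = 0.4, seed = seed)
    g <- generate_bundle(cfg)
    for (s in c("pediatric", "adult", "all")) {
      coh <- suppressWarnings(
        build_cohort(g$bundle, cfg$target_synonyms, stratum = s))
      expect_equal(sort(coh$report_ids),
                   oracle_cohort_ids(g$bundle, cfg$target_synonyms, "PS", s),
                   label = paste("seed", seed, s))
    }
  }
})

test_that("descriptive summary conserves counts and uses stated denominators", {
  b <- tiny_bundle()
  coh <- build_cohort(b, c("SEVOFLURANE", "ULTANE"), stratum = "pediatric")
  s <- summarize_cohort(coh, k = 3)
  n <- coh$n_reports
  expect_equal(sum(s[section == "sex"]$count), n)
  agerows <- s[section == "age"]
  expect_equal(sum(agerows$count), n)
  expect_equal(sum(s[section == "outcome"]$count), n)
  # report 1 has HO + DE -> counted once under Death (severity priority)
  expect_equal(s[section == "outcome" & label == "Death"]$count, 1L)
  expect_equal(
    s[section == "outcome" &
        label == "Hospitalization - initial or prolonged"]$count, 0L)
  # percentages: half-up against n
  expect_equal(s[section == "sex" & label == "Female"]$percent,
               pct(2, 3))
  expect_equal(attr(s, "median_age"), stats::median(c(6, 1.5, 17)))
})

test_that("concomitant percentages use total mentions as denominator", {
  cfg <- synthetic_config(n_reports = 300, p_target_drug = 0.3, seed = 4)
  g <- generate_bundle(cfg)
  coh <- build_cohort(g$bundle, cfg$target_synonyms, stratum = "all")
  s <- summarize_cohort(coh)
  conc <- s[section == "concomitant"]
  total <- conc[label == "Total concomitant mentions"]$count
  expect_equal(total, nrow(coh$concomitants))
  top <- conc[label != "Total concomitant mentions"][1]
  expect_equal(top$percent, pct(top$count, total))
})
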