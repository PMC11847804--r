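library(data.table)

# quick record constructors -------------------------------------------------

make_demo <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                      age_value = NA_real_, age_unit = NA_character_,
                      sex = NA_character_, reporter_type = NA_character_,
                      reporter_country = NA_character_) {
  data.table(primaryid = as.character(primaryid),
             caseid = as.character(caseid), fda_dt = fda_dt,
             age_value = age_value, age_unit = age_unit, sex = sex,
             reporter_type = reporter_type,
             reporter_country = reporter_country)
}

make_drug <- function(primaryid, drugname, role_code = "PS", drug_seq = 1L,
                      prod_ai = NA_character_) {
  data.table(primaryid = as.character(primaryid), drug_seq = drug_seq,
             role_code = role_code, drugname = drugname, prod_ai = prod_ai)
}

make_reac <- function(primaryid, pt) {
  data.table(primaryid = as.character(primaryid), pt = pt)
}

# a hand-enumerable 10-report bundle: reports 1..4 carry the target drug as
# PS (report 4 as concomitant only), ages span the pediatric boundary
tiny_bundle <- function() {
  demo <- rbindlist(list(
    make_demo(1, age_value = 6, age_unit = "YR", sex = "M",
              reporter_type = "MD", reporter_country = "US"),
    make_demo(2, age_value = 18, age_unit = "MON", sex = "F",
              reporter_type = "PH", reporter_country = "FR"),
    make_demo(3, age_value = 17, age_unit = "YR", sex = "F",
              reporter_type = "MD", reporter_country = "US"),
    make_demo(4, age_value = 30, age_unit = "YR", sex = "M"),
    make_demo(5, age_value = 2, age_unit = "DEC", sex = "M"),
    make_demo(6, age_value = 10, age_unit = "YR"),
    make_demo(7, age_value = 5, age_unit = "YR", sex = "F"),
    make_demo(8, sex = "M"),                      # missing age
    make_demo(9, age_value = 40, age_unit = "YR"),
    make_demo(10, age_value = 1, age_unit = "YR")
  ))
  drug <- rbindlist(list(
    make_drug(1, "Sevoflurane"),
    make_drug(1, "PROPOFOL", role_code = "C", drug_seq = 2L),
    make_drug(2, "ULTANE"),
    make_drug(2, "FENTANYL", role_code = "SS", drug_seq = 2L),
    make_drug(3, "SEVOFLURANE"),
    make_drug(4, "SEVOFLURANE", role_code = "C"), # concomitant only
    make_drug(4, "PROPOFOL"),
    make_drug(5, "OTHER DRUG"),
    make_drug(6, "OTHER DRUG"),
    make_drug(7, "OTHER DRUG"),
    make_drug(8, "SEVOFLURANE"),                  # matches but age missing
    make_drug(9, "OTHER DRUG"),
    make_drug(10, "OTHER DRUG")
  ))
  reac <- rbindlist(list(
    make_reac(1, c("Cough", "Cough", "Tachycardia")),
    make_reac(2, "Bradycardia"),
    make_reac(3, c("Cough", "Agitation")),
    make_reac(4, "Cough"),
    make_reac(5, "Pyrexia"),
    make_reac(6, "Cough"),
    make_reac(7, c("Pyrexia", "Rash")),
    make_reac(8, "Cough"),
    make_reac(9, "Rash"),
    make_reac(10, "Pyrexia")
  ))
  outc <- data.table(primaryid = c("1", "1", "2", "3", "7"),
                     outcome_code = c("HO", "DE", "LT", "OT", "CA"))
  indi <- data.table(primaryid = c("1", "2", "3"), drug_seq = 1L,
                     indication_pt = c("Anaesthesia", "Anaesthesia",
                                       "General anaesthesia"))
  faers_bundle(demo = demo, drug = drug, reac = reac, outc = outc,
               indi = indi)
}

tiny_mapping <- function() {
  data.table(
    pt = c("Cough", "Tachycardia", "Bradycardia", "Agitation", "Pyrexia",
           "Rash"),
    soc = c("Respiratory", "Cardiac", "Cardiac", "Psychiatric", "General",
            "Skin"))
}

# brute-force cohort oracle: exhaustive row scanning, no joins -------------

oracle_cohort_ids <- function(bundle, synonyms, roles, stratum,
                              pediatric_max = 18) {
  demo <- as.data.frame(bundle$demo)
  # dedup by caseid, latest fda_dt then largest numeric primaryid
  keep <- logical(nrow(demo))
  key <- ifelse(is.na(demo$caseid), paste0("pid", demo$primaryid),
                demo$caseid)
  for (k in unique(key)) {
    rows <- which(key == k)
    dt <- suppressWarnings(as.integer(demo$fda_dt[rows]))
    dt[is.na(dt)] <- -1L
    rows <- rows[dt == max(dt)]
    if (length(rows) > 1) {
      pid <- suppressWarnings(as.numeric(demo$primaryid[rows]))
      rows <- if (anyNA(pid)) rows[which.max(demo$primaryid[rows])]
      else rows[which.max(pid)]
    }
    keep[rows[1]] <- TRUE
  }
  demo <- demo[keep, ]
  drug <- as.data.frame(bundle$drug)
  syn <- toupper(trimws(synonyms))
  hits <- character(0)
  for (i in seq_len(nrow(drug))) {
    nm <- toupper(gsub("\\s+", " ", trimws(drug$drugname[i])))
    ai <- toupper(gsub("\\s+", " ", trimws(drug$prod_ai[i])))
    if ((isTRUE(nm %in% syn) || isTRUE(ai %in% syn)) &&
        drug$role_code[i] %in% roles) {
      hits <- c(hits, drug$primaryid[i])
    }
  }
  demo <- demo[demo$primaryid %in% hits, ]
  fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
           DY = 1 / 365.25, HR = 1 / 8766)
  yrs <- rep(NA_real_, nrow(demo))
  for (i in seq_len(nrow(demo))) {
    if (!is.na(demo$age_value[i])) {
      f <- if (is.na(demo$age_unit[i])) 1 else fac[[demo$age_unit[i]]]
      yrs[i] <- demo$age_value[i] * f
    }
  }
  ids <- switch(stratum,
                pediatric = demo$primaryid[!is.na(yrs) & yrs >= 0 &
                                             yrs < pediatric_max],
                adult = demo$primaryid[!is.na(yrs) & yrs >= pediatric_max],
                all = demo$primaryid)
  sort(ids)
}

# exhaustive two-sided Fisher oracle via choose(), independent of dhyper
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  prob <- vapply(support, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(N, k)
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
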