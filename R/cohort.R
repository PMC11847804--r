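# Cohort construction: case-level deduplication, drug/role matching, age
# stratification, and Table-1-style descriptive summaries.

#' Deduplicate spontaneous reports at the case level
#'
#' FAERS emits a new PRIMARYID every time a case is re-submitted; analysis
#' keeps one report per case. For each CASEID the record with the most recent
#' FDA_DT is retained; ties on FDA_DT are broken by the most recent PRIMARYID
#' (numeric comparison when all primaryids parse as numbers, else
#' lexicographic). Records with a missing CASEID cannot be linked to a case
#' and are retained as singletons keyed by PRIMARYID.
#'
#' @param demo a DEMO `data.table` (see [parse_quarter_table()]).
#' @return the surviving DEMO records, with attribute `"removed"` giving the
#'   number of duplicate records dropped.
#' @export
deduplicate_reports <- function(demo) {
  demo <- data.table::as.data.table(demo)
  if (nrow(demo) == 0) {
    data.table::setattr(demo, "removed", 0L)
    return(demo)
  }
  d <- data.table::copy(demo)
  d[, `:=`(
    .case_key = data.table::fifelse(is.na(caseid), paste0("\r.pid:", primaryid),
                                    caseid),
    .dt_key = parse_fda_dt(fda_dt)
  )]
  d[is.na(.dt_key), .dt_key := -1L]
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  d[, .pid_key := if (anyNA(pid_num)) xtfrm(primaryid) else pid_num]
  data.table::setorder(d, .case_key, -.dt_key, -.pid_key)
  keep <- !duplicated(d$.case_key)
  out <- d[keep][, c(".case_key", ".dt_key", ".pid_key") := NULL]
  data.table::setattr(out, "removed", nrow(demo) - nrow(out))
  out[]
}

#' Convert a reported age to years
#'
#' Harmonizes the FAERS age unit codes: `YR` (years), `DEC` (decades), `MON`
#' (months), `WK` (weeks), `DY` (days), `HR` (hours). Weeks/days/hours use the
#' Julian year (365.25 days); a month is 1/12 year. A present value with a
#' missing unit is taken as years (the dominant convention in the database).
#'
#' @param age_value numeric vector of reported ages (`NA` allowed).
#' @param age_unit character vector of unit codes (`NA` allowed).
#' @return numeric vector of ages in years; `NA` where the value is missing,
#'   negative, or the unit code is unknown.
#' @export
#' @examples
#' convert_age_to_years(c(6, 18, 36), c("YR", "MON", "WK"))
convert_age_to_years <- function(age_value, age_unit) {
  age_unit <- toupper(age_unit)
  factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
              DY = 1 / 365.25, HR = 1 / 8766)[age_unit]
  factor[is.na(age_unit)] <- 1 # missing unit, present value: assume years
  out <- age_value * unname(factor)
  out[!is.na(age_value) & age_value < 0] <- NA_real_
  out
}

#' Normalize a drug name for matching
#'
#' Uppercases, trims, and collapses internal whitespace. No further surgery:
#' dots and slash-delimited content are kept verbatim, so `"ULTANE
#' (SEVOFLURANE)"` is a distinct exact token from `"ULTANE"`.
#'
#' @param x character vector of verbatim drug names.
#' @return normalized names.
#' @export
normalize_drug_name <- function(x) norm_key(x)

#' Identify reports containing a drug of interest
#'
#' A report qualifies when any of its drug rows has a role code in `roles` and
#' a normalized `drugname` or `prod_ai` matching one of the synonyms. Under
#' the default `"exact"` policy the whole normalized name must equal a
#' synonym; under `"substring"` a synonym matching at word boundaries inside
#' the name suffices (so `"ULTANE (SEVOFLURANE)"` matches synonym
#' `"SEVOFLURANE"`).
#'
#' @param drug a DRUG `data.table`.
#' @param synonyms character vector of generic/brand names (any case).
#' @param roles character vector of FAERS role codes to accept
#'   (default `"PS"`, primary suspect).
#' @param policy `"exact"` (default) or `"substring"`.
#' @return character vector of qualifying primaryids (unique, in first-seen
#'   order).
#' @export
match_drug_reports <- function(drug, synonyms, roles = "PS",
                               policy = c("exact", "substring")) {
  policy <- match.arg(policy)
  stopifnot(length(synonyms) > 0)
  drug <- data.table::as.data.table(drug)
  if (nrow(drug) == 0) return(character(0))
  syn <- unique(norm_key(synonyms))
  name_hit <- .name_matches(drug$drugname, syn, policy)
  if ("prod_ai" %in% names(drug)) {
    name_hit <- name_hit | .name_matches(drug$prod_ai, syn, policy)
  }
  hit <- name_hit & drug$role_code %in% roles
  unique(drug$primaryid[hit])
}

.name_matches <- function(names_raw, syn, policy) {
  keys <- norm_key(names_raw)
  if (policy == "exact") {
    !is.na(keys) & keys %in% syn
  } else {
    patt <- paste0("\\b(", paste(.regex_escape(syn), collapse = "|"), ")\\b")
    !is.na(keys) & grepl(patt, keys, perl = TRUE)
  }
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Build a drug cohort from a FAERS bundle
#'
#' Fixed pipeline order: case-level deduplication, then drug/role matching,
#' then age-stratum filtering, then joining of reactions (with within-report
#' PT deduplication), outcomes, indications and concomitant drug rows.
#' `pediatric` means age in years in `[0, 18)`; `adult` means `>= 18`; reports
#' with missing or invalid age are excluded from both age-defined strata (but
#' kept under `stratum = "all"`).
#'
#' @param bundle a [faers_bundle()].
#' @param synonyms drug synonyms, as in [match_drug_reports()].
#' @param roles role codes defining suspect rows (default `"PS"`).
#' @param stratum `"pediatric"`, `"adult"` or `"all"`.
#' @param policy name-match policy, see [match_drug_reports()].
#' @param pediatric_max upper age bound (exclusive, years) of the pediatric
#'   stratum; default 18.
#' @return a `faers_cohort`: list with `report_ids`, `stratum`, `demo`
#'   (surviving demographics with `age_years`), `pairs` (deduplicated
#'   report-PT pairs), `outc`, `indi`, `concomitants` (non-suspect drug rows
#'   of matched reports), `n_reports`, `n_report_pt_pairs`, and `flow`
#'   (report counts after each pipeline stage).
#' @export
build_cohort <- function(bundle, synonyms, roles = "PS",
                         stratum = c("pediatric", "adult", "all"),
                         policy = c("exact", "substring"),
                         pediatric_max = 18) {
  stratum <- match.arg(stratum)
  policy <- match.arg(policy)
  stopifnot(inherits(bundle, "faers_bundle"))

  demo <- deduplicate_reports(bundle$demo)
  n_dedup <- nrow(demo)
  demo[, age_years := convert_age_to_years(age_value, age_unit)]

  matched_ids <- match_drug_reports(bundle$drug, synonyms, roles, policy)
  demo_m <- demo[primaryid %in% matched_ids]
  n_matched <- nrow(demo_m)

  demo_s <- switch(stratum,
    pediatric = demo_m[!is.na(age_years) & age_years >= 0 &
                         age_years < pediatric_max],
    adult     = demo_m[!is.na(age_years) & age_years >= pediatric_max],
    all       = demo_m
  )
  ids <- demo_s$primaryid
  if (length(ids) == 0) {
    warning("build_cohort(): empty cohort for stratum '", stratum, "'")
  }

  # reactions: within-report PT dedup (case-insensitive on normalized PT)
  reac <- data.table::as.data.table(bundle$reac)[primaryid %in% ids]
  if (nrow(reac)) {
    reac[, pt := squish(pt)]
    reac <- reac[!duplicated(data.table::data.table(primaryid, norm_key(pt)))]
  }

  outc <- data.table::as.data.table(bundle$outc)[primaryid %in% ids]
  indi <- data.table::as.data.table(bundle$indi)[primaryid %in% ids]

  # concomitants: drug rows on matched reports that are not suspect rows of
  # the drug of interest
  drug <- data.table::as.data.table(bundle$drug)[primaryid %in% ids]
  conc <- drug[0]
  if (nrow(drug)) {
    syn <- unique(norm_key(synonyms))
    is_target <- .name_matches(drug$drugname, syn, policy)
    if ("prod_ai" %in% names(drug)) {
      is_target <- is_target | .name_matches(drug$prod_ai, syn, policy)
    }
    conc <- drug[!(is_target & role_code %in% roles)]
  }

  structure(list(
    report_ids = ids,
    stratum = stratum,
    drug_synonyms = unique(norm_key(synonyms)),
    demo = demo_s,
    pairs = reac[, .(primaryid, pt)],
    outc = outc,
    indi = indi,
    concomitants = conc,
    n_reports = length(ids),
    n_report_pt_pairs = nrow(reac),
    flow = c(demo_rows = nrow(bundle$demo), deduplicated = n_dedup,
             drug_role_matched = n_matched, in_stratum = length(ids))
  ), class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort> stratum:", x$stratum, "\n",
      " reports:", x$n_reports,
      " report-PT pairs:", x$n_report_pt_pairs, "\n")
  invisible(x)
}

# one outcome category per report: worst outcome by severity priority;
# CA (congenital anomaly) and RI (required intervention) fold into OT
.outcome_priority <- c("DE", "LT", "HO", "DS", "OT")
.outcome_labels <- c(
  DE = "Death", LT = "Life-threatening",
  HO = "Hospitalization - initial or prolonged", DS = "Disability",
  OT = "Other serious outcome")

#' Descriptive summary of a cohort (Table-1 style)
#'
#' Produces counts and percentages for sex, age bands, reporter type, top-k
#' indications, outcomes (one category per report, worst-first severity
#' priority Death > Life-threatening > Hospitalization > Disability > Other;
#' congenital-anomaly and required-intervention codes fold into Other), top-k
#' reporter countries, events per reporting year, and top-k concomitant
#' drugs. Sex/age/reporter/outcome/country percentages use the cohort size as
#' denominator; concomitant percentages use the total number of concomitant
#' mentions (drug rows, not distinct reports). Percentages are rounded
#' half-up to 2 decimals.
#'
#' @param cohort a [build_cohort()] result.
#' @param k how many top categories for indications, countries and
#'   concomitants (default 10).
#' @param age_breaks interior age-band cut points in years (default 7 and 18).
#' @return a `data.table` with columns `section`, `label`, `count`, `percent`
#'   plus a `"median_age"` attribute.
#' @export
summarize_cohort <- function(cohort, k = 10, age_breaks = c(7, 18)) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (cohort$n_reports == 0) stop("summarize_cohort(): empty cohort")
  n <- cohort$n_reports
  demo <- cohort$demo
  rows <- list()
  add <- function(section, label, count, denom) {
    rows[[length(rows) + 1]] <<- data.table::data.table(
      section = section, label = label, count = as.integer(count),
      percent = pct(count, denom))
  }

  add("n", "Number of reports", n, n)

  sex <- factor(data.table::fifelse(demo$sex %in% c("F", "M"), demo$sex,
                                    "Missing"),
                levels = c("F", "M", "Missing"))
  for (lv in levels(sex)) {
    add("sex", c(F = "Female", M = "Male", Missing = "Missing")[[lv]],
        sum(sex == lv), n)
  }

  ages <- demo$age_years
  brk <- sort(unique(age_breaks))
  cuts <- c(0, brk, Inf)
  labs <- character(length(cuts) - 1)
  for (i in seq_along(labs)) {
    labs[i] <- if (i == 1) paste0("<", cuts[2])
    else if (is.infinite(cuts[i + 1])) paste0(">=", cuts[i])
    else paste0(cuts[i], "-<", cuts[i + 1])
  }
  band <- cut(ages, cuts, labels = labs, right = FALSE)
  for (i in seq_along(labs)) {
    cnt <- sum(band == labs[i], na.rm = TRUE)
    if (cnt > 0) add("age", labs[i], cnt, n)
  }
  if (any(is.na(ages))) add("age", "Missing", sum(is.na(ages)), n)

  rep_lab <- c(MD = "Physician", PH = "Pharmacist",
               OT = "Other health-professional", CN = "Consumer",
               LW = "Lawyer")
  rt <- demo$reporter_type
  for (code in names(rep_lab)) {
    cnt <- sum(!is.na(rt) & rt == code)
    if (cnt > 0) add("reporter", rep_lab[[code]], cnt, n)
  }
  other_rt <- sum(!is.na(rt) & !rt %in% names(rep_lab))
  if (other_rt > 0) add("reporter", "Other", other_rt, n)
  if (anyNA(rt)) add("reporter", "Missing", sum(is.na(rt)), n)

  if (nrow(cohort$indi)) {
    topi <- cohort$indi[!is.na(indication_pt),
                        .N, by = .(label = indication_pt)][order(-N)]
    for (i in seq_len(min(k, nrow(topi)))) {
      add("indication", topi$label[i], topi$N[i], n)
    }
  }

  # one outcome category per report via severity priority
  if (nrow(cohort$outc)) {
    oc <- data.table::copy(cohort$outc)
    oc[, outcome_code := data.table::fifelse(
      outcome_code %in% c("CA", "RI"), "OT", outcome_code)]
    oc <- oc[outcome_code %in% .outcome_priority]
    oc[, pri := match(outcome_code, .outcome_priority)]
    worst <- oc[, .(code = outcome_code[which.min(pri)]), by = primaryid]
  } else {
    worst <- data.table::data.table(primaryid = character(0),
                                    code = character(0))
  }
  for (code in .outcome_priority) {
    add("outcome", .outcome_labels[[code]], sum(worst$code == code), n)
  }
  add("outcome", "No outcome reported", n - nrow(worst), n)

  ctry <- demo[!is.na(reporter_country), .N,
               by = .(label = reporter_country)][order(-N)]
  for (i in seq_len(min(k, nrow(ctry)))) {
    add("country", ctry$label[i], ctry$N[i], n)
  }

  yr <- parse_fda_dt(demo$fda_dt) %/% 10000L
  ytab <- table(yr)
  for (y in names(ytab)) add("year", y, ytab[[y]], n)

  n_conc <- nrow(cohort$concomitants)
  if (n_conc > 0) {
    topc <- cohort$concomitants[!is.na(drugname), .N,
                                by = .(label = norm_key(drugname))][order(-N)]
    add("concomitant", "Total concomitant mentions", n_conc, n_conc)
    for (i in seq_len(min(k, nrow(topc)))) {
      add("concomitant", topc$label[i], topc$N[i], n_conc)
    }
  }

  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "median_age",
                      stats::median(ages, na.rm = TRUE))
  out[]
}

#' Stratum-wide report-PT background pairs
#'
#' The background for disproportionality statistics: deduplicated reports of
#' the requested age stratum (all drugs), joined to their reactions with
#' within-report PT deduplication.
#'
#' @param bundle a [faers_bundle()].
#' @param stratum `"pediatric"`, `"adult"` or `"all"`.
#' @param pediatric_max pediatric upper age bound (exclusive), default 18.
#' @return `data.table(primaryid, pt)` of background pairs.
#' @export
stratum_pairs <- function(bundle, stratum = c("pediatric", "adult", "all"),
                          pediatric_max = 18) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(bundle, "faers_bundle"))
  demo <- deduplicate_reports(bundle$demo)
  demo[, age_years := convert_age_to_years(age_value, age_unit)]
  ids <- switch(stratum,
    pediatric = demo[!is.na(age_years) & age_years >= 0 &
                       age_years < pediatric_max, primaryid],
    adult     = demo[!is.na(age_years) & age_years >= pediatric_max,
                     primaryid],
    all       = demo$primaryid
  )
  reac <- data.table::as.data.table(bundle$reac)[primaryid %in% ids]
  if (nrow(reac)) {
    reac[, pt := squish(pt)]
    reac <- reac[!duplicated(data.table::data.table(primaryid, norm_key(pt)))]
  }
  reac[, .(primaryid, pt)]
}
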