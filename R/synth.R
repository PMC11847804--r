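# Seeded generator of FAERS-like quarterly bundles with known injected
# drug-event association strengths, duplicate cases, missingness and mixed
# age units, so the whole pipeline can be validated against ground truth
# without any external download.

#' Build a synthetic PT vocabulary
#'
#' Deterministic vocabulary of preferred terms with system-organ-class
#' assignment and background per-report occurrence probabilities
#' (log-spaced between `p_range[1]` and `p_range[2]`, so the vocabulary
#' contains both rare and common events, as spontaneous-report databases do).
#' A dedicated filler term (background probability 0) absorbs reports that
#' would otherwise carry no event.
#'
#' @param n_pt number of regular PTs (default 53).
#' @param n_soc number of SOCs to spread them over (default 10).
#' @param p_range range of background per-report probabilities
#'   (default 0.002 to 0.04).
#' @return `data.table(pt, soc, p_pt, is_filler)`.
#' @export
synthetic_pt_vocabulary <- function(n_pt = 53, n_soc = 10,
                                    p_range = c(0.002, 0.04)) {
  stopifnot(n_pt >= 1, n_soc >= 1)
  pt <- sprintf("Synthetic event %03d", seq_len(n_pt))
  soc <- sprintf("Synthetic SOC %02d", rep_len(seq_len(n_soc), n_pt))
  p_pt <- exp(seq(log(p_range[2]), log(p_range[1]), length.out = n_pt))
  out <- data.table::data.table(pt = pt, soc = soc, p_pt = p_pt,
                                is_filler = FALSE)
  data.table::rbindlist(list(out, data.table::data.table(
    pt = "No adverse event described", soc = "Synthetic SOC 01",
    p_pt = 0, is_filler = TRUE)))
}

#' Extract the PT-to-SOC mapping of a vocabulary
#'
#' @param vocabulary a [synthetic_pt_vocabulary()]-style table.
#' @return `data.table(pt, soc)` suitable for [evaluate_signals()].
#' @export
soc_mapping <- function(vocabulary) {
  data.table::as.data.table(vocabulary)[, .(pt, soc)]
}

#' Configuration for the synthetic report generator
#'
#' The injected association strength is an odds multiplier: for a PT with
#' background probability p and multiplier RR, target-drug reports draw the
#' PT with probability p' = RR p / (1 - p + RR p), which makes the
#' report-level odds ratio exactly RR.
#'
#' @param n_reports number of unique cases to generate.
#' @param p_target_drug probability that a report carries the target drug as
#'   primary suspect (default 0.02).
#' @param pt_vocabulary PT vocabulary table, see [synthetic_pt_vocabulary()].
#' @param signal_map named list `pt -> RR`; each RR is a positive scalar or a
#'   named vector `c(child = ..., adult = ...)` for stratum-specific
#'   injection. PTs not listed have RR 1 (no association).
#' @param child_fraction fraction of reports in the pediatric stratum
#'   (default 0.1, reflecting the minority pediatric share of
#'   spontaneous-report databases).
#' @param duplicate_rate fraction of cases additionally emitted as an older
#'   duplicate version (default 0.1). Half the duplicates carry an earlier
#'   FDA date, half the same date with a lower primaryid, exercising both
#'   deduplication tie-break branches.
#' @param missing_age_rate,missing_sex_rate per-report missingness (defaults
#'   0.03 and 0.1).
#' @param conc_lambda Poisson mean of concomitant drug rows per report
#'   (default 1.2).
#' @param target_synonyms drug names written (in rotation, mixed case) on
#'   target suspect rows.
#' @param years calendar years over which FDA dates are drawn
#'   (default 2004:2024).
#' @param seed RNG seed; generation is bit-reproducible per seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports,
                             p_target_drug = 0.02,
                             pt_vocabulary = synthetic_pt_vocabulary(),
                             signal_map = list(),
                             child_fraction = 0.1,
                             duplicate_rate = 0.1,
                             missing_age_rate = 0.03,
                             missing_sex_rate = 0.1,
                             conc_lambda = 1.2,
                             target_synonyms = c("SEVOFLURANE", "Ultane",
                                                 "SEVORANE"),
                             years = 2004:2024,
                             seed = 1) {
  vocab <- data.table::as.data.table(pt_vocabulary)
  stopifnot(n_reports >= 1,
            p_target_drug >= 0, p_target_drug <= 1,
            child_fraction >= 0, child_fraction <= 1,
            duplicate_rate >= 0, duplicate_rate <= 0.5,
            all(c("pt", "soc", "p_pt") %in% names(vocab)),
            all(vocab$p_pt >= 0 & vocab$p_pt < 1))
  if (!"is_filler" %in% names(vocab)) vocab[, is_filler := p_pt == 0]
  rr <- .normalize_signal_map(signal_map, vocab$pt)
  # feasibility: the exact-odds adjustment must keep p' below 1
  p_adj <- .odds_adjust(vocab$p_pt, pmax(rr$child, rr$adult))
  if (any(!is.finite(p_adj) | p_adj > 0.99)) {
    bad <- vocab$pt[!is.finite(p_adj) | p_adj > 0.99]
    stop("infeasible synthetic config: adjusted probability exceeds 0.99 ",
         "for PT(s): ", paste(bad, collapse = "; "), call. = FALSE)
  }
  structure(list(
    n_reports = n_reports, p_target_drug = p_target_drug,
    pt_vocabulary = vocab, rr_child = rr$child, rr_adult = rr$adult,
    child_fraction = child_fraction, duplicate_rate = duplicate_rate,
    missing_age_rate = missing_age_rate, missing_sex_rate = missing_sex_rate,
    conc_lambda = conc_lambda, target_synonyms = target_synonyms,
    years = years, seed = seed
  ), class = "synthetic_config")
}

# signal_map (named list pt -> scalar or c(child=, adult=)) to per-PT vectors
.normalize_signal_map <- function(signal_map, pts) {
  child <- adult <- rep(1, length(pts))
  if (length(signal_map)) {
    if (is.null(names(signal_map)) || any(names(signal_map) == "")) {
      stop("signal_map must be a named list (PT -> odds multiplier)",
           call. = FALSE)
    }
    idx <- match(norm_key(names(signal_map)), norm_key(pts))
    if (anyNA(idx)) {
      stop("signal_map PT(s) not in vocabulary: ",
           paste(names(signal_map)[is.na(idx)], collapse = "; "),
           call. = FALSE)
    }
    for (i in seq_along(signal_map)) {
      v <- signal_map[[i]]
      stopifnot(all(v > 0))
      if (length(v) == 1 && is.null(names(v))) {
        child[idx[i]] <- adult[idx[i]] <- v
      } else {
        child[idx[i]] <- v[["child"]] %||% unname(v["child"])
        adult[idx[i]] <- v[["adult"]] %||% unname(v["adult"])
      }
    }
  }
  list(child = child, adult = adult)
}

# exact-odds probability adjustment: odds(p') = RR * odds(p)
.odds_adjust <- function(p, rr) {
  rr * p / (1 - p + rr * p)
}

.bg_drug_pool <- sprintf("BACKGROUND DRUG %02d", 1:30)
.conc_pool <- c("PROPOFOL", "FENTANYL", "MIDAZOLAM", "ROCURONIUM",
                "ACETAMINOPHEN", "ONDANSETRON", "DEXAMETHASONE",
                "ATROPINE", "KETAMINE", "MORPHINE", "IBUPROFEN",
                "CEFAZOLIN", "LIDOCAINE", "EPINEPHRINE", "SUXAMETHONIUM")
.country_pool <- c("US", "FR", "RU", "JP", "DE", "GB", "CN", "BR")
.indication_target <- c("Anaesthesia", "General anaesthesia",
                        "Induction of anaesthesia")
.indication_bg <- c("Hypertension", "Pain", "Infection", "Epilepsy",
                    "Asthma", "Depression")

#' Generate a synthetic FAERS-like bundle with ground truth
#'
#' Draws, per report: target-drug exposure, age stratum and demographics
#' (mixed age units, missingness), each PT independently at its background
#' probability — or at the exact-odds adjusted probability for injected PTs
#' on target-drug reports — plus outcomes, indications and concomitant drug
#' rows. Reports left with no PT are redrawn once and then given the filler
#' PT. A configurable fraction of cases is additionally emitted as an older
#' duplicate record that correct deduplication must remove. Generation is
#' bit-reproducible for a given seed and leaves the caller's RNG state
#' untouched.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory: when supplied, the bundle is also
#'   written as per-quarter FAERS ASCII files (quarter labels derived from
#'   each report's FDA date) via [write_quarter_table()].
#' @return list with `bundle` (a [faers_bundle()]), `truth` (ground-truth
#'   list: `n_reports`, per-PT/stratum realized exposure-event counts and
#'   odds ratios, injected multipliers, duplicate count) and, when `out_dir`
#'   is given, `dir` and `quarters`.
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_private_seed(config$seed, .generate_bundle_impl(config, out_dir))
}

.generate_bundle_impl <- function(cfg, out_dir) {
  n <- cfg$n_reports
  vocab <- cfg$pt_vocabulary
  J <- nrow(vocab)

  caseid <- sprintf("%d", 10000000L + seq_len(n))
  primaryid <- paste0(caseid, "2") # version suffix; duplicates get "1"

  exposed <- stats::runif(n) < cfg$p_target_drug
  child <- stats::runif(n) < cfg$child_fraction

  # ages: children uniform on [0, 17.5), adults on [18, 90); units mixed so
  # the year conversion is exercised on every run
  age_years <- data.table::fifelse(child, stats::runif(n, 0, 17.5),
                                   stats::runif(n, 18, 90))
  unit <- character(n)
  unit[child] <- sample(c("YR", "MON", "WK", "DY", "DEC"), sum(child),
                        replace = TRUE, prob = c(.55, .25, .07, .08, .05))
  unit[!child] <- sample(c("YR", "DEC", "MON"), sum(!child),
                         replace = TRUE, prob = c(.88, .1, .02))
  fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25)
  age_value <- round(age_years / fac[unit], 2)
  miss_age <- stats::runif(n) < cfg$missing_age_rate
  age_value[miss_age] <- NA_real_
  unit[miss_age] <- NA_character_
  # realized stratum as a correct pipeline will recover it
  age_rec <- convert_age_to_years(age_value, unit)
  stratum <- data.table::fifelse(is.na(age_rec), "none",
                                 data.table::fifelse(age_rec < 18,
                                                     "child", "adult"))

  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(.47, .53))
  sex[stats::runif(n) < cfg$missing_sex_rate] <- NA_character_
  reporter <- sample(c("MD", "PH", "OT", "CN", NA), n, replace = TRUE,
                     prob = c(.40, .08, .22, .15, .15))
  country <- sample(.country_pool, n, replace = TRUE,
                    prob = c(.30, .15, .10, .10, .10, .10, .08, .07))
  yr <- sample(cfg$years, n, replace = TRUE)
  fda_dt <- sprintf("%04d%02d%02d", yr,
                    sample(1:12, n, replace = TRUE),
                    sample(1:28, n, replace = TRUE))

  # per-PT Bernoulli event matrix with exact-odds injection for exposed rows
  rr_row <- function(j) {
    rr <- rep(1, n)
    rr[exposed & stratum == "child"] <- cfg$rr_child[j]
    rr[exposed & stratum != "child"] <- cfg$rr_adult[j]
    rr
  }
  draw_events <- function(rows) {
    hit <- matrix(FALSE, length(rows), J)
    for (j in seq_len(J)) {
      p <- .odds_adjust(vocab$p_pt[j], rr_row(j)[rows])
      hit[, j] <- stats::runif(length(rows)) < p
    }
    hit
  }
  hits <- draw_events(seq_len(n))
  none <- which(rowSums(hits) == 0)
  if (length(none)) { # one redraw, then the filler PT
    hits[none, ] <- draw_events(none)
    still <- none[rowSums(hits[none, , drop = FALSE]) == 0]
    filler_j <- if (any(vocab$is_filler)) which(vocab$is_filler)[1] else J
    hits[still, filler_j] <- TRUE
  }

  idx <- which(hits, arr.ind = TRUE)
  reac <- data.table::data.table(primaryid = primaryid[idx[, 1]],
                                 pt = vocab$pt[idx[, 2]])
  data.table::setorder(reac, primaryid, pt)

  # DRUG: one suspect row per report plus concomitants
  syn_rot <- rep_len(cfg$target_synonyms, n)
  ps_name <- data.table::fifelse(exposed, syn_rot,
                                 sample(.bg_drug_pool, n, replace = TRUE))
  n_conc <- stats::rpois(n, cfg$conc_lambda)
  conc_rep <- rep(seq_len(n), n_conc)
  drug <- data.table::rbindlist(list(
    data.table::data.table(
      primaryid = primaryid, drug_seq = 1L, role_code = "PS",
      drugname = ps_name,
      prod_ai = data.table::fifelse(exposed, "SEVOFLURANE", NA_character_)),
    data.table::data.table(
      primaryid = primaryid[conc_rep],
      drug_seq = unlist(lapply(n_conc[n_conc > 0], function(k) 1L + seq_len(k))),
      role_code = sample(c("C", "SS", "I"), length(conc_rep), replace = TRUE,
                         prob = c(.7, .2, .1)),
      drugname = sample(.conc_pool, length(conc_rep), replace = TRUE),
      prod_ai = NA_character_)
  ))
  data.table::setorder(drug, primaryid, drug_seq)

  # OUTC: zero, one or two severity codes per report
  has1 <- stats::runif(n) < 0.75
  code1 <- sample(c("DE", "LT", "HO", "DS", "CA", "RI", "OT"), n,
                  replace = TRUE, prob = c(.05, .07, .30, .01, .01, .02, .54))
  has2 <- has1 & stats::runif(n) < 0.2
  code2 <- sample(c("LT", "HO", "OT"), n, replace = TRUE)
  outc <- data.table::rbindlist(list(
    data.table::data.table(primaryid = primaryid[has1],
                           outcome_code = code1[has1]),
    data.table::data.table(primaryid = primaryid[has2 & code2 != code1],
                           outcome_code = code2[has2 & code2 != code1])
  ))
  data.table::setorder(outc, primaryid, outcome_code)

  indi <- data.table::data.table(
    primaryid = primaryid, drug_seq = 1L,
    indication_pt = data.table::fifelse(
      exposed,
      sample(.indication_target, n, replace = TRUE, prob = c(.45, .35, .2)),
      sample(.indication_bg, n, replace = TRUE)))

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    age_value = age_value, age_unit = unit, sex = sex,
    reporter_type = reporter, reporter_country = country)

  # duplicates: same caseid, fresh (lower-version) primaryid, FDA date
  # perturbed downward for half, identical for the other half
  n_dup <- round(cfg$duplicate_rate * n)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    older <- seq_along(di) %% 2L == 1L
    dup_dt <- fda_dt[di]
    dup_yr <- pmax(as.integer(substr(dup_dt, 1, 4)) - 1L, min(cfg$years) - 1L)
    dup_dt[older] <- paste0(sprintf("%04d", dup_yr[older]),
                            substr(dup_dt[older], 5, 8))
    dup_demo <- demo[di]
    dup_demo[, `:=`(primaryid = paste0(caseid, "1"), fda_dt = dup_dt)]
    demo <- data.table::rbindlist(list(demo, dup_demo))
    # duplicate versions carry their own suspect and first reaction rows
    dup_drug <- data.table::data.table(
      primaryid = paste0(caseid[di], "1"), drug_seq = 1L, role_code = "PS",
      drugname = ps_name[di],
      prod_ai = data.table::fifelse(exposed[di], "SEVOFLURANE", NA_character_))
    first_reac <- reac[!duplicated(primaryid)]
    m <- match(primaryid[di], first_reac$primaryid)
    dup_reac <- data.table::data.table(
      primaryid = paste0(caseid[di], "1"), pt = first_reac$pt[m])[!is.na(pt)]
    drug <- data.table::rbindlist(list(drug, dup_drug))
    reac <- data.table::rbindlist(list(reac, dup_reac))
    data.table::setorder(demo, primaryid)
    data.table::setorder(drug, primaryid, drug_seq)
    data.table::setorder(reac, primaryid, pt)
  }

  truth <- .ground_truth(cfg, vocab, hits, exposed, stratum, n_dup)

  bundle <- faers_bundle(demo = demo, drug = drug, reac = reac, outc = outc,
                         indi = indi,
                         provenance = sprintf("synthetic(seed=%d)", cfg$seed))
  out <- list(bundle = bundle, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    qtr <- function(dt) {
      y <- substr(dt, 1, 4)
      q <- (as.integer(substr(dt, 5, 6)) - 1L) %/% 3L + 1L
      paste0(y, "q", q)
    }
    demo_q <- qtr(demo$fda_dt)
    report_q <- stats::setNames(demo_q, demo$primaryid)
    quarters <- sort(unique(demo_q))
    for (q in quarters) {
      ids_q <- demo$primaryid[demo_q == q]
      write_quarter_table(demo[demo_q == q], "DEMO",
                          file.path(out_dir, paste0("demo", q, ".txt")))
      write_quarter_table(drug[primaryid %in% ids_q], "DRUG",
                          file.path(out_dir, paste0("drug", q, ".txt")))
      write_quarter_table(reac[primaryid %in% ids_q], "REAC",
                          file.path(out_dir, paste0("reac", q, ".txt")))
      write_quarter_table(outc[primaryid %in% ids_q], "OUTC",
                          file.path(out_dir, paste0("outc", q, ".txt")))
      write_quarter_table(indi[primaryid %in% ids_q], "INDI",
                          file.path(out_dir, paste0("indi", q, ".txt")))
    }
    out$dir <- out_dir
    out$quarters <- quarters
  }
  out
}

# realized per-PT exposure-event counts and odds ratios, per stratum
.ground_truth <- function(cfg, vocab, hits, exposed, stratum, n_dup) {
  strata <- list(child = stratum == "child", adult = stratum == "adult",
                 all = rep(TRUE, length(stratum)))
  per_pt <- data.table::rbindlist(lapply(names(strata), function(s) {
    in_s <- strata[[s]]
    x_e <- colSums(hits[in_s & exposed, , drop = FALSE])
    x_u <- colSums(hits[in_s & !exposed, , drop = FALSE])
    n_e <- sum(in_s & exposed)
    n_u <- sum(in_s & !exposed)
    data.table::data.table(
      stratum = s, pt = vocab$pt, is_filler = vocab$is_filler,
      rr_injected = if (s == "adult") cfg$rr_adult else if (s == "child")
        cfg$rr_child else pmax(cfg$rr_child, cfg$rr_adult),
      x_exposed = x_e, n_exposed = n_e,
      x_unexposed = x_u, n_unexposed = n_u,
      realized_or = (x_e / pmax(n_e - x_e, 1)) /
        pmax(x_u / pmax(n_u - x_u, 1), .Machine$double.eps))
  }))
  list(n_reports = cfg$n_reports, n_duplicates = n_dup,
       rr_child = stats::setNames(cfg$rr_child, vocab$pt),
       rr_adult = stats::setNames(cfg$rr_adult, vocab$pt),
       per_pt = per_pt)
}

#' Run the pipeline on a synthetic bundle and compare with ground truth
#'
#' Builds the target-drug cohort and stratum background from the generated
#' bundle, evaluates the four-algorithm signal gate, and reports recovery of
#' the injected associations: per injected PT the estimated ROR, whether its
#' 95% CI covers the injected odds multiplier, and the gate outcome; plus the
#' gate outcome over the null PTs (the filler term, whose occurrence is
#' driven by the zero-event redraw rather than a background probability, is
#' excluded from the null set).
#'
#' @param bundle a [faers_bundle()] from [generate_bundle()].
#' @param truth the matching ground-truth list.
#' @param config the [synthetic_config()] used for generation.
#' @param stratum stratum to evaluate (default `"pediatric"`).
#' @param criteria a [signal_criteria()].
#' @return list with `results` (per-PT [evaluate_signals()] rows joined to
#'   the injected multipliers and CI-coverage flags), `sensitivity`
#'   (flagged fraction of injected PTs), `n_injected_flagged`,
#'   `false_flag_rate` and `n_null_flagged` (over all null PTs in the
#'   vocabulary), and `n_null`.
#' @export
recover_parameters <- function(bundle, truth, config,
                               stratum = c("pediatric", "adult", "all"),
                               criteria = signal_criteria()) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(config, "synthetic_config"))
  vocab <- config$pt_vocabulary
  rr <- if (stratum == "adult") config$rr_adult else config$rr_child
  mapping <- soc_mapping(vocab)

  cohort <- build_cohort(bundle, config$target_synonyms, roles = "PS",
                         stratum = stratum)
  bg <- stratum_pairs(bundle, stratum)
  res <- evaluate_signals(cohort, bg, mapping, criteria)
  res <- res[level == "PT"]
  res[, `:=`(
    rr_injected = rr[match(norm_key(term), norm_key(vocab$pt))],
    is_filler = vocab$is_filler[match(norm_key(term), norm_key(vocab$pt))]
  )]
  res[, ci_covers_rr := !is.na(ror_lower) & ror_lower <= rr_injected &
        ror_upper >= rr_injected]

  injected_pts <- vocab$pt[rr > 1]
  null_pts <- vocab$pt[rr <= 1 & !vocab$is_filler]
  inj <- res[norm_key(term) %in% norm_key(injected_pts)]
  nul <- res[norm_key(term) %in% norm_key(null_pts)]
  n_inj_flag <- sum(inj$overall_signal)
  n_null_flag <- sum(nul$overall_signal)
  list(
    results = res,
    cohort = cohort,
    sensitivity = if (length(injected_pts)) n_inj_flag / length(injected_pts)
    else NA_real_,
    n_injected = length(injected_pts),
    n_injected_flagged = n_inj_flag,
    n_null = length(null_pts),
    n_null_flagged = n_null_flag,
    false_flag_rate = if (length(null_pts)) n_null_flag / length(null_pts)
    else NA_real_
  )
}
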