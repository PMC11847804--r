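# Disproportionality statistics on the four-fold (2x2) contingency table:
#
#                 target event   other events
#   target drug        a              b
#   other drugs        c              d
#
# The counting unit throughout is the (report, PT) pair after within-report
# PT deduplication, so a+b equals the cohort's report-PT pair count.

#' Four-fold contingency table
#'
#' @param a target-drug pairs with the event.
#' @param b target-drug pairs without the event.
#' @param c other-drug pairs with the event.
#' @param d other-drug pairs without the event.
#' @return a `fourfold` object (named list with `a`,`b`,`c`,`d`,`n`).
#' @export
fourfold <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fourfold(): cells must be non-negative integers", call. = FALSE)
  }
  # stored as doubles: margin products in the statistics exceed 32-bit range
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  cat(sprintf("<fourfold> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

.as_fourfold <- function(t) {
  if (inherits(t, "fourfold")) return(t)
  if (is.numeric(t) && length(t) == 4) return(fourfold(t[1], t[2], t[3], t[4]))
  stop("expected a fourfold table or numeric vector c(a, b, c, d)",
       call. = FALSE)
}

#' Reporting odds ratio with Wald 95% CI
#'
#' ROR = (a*d)/(b*c); the interval is computed on the log scale with standard
#' error sqrt(1/a + 1/b + 1/c + 1/d). Any zero cell leaves the statistic
#' undefined (`NA`); no Haldane-style 0.5 correction is applied by default
#' because the minimum-count gate makes sparse tables ineligible anyway.
#'
#' @param t a [fourfold()] table (or numeric `c(a,b,c,d)`).
#' @param correction add 0.5 to every cell when any cell is zero (default
#'   `FALSE`).
#' @return list with `ror`, `lower`, `upper`, `defined`.
#' @export
#' @examples
#' ror_statistic(fourfold(10, 20, 5, 40))
ror_statistic <- function(t, correction = FALSE) {
  t <- .as_fourfold(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!correction) {
      return(list(ror = NA_real_, lower = NA_real_, upper = NA_real_,
                  defined = FALSE))
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror,
       lower = exp(log(ror) - 1.96 * se),
       upper = exp(log(ror) + 1.96 * se),
       defined = TRUE)
}

#' Proportional reporting ratio with chi-squared statistic
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]. The accompanying chi-squared statistic is
#' the usual 2x2 Pearson statistic with expected counts from the margins,
#' optionally (default) with the Yates continuity correction
#' (|O-E| - 0.5)^2 / E.
#'
#' @param t a [fourfold()] table.
#' @param continuity_correction apply Yates correction (default `TRUE`).
#' @return list with `prr`, `chi2`, `defined`.
#' @export
#' @examples
#' prr_statistic(fourfold(10, 20, 5, 40), continuity_correction = FALSE)
prr_statistic <- function(t, continuity_correction = TRUE) {
  t <- .as_fourfold(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  if (a + b == 0 || c + d == 0 || c == 0) {
    return(list(prr = NA_real_, chi2 = NA_real_, defined = FALSE))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  obs <- c(a, b, c, d)
  expd <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / n
  if (any(expd == 0)) {
    chi2 <- NA_real_
  } else {
    cc <- if (continuity_correction) 0.5 else 0
    dev <- pmax(abs(obs - expd) - cc, 0)
    chi2 <- sum(dev^2 / expd)
  }
  list(prr = prr, chi2 = chi2, defined = TRUE)
}

#' BCPNN prior pseudo-counts
#'
#' Priors of the Bayesian confidence propagation neural network information
#' component, following the standard moment-based formulation: marginal
#' pseudo-counts `alpha1`/`beta1` with prior totals `alpha`/`beta`, joint
#' pseudo-count `gamma11`, and the data-dependent joint prior total
#' gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1)),
#' which centres the prior IC at zero.
#'
#' @param alpha1,beta1 marginal pseudo-counts (default 1).
#' @param alpha,beta marginal prior totals (default 2).
#' @param gamma11 joint pseudo-count (default 1).
#' @return a `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha > 0, beta > 0, gamma11 > 0)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
                 gamma11 = gamma11), class = "bcpnn_priors")
}

#' Information component (BCPNN) with lower credibility bound
#'
#' The point estimate is the observed-to-expected information component
#' IC = log2\[ a N / ((a+b)(a+c)) \]. The lower bound IC025 is the
#' moment-based E(IC) - 2 sqrt(V(IC)) under the Dirichlet posterior of the
#' Bayesian confidence propagation neural network.
#'
#' @param t a [fourfold()] table.
#' @param priors a [bcpnn_priors()] object.
#' @return list with `ic` (point estimate; `-Inf` when a = 0), `ic025`,
#'   `e_ic`, `v_ic`, `defined` (`FALSE` when a = 0: the point estimate
#'   degenerates although the posterior moments remain computable).
#' @export
#' @examples
#' bcpnn_statistic(fourfold(10, 20, 5, 40))
bcpnn_statistic <- function(t, priors = bcpnn_priors()) {
  t <- .as_fourfold(t)
  a <- t$a; n <- t$n
  ab <- t$a + t$b; ac <- t$a + t$c
  if (n == 0) stop("bcpnn_statistic(): empty table", call. = FALSE)
  p <- priors
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((ab + p$alpha1) * (ac + p$beta1))
  ic <- if (a == 0 || ab == 0 || ac == 0) -Inf else log2(a * n / (ab * ac))
  e_ic <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                 ((n + gamma) * (ab + p$alpha1) * (ac + p$beta1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
      (n - ab + p$alpha - p$alpha1) / ((ab + p$alpha1) * (1 + n + p$alpha)) +
      (n - ac + p$beta - p$beta1) / ((ac + p$beta1) * (1 + n + p$beta)))
  list(ic = ic, ic025 = e_ic - 2 * sqrt(v_ic), e_ic = e_ic, v_ic = v_ic,
       defined = is.finite(ic))
}

#' Empirical Bayes geometric mean (gamma-Poisson shrinker form)
#'
#' Point estimate in the relative-reporting-ratio form
#' EBGM = a N / ((a+b)(a+c)) — identical on the log2 scale to the information
#' component, EBGM = 2^IC. The lower bound EBGM05 is a one-sided 90% lognormal
#' bound, exp(ln EBGM - 1.64 sqrt(1/a + 1/b + 1/c + 1/d)). The full
#' two-component-gamma mixture shrinker is deliberately not implemented.
#'
#' @param t a [fourfold()] table.
#' @return list with `ebgm`, `ebgm05`, `defined` (`FALSE`, with `ebgm05 = NA`,
#'   when any cell is zero).
#' @export
#' @examples
#' mgps_statistic(fourfold(10, 20, 5, 40))
mgps_statistic <- function(t) {
  t <- .as_fourfold(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  ab <- a + b; ac <- a + c
  if (ab == 0 || ac == 0) {
    return(list(ebgm = NA_real_, ebgm05 = NA_real_, defined = FALSE))
  }
  ebgm <- a * n / (ab * ac)
  if (any(c(a, b, c, d) == 0)) {
    return(list(ebgm = ebgm, ebgm05 = NA_real_, defined = FALSE))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.64 * se), defined = TRUE)
}

#' Positivity criteria for the four-algorithm signal gate
#'
#' A term is a signal only when all four algorithms pass their thresholds and
#' the pair count `a` reaches `min_a`: ROR lower 95% bound > `ror_lower_gt`;
#' PRR >= `prr_min` with chi-squared >= `chi2_min`; IC025 > `ic025_gt`;
#' EBGM05 > `ebgm05_gt`.
#'
#' @param min_a minimum target-drug pair count (default 3).
#' @param ror_lower_gt ROR lower-bound threshold (default 1).
#' @param prr_min PRR threshold (default 2).
#' @param chi2_min chi-squared threshold (default 4).
#' @param ic025_gt IC025 threshold (default 0).
#' @param ebgm05_gt EBGM05 threshold (default 2).
#' @param chi2_continuity_correction Yates correction for the PRR chi-squared
#'   (default `TRUE`).
#' @param zero_cell_correction pass-through to [ror_statistic()] (default
#'   `FALSE`).
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_a = 3, ror_lower_gt = 1, prr_min = 2,
                            chi2_min = 4, ic025_gt = 0, ebgm05_gt = 2,
                            chi2_continuity_correction = TRUE,
                            zero_cell_correction = FALSE) {
  stopifnot(min_a > 0, prr_min > 0, chi2_min > 0, ebgm05_gt > 0)
  structure(list(min_a = min_a, ror_lower_gt = ror_lower_gt,
                 prr_min = prr_min, chi2_min = chi2_min, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt,
                 chi2_continuity_correction = chi2_continuity_correction,
                 zero_cell_correction = zero_cell_correction),
            class = "signal_criteria")
}

#' Build the four-fold table for one term
#'
#' Counts (report, PT) pairs: `a` = target-drug pairs whose PT equals `term`
#' (or maps to the SOC `term` at SOC level), `b` = remaining target-drug
#' pairs, `c` = other pairs with the term, `d` = the remainder. The
#' background must contain the cohort's pairs.
#'
#' @param term a PT (level `"PT"`) or SOC (level `"SOC"`) name.
#' @param level `"PT"` or `"SOC"`.
#' @param cohort_pairs `data.table(primaryid, pt)` of the target-drug cohort.
#' @param background_pairs `data.table(primaryid, pt)` of the whole stratum
#'   (including the cohort).
#' @param mapping `data.table(pt, soc)` (required at SOC level); PT matching
#'   is case-insensitive after whitespace normalization.
#' @return a [fourfold()] table.
#' @export
build_contingency <- function(term, level = c("PT", "SOC"), cohort_pairs,
                              background_pairs, mapping = NULL) {
  level <- match.arg(level)
  cp <- data.table::as.data.table(cohort_pairs)
  bp <- data.table::as.data.table(background_pairs)
  if (level == "PT") {
    key_c <- norm_key(cp$pt)
    key_b <- norm_key(bp$pt)
    tk <- norm_key(term)
  } else {
    if (is.null(mapping)) {
      stop("build_contingency(): SOC level requires a PT->SOC mapping",
           call. = FALSE)
    }
    key_c <- map_pt_to_soc(cp$pt, mapping, strict = TRUE)
    key_b <- map_pt_to_soc(bp$pt, mapping, strict = FALSE)
    tk <- norm_key(term)
    key_c <- norm_key(key_c); key_b <- norm_key(key_b)
  }
  a <- sum(key_c == tk)
  b <- nrow(cp) - a
  c_tot <- sum(key_b == tk, na.rm = TRUE)
  c <- c_tot - a
  d <- (nrow(bp) - nrow(cp)) - c
  fourfold(a, b, c, d)
}

#' Map preferred terms to system organ classes
#'
#' @param pts character vector of PTs.
#' @param mapping `data.frame`/`data.table` with columns `pt` and `soc`.
#' @param strict error (naming the offending PTs) when a PT is unmapped;
#'   otherwise unmapped PTs return `NA`.
#' @return character vector of SOC names.
#' @export
map_pt_to_soc <- function(pts, mapping, strict = FALSE) {
  mapping <- data.table::as.data.table(mapping)
  idx <- match(norm_key(pts), norm_key(mapping$pt))
  out <- mapping$soc[idx]
  if (strict && anyNA(out)) {
    miss <- unique(pts[is.na(out)])
    stop("unmapped PT(s) in SOC mapping: ",
         paste(utils::head(miss, 10), collapse = "; "), call. = FALSE)
  }
  out
}

#' Read a two-column PT-to-SOC mapping file
#'
#' The MedDRA dictionary is licensed and is not bundled; users supply their
#' own mapping as a delimited two-column text file with header `pt<sep>soc`.
#'
#' @param path file path.
#' @param sep field separator (default tab; PT names may contain commas).
#' @return `data.table(pt, soc)`.
#' @export
read_soc_mapping <- function(path, sep = "\t") {
  m <- data.table::fread(path, sep = sep, header = TRUE, quote = "",
                         colClasses = "character")
  data.table::setnames(m, tolower(names(m)))
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("SOC mapping file must have columns 'pt' and 'soc': ", path,
         call. = FALSE)
  }
  m[, .(pt = squish(pt), soc = squish(soc))]
}

.stat_row <- function(term, level, t, criteria) {
  ror <- ror_statistic(t, correction = criteria$zero_cell_correction)
  prr <- prr_statistic(t, criteria$chi2_continuity_correction)
  bcp <- bcpnn_statistic(t)
  mgp <- mgps_statistic(t)
  flag_ror <- isTRUE(ror$defined && ror$lower > criteria$ror_lower_gt)
  flag_prr <- isTRUE(prr$defined && !is.na(prr$chi2) &&
                       prr$prr >= criteria$prr_min &&
                       prr$chi2 >= criteria$chi2_min)
  flag_bcpnn <- isTRUE(bcp$ic025 > criteria$ic025_gt)
  flag_mgps <- isTRUE(mgp$defined && mgp$ebgm05 > criteria$ebgm05_gt)
  data.table::data.table(
    term = term, level = level,
    a = t$a, b = t$b, c = t$c, d = t$d,
    ror = ror$ror, ror_lower = ror$lower, ror_upper = ror$upper,
    prr = prr$prr, chi2 = prr$chi2,
    ic = bcp$ic, ic025 = bcp$ic025,
    ebgm = mgp$ebgm, ebgm05 = mgp$ebgm05,
    flag_ror = flag_ror, flag_prr = flag_prr, flag_bcpnn = flag_bcpnn,
    flag_mgps = flag_mgps,
    overall_signal = flag_ror && flag_prr && flag_bcpnn && flag_mgps &&
      t$a >= criteria$min_a
  )
}

#' Evaluate disproportionality signals at PT and SOC level
#'
#' For every distinct PT observed in the cohort (pair count >= 1) and every
#' SOC reached through the mapping, builds the four-fold table against the
#' stratum background and computes all four statistics with their positivity
#' flags. `overall_signal` is the conjunction of the four per-algorithm flags
#' and the minimum-count rule. Cohort PTs absent from the mapping are
#' collected under the sentinel SOC `"Unmapped"` and reported via the
#' `"unmapped_pts"` attribute.
#'
#' @param cohort a [build_cohort()] result (or `data.table(primaryid, pt)` of
#'   target pairs).
#' @param background_pairs stratum-wide `data.table(primaryid, pt)` pairs
#'   (must include the cohort's pairs).
#' @param mapping PT-to-SOC mapping, see [read_soc_mapping()].
#' @param criteria a [signal_criteria()] object.
#' @param adjust_bh also report a Benjamini-Hochberg adjusted chi-squared
#'   p-value column `bh_q` per level (informational; never gates
#'   `overall_signal`). Default `FALSE`.
#' @return a `data.table` of per-term results (PT rows then SOC rows, sorted
#'   by SOC then pair count descending), columns as in [.stat_row] plus
#'   `soc` for PT-level rows.
#' @export
evaluate_signals <- function(cohort, background_pairs, mapping,
                             criteria = signal_criteria(),
                             adjust_bh = FALSE) {
  pairs <- if (inherits(cohort, "faers_cohort")) cohort$pairs
  else data.table::as.data.table(cohort)
  bp <- data.table::as.data.table(background_pairs)
  if (nrow(pairs) == 0) {
    warning("evaluate_signals(): empty cohort; no results")
    return(data.table::data.table())
  }
  mapping <- data.table::as.data.table(mapping)

  pair_soc <- map_pt_to_soc(pairs$pt, mapping, strict = FALSE)
  unmapped <- unique(pairs$pt[is.na(pair_soc)])
  if (length(unmapped)) {
    warning("evaluate_signals(): ", length(unmapped),
            " cohort PT(s) missing from the SOC mapping; grouped under",
            " sentinel SOC 'Unmapped'")
    mapping <- data.table::rbindlist(list(
      mapping[, .(pt, soc)],
      data.table::data.table(pt = unmapped, soc = "Unmapped")))
  }

  pt_tab <- pairs[, .N, by = .(pt_key = norm_key(pt), term = pt)]
  pt_tab <- pt_tab[!duplicated(pt_key)]
  bg_key <- norm_key(bp$pt)
  bg_counts <- table(bg_key)
  n_cp <- nrow(pairs); n_bp <- nrow(bp)

  lookup <- function(counts, key, fallback) {
    v <- unname(counts[key])
    if (is.na(v)) fallback else as.integer(v)
  }
  pt_rows <- lapply(seq_len(nrow(pt_tab)), function(i) {
    a <- pt_tab$N[i]
    ctot <- lookup(bg_counts, pt_tab$pt_key[i], a)
    t <- fourfold(a, n_cp - a, ctot - a, (n_bp - n_cp) - (ctot - a))
    .stat_row(pt_tab$term[i], "PT", t, criteria)
  })
  pt_res <- data.table::rbindlist(pt_rows)
  pt_res[, soc := map_pt_to_soc(term, mapping, strict = TRUE)]

  coh_soc <- map_pt_to_soc(pairs$pt, mapping, strict = TRUE)
  bg_soc <- map_pt_to_soc(bp$pt, mapping, strict = FALSE)
  soc_tab <- data.table::data.table(soc = coh_soc)[, .N, by = soc]
  bg_soc_counts <- table(bg_soc)
  soc_rows <- lapply(seq_len(nrow(soc_tab)), function(i) {
    a <- soc_tab$N[i]
    ctot <- lookup(bg_soc_counts, soc_tab$soc[i], a)
    t <- fourfold(a, n_cp - a, ctot - a, (n_bp - n_cp) - (ctot - a))
    .stat_row(soc_tab$soc[i], "SOC", t, criteria)
  })
  soc_res <- data.table::rbindlist(soc_rows)
  soc_res[, soc := term]

  out <- data.table::rbindlist(list(pt_res, soc_res), use.names = TRUE)
  data.table::setorder(out, level, soc, -a)
  out <- out[order(match(level, c("PT", "SOC")))]
  if (adjust_bh) {
    out[, chi2_p := stats::pchisq(chi2, df = 1, lower.tail = FALSE)]
    out[, bh_q := stats::p.adjust(chi2_p, method = "BH"), by = level]
  }
  data.table::setattr(out, "unmapped_pts", unmapped)
  out[]
}
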