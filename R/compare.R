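# Pediatric-versus-adult contrast of per-PT reporting: a comparison odds
# ratio on the two cohorts' (report, PT) pairs plus Fisher's exact test.
#
#              PT      other PTs
#   adult    a_adult    b_adult
#   child    a_child    b_child
#
# The adult row sits in the numerator, so ROR < 1 means relatively more
# reporting of the PT in children.

#' Comparison table for one PT across the two age strata
#'
#' @param a_adult,b_adult adult pairs with / without the PT.
#' @param a_child,b_child child pairs with / without the PT.
#' @return a `comparison_table` object.
#' @export
comparison_table <- function(a_adult, b_adult, a_child, b_child) {
  cells <- c(a_adult, b_adult, a_child, b_child)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("comparison_table(): cells must be non-negative integers",
         call. = FALSE)
  }
  structure(list(a_adult = a_adult, b_adult = b_adult,
                 a_child = a_child, b_child = b_child),
            class = "comparison_table")
}

.as_comparison <- function(t) {
  if (inherits(t, "comparison_table")) return(t)
  if (is.numeric(t) && length(t) == 4) {
    return(comparison_table(t[1], t[2], t[3], t[4]))
  }
  stop("expected a comparison_table or numeric",
       " c(a_adult, b_adult, a_child, b_child)", call. = FALSE)
}

#' Comparison reporting odds ratio (adult vs child)
#'
#' ROR = (a_adult/b_adult) / (a_child/b_child) with a Wald 95% CI on the log
#' scale. Values below 1 indicate relatively more reporting of the PT in the
#' pediatric stratum. Swapping the two groups maps the ROR to its reciprocal
#' and mirrors the interval.
#'
#' @param t a [comparison_table()] (or numeric
#'   `c(a_adult, b_adult, a_child, b_child)`).
#' @param child_in_numerator flip the orientation (default `FALSE`).
#' @return list with `ror`, `lower`, `upper`, `defined`.
#' @export
comparison_ror <- function(t, child_in_numerator = FALSE) {
  t <- .as_comparison(t)
  cells <- c(t$a_adult, t$b_adult, t$a_child, t$b_child)
  if (any(cells == 0)) {
    return(list(ror = NA_real_, lower = NA_real_, upper = NA_real_,
                defined = FALSE))
  }
  ror <- (t$a_adult / t$b_adult) / (t$a_child / t$b_child)
  if (child_in_numerator) ror <- 1 / ror
  se <- sqrt(sum(1 / cells))
  list(ror = ror,
       lower = exp(log(ror) - 1.96 * se),
       upper = exp(log(ror) + 1.96 * se),
       defined = TRUE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value is the sum of the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (with the customary 1 + 1e-7 relative
#' tolerance for probability comparisons). Probabilities are handled in log
#' space.
#'
#' @param t a [comparison_table()] or any 2x2 given as numeric `c(a, b, c, d)`
#'   (rows `(a, b)` and `(c, d)`).
#' @return the p-value in (0, 1]. A table with an empty margin is degenerate
#'   and returns 1.
#' @export
#' @examples
#' fisher_exact_two_sided(c(3, 1, 1, 3)) # 0.4857143
fisher_exact_two_sided <- function(t) {
  t <- .as_comparison(t)
  a <- t$a_adult; b <- t$b_adult; c <- t$a_child; d <- t$b_child
  m <- a + b          # row-1 total
  n2 <- c + d         # row-2 total
  k <- a + c          # column-1 total
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  logp <- stats::dhyper(support, m, n2, k, log = TRUE)
  log_obs <- stats::dhyper(a, m, n2, k, log = TRUE)
  min(1, sum(exp(logp[logp <= log_obs + log1p(1e-7)])))
}

#' Compare per-PT reporting between the pediatric and adult cohorts
#'
#' For each PT, builds the adult-vs-child comparison table from the two
#' cohorts' (report, PT) pairs and reports the comparison ROR with 95% CI,
#' the two-sided Fisher p-value, and a direction label: `child-dominant` when
#' the ROR upper bound is below 1 with p < `alpha`, `adult-dominant` when the
#' lower bound exceeds 1 with p < `alpha`, `indeterminate` otherwise.
#'
#' @param child,adult [build_cohort()] results for the two strata.
#' @param pts PTs to compare; default: PTs flagged `overall_signal` in at
#'   least one stratum by [evaluate_signals()] when `signals` is supplied,
#'   else all PTs observed in either cohort.
#' @param alpha significance level (default 0.05).
#' @param signals optional list with elements `child` and/or `adult`:
#'   [evaluate_signals()] outputs used to pick default PTs.
#' @param child_in_numerator orientation flag, see [comparison_ror()].
#' @return `data.table` with columns `pt`, the four counts, `ror`, `ci_low`,
#'   `ci_high`, `p`, `direction`, sorted by `ror`.
#' @export
compare_populations <- function(child, adult, pts = NULL, alpha = 0.05,
                                signals = NULL, child_in_numerator = FALSE) {
  stopifnot(inherits(child, "faers_cohort"), inherits(adult, "faers_cohort"))
  if (adult$n_report_pt_pairs == 0 || child$n_report_pt_pairs == 0) {
    warning("compare_populations(): a cohort has no report-PT pairs;",
            " all PTs skipped")
    return(data.table::data.table())
  }
  if (is.null(pts)) {
    if (!is.null(signals)) {
      pick <- function(s) if (is.null(s) || nrow(s) == 0) character(0)
      else s[level == "PT" & overall_signal == TRUE, term]
      pts <- unique(c(pick(signals$child), pick(signals$adult)))
    } else {
      pts <- unique(c(child$pairs$pt, adult$pairs$pt))
    }
  }
  ck <- norm_key(child$pairs$pt)
  ak <- norm_key(adult$pairs$pt)
  nc <- length(ck); na_ <- length(ak)
  rows <- lapply(pts, function(p) {
    key <- norm_key(p)
    a_child <- sum(ck == key)
    a_adult <- sum(ak == key)
    if (a_child == 0 && a_adult == 0) return(NULL)
    t <- comparison_table(a_adult, na_ - a_adult, a_child, nc - a_child)
    r <- comparison_ror(t, child_in_numerator)
    pv <- fisher_exact_two_sided(t)
    direction <- "indeterminate"
    if (r$defined && pv < alpha) {
      lo <- r$lower; hi <- r$upper
      if (child_in_numerator) {
        if (lo > 1) direction <- "child-dominant"
        if (hi < 1) direction <- "adult-dominant"
      } else {
        if (hi < 1) direction <- "child-dominant"
        if (lo > 1) direction <- "adult-dominant"
      }
    }
    data.table::data.table(pt = p, a_adult = a_adult,
                           b_adult = na_ - a_adult, a_child = a_child,
                           b_child = nc - a_child, ror = r$ror,
                           ci_low = r$lower, ci_high = r$upper, p = pv,
                           direction = direction)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    message("compare_populations(): ", skipped,
            " PT(s) absent from both cohorts skipped")
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) data.table::setorder(out, ror, na.last = TRUE)
  out[]
}
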