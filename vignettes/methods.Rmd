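---
title: "Methods: disproportionality screening of FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsignal)
```

## The problem and the data model

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited reports of suspected drug reactions. Each report carries
demographics (DEMO), one or more drug rows with role codes (DRUG, with PS =
primary suspect), reaction preferred terms (REAC), outcome codes (OUTC) and
indications (INDI), published quarterly as `$`-delimited ASCII tables.
Because there is no exposure denominator, safety screening works by
*disproportionality*: an event is suspicious for a drug when its share of
that drug's reports clearly exceeds its share of all other drugs' reports.

`pedsignal` implements that screen end to end for a pediatric use case:
ingest quarters, deduplicate cases, select reports where the drug of
interest is the primary suspect, restrict to an age stratum, screen every
PT and SOC through four disproportionality statistics under an all-four
positivity gate, and contrast the pediatric and adult reporting profiles.

Era drift in the quarterly files is absorbed at parse time: headers are
matched case-insensitively with aliases (e.g. the older `GNDR_COD` for
sex), absent columns become missing values without changing row counts, and
malformed rows are skipped and counted under the default lenient mode
(strict mode turns them into errors, which suits machine-written fixtures).
Only the PRIMARYID-keyed layout is supported; legacy ISR-keyed files
predating it are a documented limitation.

## Deduplication and cohort construction

FAERS re-issues a case under a new PRIMARYID each time it is amended, so
counting reports naively overcounts. Per CASEID we keep the record with the
latest FDA acceptance date (FDA_DT); ties are broken by the largest
PRIMARYID (numerically when all identifiers parse as numbers, otherwise
lexicographically). Records without a CASEID cannot be linked and survive
as singletons. The operation is total and idempotent.

The cohort pipeline order is fixed — deduplicate, match drug and role,
filter by age stratum, then join reactions, outcomes, indications and
concomitants — so that synonym matching never resurrects a superseded
report version. Drug matching normalizes names (uppercase, trimmed,
internal whitespace collapsed) and compares them with the synonym list
either exactly (default) or as word-boundary substrings; the substring
policy catches composite verbatims such as `ULTANE (SEVOFLURANE)` at the
cost of some specificity, which is why it is opt-in.

Ages arrive in mixed units. Conversion to years uses YR×1, DEC×10, MON÷12,
WK×7/365.25, DY÷365.25, HR÷8766 — weeks, days and hours through the Julian
year, months as 1/12 year. Any convention within rounding of these is
equivalent at the stratum boundary. A present value with a missing unit is
taken as years, the dominant pattern in the database. Pediatric means age
in [0, 18) years and adult means ≥ 18; the half-open boundary is exposed as
`pediatric_max`. Reports with missing, negative or un-unit-convertible ages
are excluded from both age-defined strata (they remain available under
`stratum = "all"`), rather than imputed.

Descriptive summaries follow clinical Table-1 conventions: percentages are
computed against explicitly stated denominators and rounded half-up to two
decimals (base R's half-to-even rounding prints unstable last digits);
every report contributes exactly one outcome category through the severity
priority Death > Life-threatening > Hospitalization > Disability > Other,
with the rarer congenital-anomaly and required-intervention codes folded
into Other; concomitant medications are counted as mentions (drug rows),
not distinct reports, with the total mention count as denominator.
Percentages are always recomputed from the underlying counts, never copied
from a source table.

## The counting unit

All contingency tables count (report, PT) pairs after within-report PT
deduplication, not reports: a report listing cough twice and tachycardia
once contributes two pairs. The drug margin a+b therefore equals the
cohort's pair count, which is the convention under which published
pediatric anesthetic signal tables are internally consistent (their drug
margins match their stated adverse-event record counts, and the implied
ln-ROR standard errors match their printed intervals). Report-level
counting differs only in how multi-event reports weigh the margins; the
pair convention is used consistently across the signal engine and the
population comparison.

## The four statistics and the gate

With cells a, b, c, d and N = a+b+c+d:

- **ROR** = ad/bc, with the Wald interval
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
- **PRR** = [a/(a+b)] / [c/(c+d)], accompanied by the 2×2 Pearson χ² with
  expected counts from the margins. The Yates continuity correction
  (|O−E|−0.5)²/E is on by default — the common convention for the PRR
  criterion — and can be switched off.
- **IC** = log2[aN/((a+b)(a+c))], the information component. Its lower
  credibility bound IC025 = E(IC) − 2√V(IC) uses the moment formulas of the
  Bayesian confidence propagation neural network with the standard priors
  (marginal pseudo-counts α₁ = β₁ = 1 with totals α = β = 2, joint
  pseudo-count γ₁₁ = 1, and the data-dependent joint total
  γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)) that centres the prior IC at zero).
- **EBGM** = aN/((a+b)(a+c)), the relative-reporting-ratio form of the
  gamma-Poisson shrinker, with EBGM05 = exp(ln EBGM − 1.64·√(1/a+…+1/d)),
  a one-sided 90% lognormal bound.

Two identities follow by construction and are enforced by tests: IC =
log2(EBGM) exactly, and EBGM ≤ PRR ≤ ROR whenever ROR > 1. The full
DuMouchel two-component-gamma MGPS is deliberately out of scope — at the
single-drug screening scale there is no empirical prior to fit — and the
simplified estimator pair is the one under which published pediatric signal
tables are row-by-row self-consistent.

A term is a **signal** when all four rules hold simultaneously: a ≥ 3,
ROR lower bound > 1, PRR ≥ 2 with χ² ≥ 4, IC025 > 0, EBGM05 > 2. These are
the field-standard thresholds; all are configurable through
`signal_criteria()` rather than hard-coded. No multiple-testing adjustment
gates signals (the four-way conjunction plus the minimum count is itself
the false-positive control); an optional Benjamini–Hochberg column is
available for context but never changes `overall_signal`.

Zero cells leave a statistic undefined (`NA`, flagged) rather than
Haldane-corrected: with the a ≥ 3 gate a zero-a table can never signal, so
a 0.5-cell correction would only manufacture numbers where the data are
degenerate. The correction is available behind a flag for users who want
every row populated. SOC-level tables count a pair once per constituent PT
(a report with two PTs of one SOC contributes two SOC pairs), keeping the
SOC margin equal to the PT margin. Cohort PTs missing from the user's
PT→SOC mapping are collected under a sentinel `Unmapped` SOC and reported,
never silently dropped.

## Pediatric-adult comparison

For each PT the two cohorts form a 2×2 with the adult row in the
numerator: ROR = (a_adult/b_adult)/(a_child/b_child), so values below 1
mean relatively more pediatric reporting. The orientation is arbitrary; the
output always carries a direction label (`child-dominant` when the upper
bound is below 1 with p < α, `adult-dominant` mirrored, `indeterminate`
otherwise) so the number cannot be misread, and a flag flips the
orientation. Significance uses the two-sided Fisher exact test: the sum of
hypergeometric probabilities, conditional on the margins, of all tables no
more probable than the observed one (with the customary 1 + 10⁻⁷ relative
tolerance), computed in log space. Mid-p is not used.

## The synthetic generator

`generate_bundle()` emulates the relational structure a correct pipeline
must handle: duplicate CASEIDs with perturbed dates (half older-date, half
same-date lower-PRIMARYID, exercising both tie-break branches), missing
demographics, mixed age units on every run, suspect and concomitant drug
rows, outcomes, indications, and drug–event associations of configurable
strength. Associations are injected per PT as an odds multiplier RR via the
exact-odds adjustment p′ = RR·p/(1 − p + RR·p), so the report-level odds
ratio equals RR by construction and recovery tests are sharp rather than
approximate. A report drawing no event is redrawn once and then given a
dedicated filler PT; because the filler's occurrence is driven by that
mechanism rather than a background probability, it is excluded from
null-PT calibration accounting. Generation is bit-reproducible per seed and
restores the caller's RNG state.

Defaults are chosen to be realistic for this class of database: a 10%
pediatric share, 2% target-drug exposure, 10% duplicated cases, a 54-term
vocabulary with background probabilities log-spaced over 0.002–0.04 (mixing
rare and common events), and FDA dates spread over 2004–2024. What the
generator does *not* emulate — correlated co-prescription structure,
temporal reporting trends, event clustering within reports, verbatim drug
name noise beyond case/whitespace — bounds what passing tests show: they
validate the pipeline's bookkeeping and the statistics' calibration, not
robustness to every real-world data pathology.

## Validation scales and observed behaviour

The test suite validates, among others: exact closed-form values of all
four statistics on a reference table; χ² against `stats::chisq.test` and
Fisher against both an independent `choose()`-based enumeration and
`stats::fisher.test`; nominal 93–97% coverage of the ln-ROR interval over
2,000 tables simulated from a known-odds-ratio model; recovery of three
injected odds-ratio-10 signals (background probability 0.01) from a
200,000-report bundle with at most 3 of 50 null PTs flagged; estimator
consistency at odds ratio 5 over 100 seeded replicates of 20,000 reports
(median pair-level ROR within [4, 6], interval coverage within [93%, 97%]);
and child–adult comparison power (child-only odds ratio 8 detected as
child-dominant) and calibration (symmetric injection directional in well
under 10% of 200 replicates of 6,000 reports). These sizes keep the whole
suite within a few minutes on one CPU while leaving the binomial noise of
each check well inside its asserted band.

One behaviour worth knowing: the pair-counting ROR estimates the
association at the pair level, which sits slightly below the injected
report-level odds ratio when injection lengthens exposed reports' PT lists
(observed median ≈ 4.8–5.0 at RR = 5). The Wald interval still covers the
injected value at nominal rates at these table sizes.

## Limitations

Disproportionality quantifies reporting, not risk: no incidence, no
causality. The package inherits the usual spontaneous-reporting caveats
(under-reporting, notoriety effects, missing fields) and adds its own
scope bounds: PRIMARYID-keyed input only, no MedDRA hierarchy traversal
beyond the user-supplied PT→SOC mapping, no dose analysis, no stratified or
covariate-adjusted shrinkage, and a comparison module limited to the
two-group child/adult split.
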