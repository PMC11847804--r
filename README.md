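# pedsignal

Disproportionality signal detection for spontaneous adverse-event reports in
the FAERS quarterly ASCII dialect, built for pediatric drug-safety questions:
which adverse events are reported disproportionately often for a drug of
interest in children, and how does the pediatric reporting profile differ
from the adult one?

Spontaneous-reporting databases have no denominators, so safety screening
relies on *disproportionality*: for each MedDRA preferred term (PT), compare
how often the event is reported with the drug against how often it is
reported with all other drugs, via a four-fold table of (report, PT) pairs

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

`pedsignal` computes four standard statistics on this table and combines
them through a conservative all-four gate:

- **ROR** (reporting odds ratio): `ad / bc`, Wald 95% CI on the log scale
  with SE `sqrt(1/a + 1/b + 1/c + 1/d)`; positive when the lower bound
  exceeds 1.
- **PRR** (proportional reporting ratio): `[a/(a+b)] / [c/(c+d)]` with the
  2×2 Pearson chi-squared (Yates-corrected by default); positive when
  PRR ≥ 2 and χ² ≥ 4.
- **BCPNN IC** (information component): `log2[aN / ((a+b)(a+c))]` with the
  moment-based lower credibility bound IC025 = E(IC) − 2·√V(IC); positive
  when IC025 > 0.
- **EBGM** (empirical Bayes geometric mean, gamma-Poisson-shrinker form):
  `aN / ((a+b)(a+c))` (= 2^IC) with one-sided 90% lognormal lower bound
  EBGM05; positive when EBGM05 > 2.

A PT (or SOC, after mapping PTs to system organ classes) is a **signal**
only when all four rules hold and it has at least 3 pairs. A separate module
contrasts pediatric and adult cohorts PT-by-PT with a comparison odds ratio
(adult over child, so values below 1 mean relatively more pediatric
reporting) and a two-sided Fisher exact test.

Around the statistics sits a complete pipeline: FAERS `$`-delimited quarterly
file ingestion tolerant of era schema drift, case-level deduplication
(latest FDA date per CASEID, ties to the largest PRIMARYID), drug cohort
construction by synonym and role-code matching with age stratification
(pediatric = [0, 18) years), Table-1-style descriptive summaries, and a
seeded synthetic FAERS-like generator with exact injected odds ratios for
end-to-end validation. The MedDRA dictionary is licensed and not bundled;
you supply a two-column PT→SOC mapping file.

## Worked example

Generate a synthetic pediatric-weighted bundle with one event injected at
odds ratio 8, build the pediatric cohort, and screen for signals:

```r
library(pedsignal)

vocab <- synthetic_pt_vocabulary(n_pt = 20, n_soc = 5, p_range = c(0.005, 0.04))
cfg <- synthetic_config(n_reports = 20000, p_target_drug = 0.05,
                        pt_vocabulary = vocab,
                        signal_map = list("Synthetic event 001" = 8),
                        child_fraction = 0.4, seed = 11)
g <- generate_bundle(cfg)

cohort <- build_cohort(g$bundle, cfg$target_synonyms, stratum = "pediatric")
cohort
#> <faers_cohort> stratum: pediatric
#>   reports: 355  report-PT pairs: 412

bg  <- stratum_pairs(g$bundle, "pediatric")
sig <- evaluate_signals(cohort, bg, soc_mapping(vocab))
sig[level == "PT" & overall_signal == TRUE,
    .(term, a, ror = round(ror, 2), ror_lower = round(ror_lower, 2),
      prr = round(prr, 2), chi2 = round(chi2, 1),
      ic025 = round(ic025, 2), ebgm05 = round(ebgm05, 2))]
#>                   term     a   ror ror_lower   prr  chi2 ic025 ebgm05
#> 1: Synthetic event 001   144  8.37      6.71   5.8 472.2   1.9    3.9
```

Only the injected event passes the four-way gate: estimated ROR 8.37
(truth 8), with every per-algorithm threshold met — exactly what the screen
should report. `run_pipeline()` wraps the same steps (both strata, summaries,
PT/SOC signal tables, child–adult comparison) into one call that writes CSV
outputs and a run log; `inst/scripts/pedsignal` exposes it as a shell command
(`pedsignal run|synth|stats`).

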