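# pharmsig

Pharmacovigilance signal detection and time-to-onset analysis for
spontaneous-report databases, built for analysts mining FAERS-style
quarterly tables for adverse-event signals of a single target drug.

Spontaneous-report systems have no denominators, so drug safety screening
works by *disproportionality*: for each (drug, event-term) pair a 2×2
table is built —

|              | event term | other terms |
|--------------|-----------:|------------:|
| target drug  | a          | b           |
| other drugs  | c          | d           |

— and the pair is screened with four algorithms:

- **ROR** = ad/bc with the log-scale Wald 95% CI,
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Yates-corrected χ²,
- **BCPNN IC** = log₂[(a+½)/(E+½)] with E = (a+b)(a+c)/n and the
  closed-form IC025 shrinkage bound,
- **MGPS EBGM**: empirical-Bayes geometric mean of the relative reporting
  rate under a fitted two-component gamma-mixture prior, with its 5th
  posterior percentile EBGM05.

A term is a positive signal only if **all four** criteria hold: N ≥ 3,
ROR lower CI > 1, PRR ≥ 2 with χ² ≥ 4, IC025 > 0, EBGM > 2 (all
configurable). Screening runs at the PT, HLGT and SOC levels of a
MedDRA-style hierarchy, for the whole corpus and within sex strata.

Time-to-onset analysis fits a Weibull distribution to the onset intervals
(inclusive days from therapy start to event), classifies the hazard from
the shape parameter β — CI below 1: *early failure* (risk decreasing),
spanning 1: *random*, above 1: *wear-out* — and compares sexes with
Kaplan–Meier cumulative incidence and a log-rank test.

The package also ships a synthetic FAERS-like generator
(`generate_faers()`) that emits the `"$"`-delimited quarterly dialect with
planted signal multipliers, duplicate case versions, realistic demographic
missingness and Weibull onset times, plus a truth table of expected
contingency cells — so the entire pipeline is testable without any
database download. See the vignette
(`vignettes/pharmacovigilance-methods.Rmd`) for the models, conventions
and design decisions.

## Worked example

Generate a synthetic corpus with two planted signals, run the pipeline,
and inspect the screened signals and onset analysis:

```r
library(pharmsig)
library(dplyr)

cfg <- generator_config(
  n_reports = 20000, target_drug_fraction = 0.02,
  signal_multipliers = c("Phrenic nerve paralysis" = 10,
                         "Anaesthetic complication" = 5),
  missing_date_p = 0.5, seed = 2024
)
dir <- file.path(tempdir(), "faers")
gen <- generate_faers(cfg, dir = dir)

reports <- read_faers_tables(dir) |> deduplicate_reports()
flagged <- select_target_cases(reports,
                               c("Ropivacaine", "Naropin", "Naropeine"),
                               keep_all = TRUE)
res <- disproportionality(flagged, level = "PT")
res |> filter(significant) |> arrange(desc(ror)) |>
  select(term, a, ror, ror_lo, ror_hi, prr, chi2, ic025, ebgm)
#> # A tibble: 2 × 9
#>   term                         a   ror ror_lo ror_hi   prr  chi2 ic025  ebgm
#>   <chr>                    <int> <dbl>  <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 Phrenic nerve paralysis     45  8.18   5.88  11.4   7.34  214.  2.13  6.13
#> 2 Anaesthetic complication    50  7.21   5.27   9.87  6.40  202.  2.00  6.13
```

Exactly the two planted terms pass the joint four-algorithm criterion; the
observed ROR of 8.2 for the tenfold term reflects the generator's
renormalisation and the target share (see the vignette). The onset
analysis on the target cases:

```r
tto <- extract_tto(filter(flagged, is_target))
weibull_tto_fit(tto$samples$tto_days)
#> Weibull time-to-onset fit (n = 185)
#>   median 3.0 d (IQR 1.0-8.0), range 1-96 d
#>   scale alpha = 6.23 d (95% CI 5.21-7.45)
#>   shape beta  = 0.86   (95% CI 0.77-0.95)
#>   failure type: early failure
```

The shape CI lies entirely below 1: reporting risk is front-loaded, an
early-failure pattern. (The fitted shape exceeds the generating 0.63
because onset dates are whole days; see the vignette on discretisation.)
`tto_analysis()` adds per-sex fits, KM curves (`autoplot()`) and the
log-rank comparison; `run_pipeline()` orchestrates all of the above and
writes the result tables plus a run manifest, and
`inst/cli/pharmsig.R` exposes `generate` / `ingest` / `signals` / `tto` /
`summarize` / `run` subcommands for shell use.

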