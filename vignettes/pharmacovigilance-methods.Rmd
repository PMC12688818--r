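---
title: "Disproportionality signal detection and time-to-onset analysis with pharmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset analysis with pharmsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsig)
library(dplyr)
```

## The problem

Spontaneous-report databases such as FAERS collect adverse-event reports
without denominators: we observe how often a drug--event pair is *reported*,
never how often it *occurs*. Disproportionality analysis turns this into a
screening statistic by asking whether an event is reported more often with
the drug of interest than with everything else in the database. For each
(drug, event-term) pair a 2×2 table is formed:

|              | event term | other terms |
|--------------|-----------:|------------:|
| target drug  | a          | b           |
| other drugs  | c          | d           |

The counting unit throughout is the unique report–term pair: a report
mentioning a term twice still contributes one count, and within a sex
stratum both the target and the background counts come from that stratum
only.

`pharmsig` implements this workflow end to end for FAERS-dialect quarterly
tables — ingestion, FDA-rule deduplication, primary-suspect drug selection,
MedDRA-style PT/HLGT/SOC roll-up, four signal-detection algorithms under a
joint significance rule, sex-stratified screening, and a Weibull /
Kaplan–Meier time-to-onset analysis — together with a synthetic
FAERS-like generator so every stage is testable with known ground truth.

## The four algorithms

**Reporting odds ratio.** ROR $= ad/bc$ with the log-scale Wald interval
$\exp(\ln \mathrm{ROR} \pm z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$. When any cell
is zero the Haldane–Anscombe correction adds 0.5 to all four cells
(`correct = TRUE`, the default); with the correction disabled a zero cell
yields an undefined-result marker rather than an error.

**Proportional reporting ratio.** PRR $= [a/(a+b)]/[c/(c+d)]$, accompanied
by the 1-df chi-squared statistic. The classic screening criteria use the
Yates-corrected form
$\chi^2 = n(|ad-bc|-n/2)^2/[(a+b)(c+d)(a+c)(b+d)]$; the uncorrected
statistic is available via `yates = FALSE`. At a perfectly balanced table
the Yates statistic is exactly 0.

**BCPNN information component.** With the independence expectation
$E = (a+b)(a+c)/n$, the shrinkage form is
$\mathrm{IC} = \log_2\frac{a+0.5}{E+0.5}$, finite even at $a = 0$. The
lower credibility bound uses the closed-form approximation
$\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2.0(a+0.5)^{-3/2}$.
This approximates the 2.5th percentile of $\log_2\lambda$ under the
posterior $\lambda \mid a \sim \mathrm{Gamma}(a+0.5,\ E+0.5)$ that the
shrinkage form implies; the test suite checks it against $10^5$ Monte-Carlo
draws from that posterior and requires agreement within 0.15 bits for
$a \ge 5$. (Several BCPNN variants exist in the literature; the package
implements this closed-form shrinkage version and uses the matching
posterior — not the original full Dirichlet model, which estimates a
slightly different quantity — as its simulation oracle.)

**MGPS / EBGM.** The multi-item gamma-Poisson shrinker models
$a \sim \mathrm{Poisson}(\lambda E)$ with a two-component gamma mixture
prior on $\lambda$,
$w\,\Gamma(\alpha_1,\beta_1) + (1-w)\,\Gamma(\alpha_2,\beta_2)$.
Marginally each count is a mixture of negative binomials; `mgps_fit()`
maximises that likelihood over all cells by BFGS on the unconstrained scale
(log for the four gamma parameters, logit for $w$), starting from
DuMouchel's canonical values $(0.2, 0.1, 2, 4, 1/3)$ with relative
tolerance $10^{-8}$. The posterior for one cell is again a gamma mixture;
EBGM is its geometric mean $2^{\mathrm{E}[\log_2 \lambda \mid a, E]}$
computed in closed form via $\psi(\alpha)-\ln\beta$, and EBGM05 is the 5th
posterior percentile found by root-finding on the mixture CDF. Fewer than
about 50 cells triggers a stability warning: with very few tables the
mixture can degenerate to a spike and shrinkage becomes nominal.

**Joint criterion.** A term is a positive signal only if *all* of:
$N = a \ge 3$, ROR lower 95% bound $> 1$, PRR $\ge 2$ with $\chi^2 \ge 4$,
$\mathrm{IC}_{025} > 0$, and EBGM $> 2$. All thresholds are configurable
(`signal_thresholds()`), and because published criteria are ambiguous about
whether the EBGM rule applies to the geometric mean or its 5th percentile,
`ebgm_stat = "ebgm05"` switches the criterion to EBGM05 without changing
the reported columns. The joint rule is deliberately conservative; the
acceptance suite measures its per-term false-flag rate at $\le 5\%$ across
200 null corpora (it is in practice far below that).

No multiplicity adjustment is applied beyond the joint rule itself — the
four-algorithm intersection *is* the screening device, matching standard
pharmacovigilance practice.

## Time to onset

TTO is the interval from therapy start (START_DT) to event onset
(EVENT_DT), counted inclusively: `tto = (event - start) + 1` days, so
same-day onset is 1 day. Spontaneous-report conventions never define day-0
handling; the inclusive convention keeps every interval strictly positive
(a requirement of the Weibull likelihood) and reproduces the published
minimum of 1 day. Reports with a missing, partial (YYYY or YYYYMM) or
invalid date on either side, or with the event before the start, are
excluded and tallied by reason.

`weibull_tto_fit()` fits the two-parameter Weibull by maximum likelihood
(via `fitdistrplus`), reports scale $\alpha$ (days) and shape $\beta$ with
Wald 95% CIs computed on the log-parameter scale (a seeded nonparametric
bootstrap is available for small samples), and classifies the hazard:

* $\beta$ CI entirely below 1 → **early failure** (risk decreasing),
* CI containing 1 → **random failure** (constant risk),
* CI entirely above 1 → **wear-out failure** (risk increasing).

Medians and IQRs use inclusive (Tukey) quartiles, i.e. `fivenum()`.
Kaplan–Meier curves are computed with the product-limit estimator; since
spontaneous reports carry no censoring mechanism every observation is an
event and the curve equals the empirical CDF — the estimator is kept for
its at-risk bookkeeping and to admit censoring should a source provide it.
Two-group comparisons use the standard unstratified log-rank test with the
hypergeometric variance and no extra tie correction.

## The synthetic generator

`generate_faers()` emits DEMO/DRUG/REAC/THER/OUTC/RPSR tables in the
`"$"`-delimited quarterly dialect with known ground truth. Its defaults are
fixed at the conditions of a real local-anaesthetic safety cohort:

| parameter | default | rationale |
|---|---|---|
| `tto_shape`, `tto_scale` | 0.63, 4.46 | published Weibull fit for onset intervals (days) |
| `missing_sex_p` | 0.1852 | sex missing in 18.52% of reports |
| `missing_age_p` | 0.3459 | age missing in 34.59% |
| `missing_weight_p` | 0.6938 | weight missing in 69.38% |
| `missing_date_p` | 0.913 | only 8.7% of cases carry usable onset dates |
| sex split | 748 : 444 | F:M among reports with known sex |
| `events_per_report_mean` | 2 | event count per report ~ 1 + Poisson(2); FAERS reports list several PTs and no published event-count model exists, so this is a stand-in, not an inference |
| `target_drug_fraction` | 0.05 | a desk-scale target share; the real database share (≈1500 of 22 M) is not simulable at test sizes |
| `duplicate_fraction` | 0.10 | exercises both deduplication branches at a realistic rate |

Event terms are drawn from a 30-term background multinomial
(`default_pt_vocabulary()`); for target-drug reports the probabilities are
multiplied by the planted $\lambda$ values and renormalised. Onset dates
are placed so that the *recorded interval* is a Weibull draw rounded up to
whole days (`event_dt = start_dt + floor(W)`, hence
`tto = floor(W) + 1 = ceil(W)` ≥ 1). Duplicate case versions replicate the
full report with either a later FDA_DT or a higher PRIMARYID, with equal
probability. The `TruthTable` returned alongside gives each term's exact
expected cells under the model (marginalising the per-report event count
and, when per-sex multipliers are set, the sex distribution).

Three model properties matter when interpreting test results:

1. **Renormalisation.** Planting $\lambda > 1$ on some terms necessarily
   deflates the remaining terms' effective rates in target reports, so the
   realised relative rate of a planted term is slightly below $\lambda$.
   Recovery tests that need the planted rate isolated use *compensated*
   multiplier maps (mild down-weights on common terms keeping
   $\sum_t \lambda_t p_t = 1$).
2. **Margin inflation.** $a/E$ with $E$ from the corpus margins equals
   $\rho / (1 + f(\rho - 1))$ for true rate ratio $\rho$ and target share
   $f$, so recovery tests keep $f$ small (0.004).
3. **Day rounding.** Fitting a continuous Weibull to `ceil(W)` intervals
   inflates the fitted shape (≈0.63 → ≈0.85 at these parameter values)
   because of the tie mass at 1 day. Parameter-recovery claims are
   therefore made on continuous draws; fits to generated *date* data are
   reported as properties of the discretised model.

The generator does **not** simulate free-text narratives, secular
reporting trends across quarters, indication-driven drug--event
correlation, or the real (licensed) MedDRA dictionary — a synthetic
hierarchy over the generator vocabulary ships instead
(`synthetic_hierarchy()`, also as `extdata/synthetic_meddra_hierarchy.tsv`),
including one deliberately multi-axial PT. Passing tests therefore
demonstrate correctness of the counting, statistics and inference
machinery under a known model, not fidelity to any real database's
co-reporting structure.

## Ingestion and deduplication choices

* Deduplication follows the FDA-recommended rule: per CASEID keep the
  latest FDA_DT, breaking ties by the highest PRIMARYID. The operation is
  idempotent and is verified against corpora with injected duplicates.
* Drug-name matching is case-insensitive substring matching after
  normalisation (uppercase, punctuation stripped), applied to both the
  DRUGNAME and active-ingredient columns; published analyses state their
  search terms but rarely the matching rule, and substring matching
  captures strength/formulation suffixes ("NAROPIN 0.2% INJ"). Both the
  searched columns and the role code (default PS, primary suspect) are
  configurable.
* Reports with no event rows are dropped with a logged count — an
  event-less report can enter no contingency table.
* A multi-axial PT (one PT under several SOCs) counts once per mapped SOC,
  matching standard practice when primary-SOC flags are unavailable;
  `roll_up()` deduplicates within report and level, so per-SOC Ns may sum
  above the distinct-report count.
* Demographic percentages round half away from zero at two decimals, and
  the "healthcare professional" aggregate is HP+MD+OT+PH — the
  combination that reproduces the published 90.70% (1327/1463); including
  RN does not.

## Problem sizes used by the test suite

The suite builds every fixture in code. The heavier checks use: a
50,000-report corpus with planted multipliers $\lambda \in \{1,2,5,10\}$
run through the full file-based pipeline; 50 replicate 50,000-report
corpora for multiplier recovery (median $a/E$ per $\lambda$); 200
null corpora of 2,000 reports for false-flag calibration; 5,000 Weibull
draws for parameter recovery plus 200 replicates at the published usable
cohort size of 127; and $10^5$ Monte-Carlo posterior draws for the IC025
check. These sizes were chosen so each statistical tolerance sits several
standard errors from its threshold under the model.

## Known limitations

* The MGPS prior is fitted per corpus; on small vocabularies (tens of
  cells) the mixture likelihood is weakly identified and EBGM05 can sit
  close to EBGM. Real screens with thousands of cells do not exhibit this.
* The BCPNN implementation is the closed-form shrinkage variant; results
  differ in the third decimal from the original full-model Monte-Carlo
  formulation for very small $a$.
* Weibull fits on day-rounded onset data inherit the discretisation bias
  described above; with most mass in the first few days an
  interval-censored likelihood would be more faithful, and is out of scope
  here.
* The log-rank test treats all onset times as uncensored events, which is
  the only defensible choice for spontaneous reports but means the test
  compares reporting-time distributions, not hazards in any cohort sense.
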