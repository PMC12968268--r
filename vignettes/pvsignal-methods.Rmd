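---
title: "Methods: disproportionality, time-to-onset and boosted risk modelling for drug-associated miscarriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, time-to-onset and boosted risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
Individual Case Safety Reports (ICSRs): a case may be reported several
times (versions), drugs on a report carry role codes (primary suspect PS,
secondary suspect SS, concomitant C, interacting I), adverse events are
coded as MedDRA preferred terms (PTs), and demographic fields are missing
heavily and non-randomly. `pvsignal` implements a complete screening
pipeline for one outcome — miscarriage, identified by the PTs
`ABORTION SPONTANEOUS` and `ABORTION` — from raw quarterly extracts to a
consolidated per-drug result table, together with a synthetic report
generator with known ground truth so that every stage can be validated
without the multi-gigabyte FAERS archive.

## Cohort construction

Deduplication keeps one record per `CASEID`: the highest case version,
then the latest FDA receipt date, then the fewest missing values among
age, weight, sex, occupation, country and event date, with a final
deterministic keep-last tie-break. Obsolete cases can be removed by
supplying the deleted-case lists shipped with recent quarterly extracts;
without them that step is a no-op.

The analysis background keeps reports inside the study window whose
reporter is a health professional or consumer (`MD`, `CN`, `PH`, `HP`,
`OT`; configurable — public summary tables still tabulate a small number
of lawyer reports, so the filter is a default, not a hard rule) and which
carry at least one primary-suspect drug not on the exclusion list.
Progestogens and related formulations are excluded by default: these
drugs are prescribed *because* a pregnancy is at risk, so their
association with miscarriage is protopathic rather than causal. Cases are
the background subset whose reactions match a target PT exactly (after
trimming and case-folding — no substring matching, so `ABORTION INDUCED`
never qualifies).

Age is normalized to years (`DEC` ×10, `MON` ÷12, `DY` ÷365.25), weight
to kg (`LBS` ×0.453592), with implausible entries (age > 120 y, weight
> 650 kg or ≤ 0) treated as missing. Descriptive tables use the
known-value denominator for percentages (missing tabulated separately)
and half-up rounding to 2 decimals, the convention of published
demographic tables. Reporter-country percentages in public reports are
not always consistent with a single denominator; `summarize_demographics`
always uses the known-value denominator, and `aggregate_countries`
reports region *sums* (e.g. US + Canada; UK, Germany, France, Italy,
Netherlands, Sweden, Spain, Denmark for Western Europe), which are
denominator-free.

## Disproportionality statistics

All four methods are computed from the 2×2 table of one drug (PS
exposure) against the background: `a` exposed cases, `b` exposed
non-cases, `c` unexposed cases, `d` unexposed non-cases;
`E = (a+b)(a+c)/N` is the expected `a` under independence.

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96 √(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)] / [c/(c+d)]`, with the Pearson χ² (df 1, no
  continuity correction).
* **BCPNN IC** `= log2[(a+0.5)/(E+0.5)]` with the asymptotic lower
  credibility bound `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`.
  This is the closed-form variant in dominant modern use; the original
  full-Bayes Dirichlet formulation requires sampling and is out of scope.
* **MGPS EBGM/EB05**: the relative reporting rate λ has a two-gamma
  mixture prior whose five hyperparameters are fitted by maximizing the
  negative-binomial marginal likelihood of all observed `(a, E)` pairs
  (BFGS on log/logit-transformed parameters, deterministic jittered
  restarts from the customary initialization α₁=0.2, β₁=0.1, α₂=2, β₂=4,
  P=1/3; with fewer than 50 usable tables the default prior is returned
  with a warning). The posterior is again a two-gamma mixture;
  `EBGM = 2^{E[log2 λ]}` has a digamma closed form per component and
  `EB05` is found by monotone root-finding on the posterior CDF
  (tolerance 1e-8).

**Zero cells.** When any cell is zero, ROR and PRR point estimates and
intervals use the Haldane–Anscombe +0.5 correction on all four cells; the
χ² statistic always uses the raw cells, so the correction keeps estimates
finite without biasing the test.

**Thresholds and consensus.** The canonical literature thresholds are the
defaults: ROR flag `a ≥ 3` and interval lower bound > 1; PRR flag
`PRR ≥ 2`, `χ² ≥ 4`, `a ≥ 3`; BCPNN flag `IC025 > 0`; MGPS flag
`EB05 ≥ 2`. A drug is a **consensus signal** when the ROR flag holds
together with at least one other method. Multiple testing across drugs is
controlled by Benjamini–Hochberg FDR on the association-χ² p-values (the
choice of p-value family is a documented default; published reports do
not always state which p-values were adjusted).

A caution on interpretation: `2^IC` and `EBGM` estimate the observed/
expected reporting ratio against the *whole* background (including the
exposed stratum). They coincide with the exposure rate ratio only when
the exposed fraction is small; with a drug present on a fifth of all
reports, `E` itself is inflated and both statistics are conservative.
The package's large-count consistency test therefore uses a small exposed
fraction.

## Subgroups

`stratify` splits the cohort strictly at a cutpoint (< vs ≥; 35 years and
70 kg by default), excluding and counting records with the variable
missing. Each stratum is analyzed as a self-contained 2×2 against its own
within-stratum non-case background, so the stratum tables of one variable
sum cell-wise to the pooled complete-data table (an invariant under
test). Published subgroup analyses do not always define their comparator;
this self-contained construction is the package's documented choice, and
no attempt is made to reproduce published subgroup magnitudes built on an
unknown comparator. Stratum estimates require `a ≥ 3`, and by default
only drugs with at least 100 case reports are sub-stratified (rarer drugs
keep their overall signal only); both floors are configurable.

## Time-to-onset

TTO is the day difference between the *earliest* full-precision
primary-suspect therapy start date and the full-precision event date;
partial dates (year or year-month only) and non-positive intervals are
excluded and counted, never imputed. Using the earliest start is the most
conservative exposure-onset convention when several PS drugs carry dates.

The Weibull density `f(t) = (α/β)(t/β)^{α−1} exp(−(t/β)^α)` is fitted by
exact profile likelihood: for fixed shape the scale MLE is
`mean(t^α)^{1/α}`, and the profile score for the shape is monotone and
solved to near machine precision; 95% intervals come from the analytic
observed information in `(log α, log β)`, mapped back by exponentiation.
The fit is deterministic and agrees with `survival::survreg` to ~1e-7.
Samples below 30 observations (configurable) get a summary without a fit;
zero-dispersion samples are an error.

Hazard classification uses unrounded interval bounds: **early failure**
(decreasing hazard) when the shape interval lies entirely below 1,
**degradation/wear-out** (increasing hazard) when entirely above 1,
**random failure** otherwise. When classifying from values printed at
limited precision, `printed_precision` widens the boundary by half an ulp
of the printed scale, so a lower bound printed as exactly 1.00 alongside
a shape above 1 is recognized as degradation — resolving the ambiguity
rounding creates in published tables.

**Discretization note.** The synthetic generator rounds TTO draws up to
whole days (≥ 1), matching how calendar dates quantize real intervals.
Fitting a continuous Weibull to day-rounded data biases the shape upward
by ≈ +0.009 at shape 0.73 / scale 481 days (measured against a
pseudo-true fit on 3×10⁶ draws) — negligible for screening, but larger
than the sampling error above n ≈ 5,000, which is why the generator
recovery test runs at a long-scale parameter point where the bias is
well below one standard error. Interval-censored fitting would remove the
bias and is a known limitation, not implemented.

## Risk model

The report-level feature matrix contains one row per deduplicated report
exposed (PS) to at least one of the top-k drugs (k = 30 by default,
ranked by case-report count, ties lexicographic) and one binary indicator
column per drug; the outcome is the case flag. Features are drug
indicators only — published work on this outcome lists no non-drug
features. Gradient-boosted trees are trained with fixed documented
defaults (logistic objective, depth 4, 200 rounds, learning rate 0.1,
class imbalance via `scale_pos_weight` = negatives/positives on each
training set; weighting, not resampling). Discrimination is estimated by
seeded stratified cross-validation — 5 folds by default, matching the
fold count whose results public reports actually tabulate, with any
other count available via `n_folds` — using the package's own
Mann–Whitney rank AUC (ties get half credit) and pooled accuracy at the
0.5 threshold with an exact binomial interval.

Feature importance is reported two ways: gain (total split gain per
feature from the booster's trees, normalized to sum 1) and SHAP (TreeSHAP
attributions from the booster's native contribution predictions).
Additivity — per-row attributions plus base value equal the model margin —
is enforced to 1e-4. Mean |SHAP| ranks global importance; the mean signed
attribution among exposed rows summarizes direction. Because TreeSHAP
cost grows with rows × trees, `shap_ranking` can evaluate a seeded
uniform row subsample (`sample_rows`); the default explains every row.

## Indication confounding

A drug indicated for a condition that itself raises miscarriage risk will
show a spurious association. Drugs are annotated against a user-editable
YAML map from drug name to categories in a five-member controlled
vocabulary: autoimmune disease, reproductive-tract infection, metabolic
disorder, thyroid dysfunction, progestogen use. Licensed terminologies
(UMLS `may_treat`) cannot be redistributed, so the bundled map is a small
illustrative example covering well-known drugs; real analyses should
supply their own mapping. Unmapped drugs are reported unflagged with an
`unmapped` note rather than silently treated as clean.

## The synthetic generator

`generate_cohort` draws each report's exposures independently (each
configured drug present as PS with its `use_prob`); the report is a case
with probability `event_base_rate` times the product of the injected
relative risks of its exposed drugs, capped at 1. This Bernoulli model
makes the implied 2×2 cell probabilities available in closed form — the
oracle used by the recovery tests (e.g. use_prob 0.05, base rate 0.01,
RR 5 implies an odds ratio of (0.05/0.95)/(0.01/0.99) ≈ 5.21).
Event-positive exposed reports get a therapy start preceding the event by
a per-drug Weibull draw rounded up to whole days; unexposed reports
receive a background PS drug so every report passes the role filter;
occasional concomitant rows exercise the role filter. Default
demographics emulate the published descriptive table: occupation mix
(~32% MD, ~33% CN, ~22% OT, …, 4.6% missing), age ~ Normal(32, 9) clamped
to [0, 84] with 45.4% missing, weight ~ Normal(68, 16) clamped with 78.2%
missing, dates 30% degraded (half to month precision, half removed).
Duplicates re-emit a configurable fraction of cases: half with a bumped
case version, half with the same version and an FDA date 0–90 days later,
filling one missing demographic with probability 0.5 — so all four
deduplication rules are exercised. A single explicitly seeded RNG stream
is used and the caller's RNG state is untouched; identical configurations
are bitwise-reproducible.

What the generator does **not** emulate: MedDRA coding noise, reporting
waves and country-specific reporting cultures, correlated co-prescription,
longitudinal patient histories, or non-random missingness mechanisms
(missingness is independent of severity). Passing tests therefore
demonstrate the correctness of the pipeline's arithmetic and bookkeeping
under a known model — not that real FAERS signals are unbiased, which no
spontaneous-report analysis can promise.

## Validation problem sizes

The shipped checks use problem sizes chosen to put Monte-Carlo error well
inside each acceptance band: 500 null cohorts of 8,000 reports (one drug,
use_prob 0.15, base rate 0.08) for interval coverage and FDR calibration;
20 seeds of 200,000 reports (planted RR 5 drug at use_prob 0.05, base
rate 0.01, nine null drugs) for consensus and SHAP-rank recovery; 5,000
simulated tables for MGPS prior recovery; 10,000 Weibull draws for TTO
recovery; 400 replications at n = 1,000 for interval coverage of the
Weibull shape.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_reports = 200000,
  drugs = data.frame(name = c("DRUG X", sprintf("NULL DRUG %02d", 1:9)),
                     use_prob = c(0.05, rep(0.03, 9)),
                     injected_rr = c(5, rep(1, 9)),
                     tto_shape = 1, tto_scale = 300),
  event_base_rate = 0.01, duplicate_rate = 0.1, seed = 42)
g <- generate_cohort(cfg)
cohort <- filter_cohort(deduplicate(g$cohort))
signals <- signal_scan(cohort, min_count = 3)
signals[consensus == TRUE]

fm <- build_feature_matrix(cohort, select_top_drugs(cohort, k = 10))
cv <- cross_validate(fm, n_folds = 5, seed = 7)
model <- fit_risk_model(fm)
shap_ranking(model, fm, sample_rows = 20000)
```

## Known limitations

* Signals are reporting associations, not causal effects; indication
  confounding is annotated, not adjusted for.
* No probabilistic record linkage across different CASEIDs.
* No MedDRA hierarchy traversal; PTs are opaque strings.
* Weibull fitting ignores day-level interval censoring (see above) and
  does not model competing risks or mixture hazards.
* The MGPS implementation is the drug×event pair shrinker, not the
  multi-item itemset variant.
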