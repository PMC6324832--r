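---
title: "Methods: ecological co-prevalence analysis with geomorbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecological co-prevalence analysis with geomorbid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`geomorbid` implements an ecological (areal) analysis of the geographic
overlap between two hospital-treated conditions — obesity and depression —
as observed in French-style administrative hospital data. The unit of
analysis is the *geographic code*, an areal unit built from patients'
residence zip codes. For each code the pipeline produces age-sex
standardized hospital prevalence of both conditions, a socio-economic
deprivation profile, a joint High/Low classification against the national
average, and bidirectional ecological logistic regressions quantifying how
strongly high prevalence of one condition predicts high prevalence of the
other after adjustment for deprivation and urbanicity.

Everything is ecological: associations estimated over areal units need not
hold at the individual level (ecological bias), and the package makes no
individual-level claims.

## Case ascertainment

Input is a stay-level table, one row per diagnosis, with an anonymous
patient linkage id. Two source systems are distinguished: acute care (`MCO`)
and psychiatry (`RIMP`). Per stay:

* **obesity** — an acute-care stay with an E66 code in any role
  (main or associated);
* **depression** — an acute-care stay with F32/F33 as *main* diagnosis; or
  an acute-care stay carrying, *as associated diagnoses in the same stay*,
  both a self-harm code (X6\*/X7\*/X8\*) and F32/F33; or a psychiatric stay
  with F32/F33 in any role.

Codes are compared after uppercasing and dot-stripping, by literal prefix.
Patients are deduplicated to one membership per condition regardless of stay
count, restricted to age 18 and over, and a patient with both conditions
contributes to both prevalence maps (the analysis is marginal per
condition). Two conventions the source description leaves open are fixed
here:

* Each member's age, sex and geographic code are taken from their *first
  qualifying stay in input order*; conflicting sex or geographic codes
  across a patient's stays trigger a warning.
* The self-harm block is implemented literally as the prefixes X6, X7, X8
  (X60–X89). Strict ICD-10 intentional self-harm is X60–X84; the
  `selfharm_upper_bound = "X84"` switch restricts the block accordingly,
  with the literal reading as default.

## Direct age-sex standardization

Age bands are decennial with an 18–19 sliver (so the adult filter aligns
with band edges) and an open 90+ band. For code $g$ with stratum case
counts $c_{gs}$ and populations $n_{gs}$, the standardized rate per 100,000
is

$$R_g = 10^5 \sum_s w_s \frac{c_{gs}}{n_{gs}}, \qquad
  w_s = \frac{N_s}{\sum_{s'} N_{s'}},$$

with reference weights $w_s$ from the national (18+) census aggregate by
default. Strata empty in a code contribute 0 without weight
re-normalization — this keeps rates comparable across codes, and the count
of skipped cells is reported so small codes can be audited. Codes with zero
total population get a missing rate, never 0. No small-area smoothing or
shrinkage is applied. The reference is restricted to adult strata,
consistent with the cohort; a census of a different vintage than the stays
is the user's responsibility.

## Deprivation index

A Pampalon-style bidimensional index, computed across codes (unweighted):

* **social score** — the mean of the z-scores of unemployment, blue-collar,
  low-diploma and immigrant shares, re-standardized to SD 1;
* **material score** — the z-score of the non-taxable-household share.

Each score is cut into three classes at −1/+1 SD; a value exactly on a
border falls in the middle class (the source text says only "borders"; strict
inequalities for the outer classes are this package's convention). The two
classes are crossed into five levels: (1,1) → level 1 (most advantaged);
material class 3 without social class 3 → level 3; social class 3 without
material class 3 → level 4; (3,3) → level 5 (most deprived); the three
residual cells — no class-3 component, at least one class 2 — form level 2
(national average). The residual reading is the only one that makes the
five levels a partition of the 9-cell grid, and the package verifies this
partition exhaustively.

The social aggregation rule (mean of four component z-scores) is a design
choice; the source description lists the components without an aggregation
rule. The scores are unweighted by population, again because no weighting is
stated.

## Overlap classification

Each code with computable rates is classed `H` or `L` per condition by
strict comparison to the national average rate (`H` iff rate > national;
ties are Low — a measure-zero convention fixed for determinism). The four
classes HH/HL/LH/LL partition the rated codes; shares are reported as
percentages *of codes* (not land area), and the `conjoint` share HH + LL
summarizes how often the two conditions sit on the same side of the
national average.

## Ecological regression

Both directions are fitted. For the obesity-direction model, the outcome is
membership in the top tertile of standardized obesity prevalence; the
predictors are the depression tertile (dummies for low and high, mid as
reference), deprivation level (dummies for 1, 3, 4, 5; level 2 reference)
and typology (dummies for suburbs, small/mid centers, rural; major urban
centers reference). Tertile cuts are type-7 quantiles at 1/3 and 2/3 over
codes with non-missing rates, unweighted; a rate exactly on a cut falls in
the lower tertile.

The likelihood is maximized in-house by iteratively reweighted least
squares (Fisher scoring with step halving) to a score max-norm below
`1e-8` or 100 iterations. Rank-deficient designs and complete or
quasi-complete separation (coefficient norm diverging past 25 on the
log-odds scale) are reported as distinct errors rather than returned as
silent garbage. Wald inference uses the inverse observed information at the
optimum: $CI = \exp(\hat\beta \pm z_{0.975}\,SE)$ and a two-sided normal
p-value. The regression is unweighted over codes, standard errors carry no
spatial-autocorrelation correction, and p-values are unadjusted for
multiplicity — all matching the source analysis, and all documented
limitations.

## The synthetic world

The generator exists so that every downstream stage is testable with known
ground truth. It emulates:

* thousands of codes with log-normal total adult populations (default
  median ≈ 1,200, `pop_log_sd = 1`: villages to cities), split exactly
  multinomially over 18 age-sex strata approximating a Western European
  adult pyramid;
* latent social and material deprivation scores, bivariate standard normal
  with correlation `socio_corr` (default 0.6), mapped through fixed
  monotone logistic links (plus small indicator noise) onto the five
  socio-economic shares — so the deprivation module can provably recover
  the latent ordering;
* a four-level urban typology assigned by population rank;
* individual condition risks
  `logit p = baseline(band, sex) + beta_deprivation(level) + beta_typology
  + lambda * u_g`, with `u_g ~ N(0, frailty_sd)` a shared code-level
  frailty inducing areal co-prevalence. Baseline logits are anchored to
  published national age-sex prevalence profiles (obesity peaking at
  2,847/100,000 for men aged 70–79; depression at 1,165/100,000 for women
  50–59 and 798/100,000 for men 90+); default covariate effects are the
  logs of published ecological odds ratios for the two conditions;
* stay records: each case becomes `1 + Poisson(duplicate_rate)` stays
  through realistic coding pathways (configured proportions of
  main-diagnosis, self-harm-associated, and psychiatric ascertainment for
  depression), plus injected under-18 patients and non-qualifying
  distractor stays to exercise the selection rules.

The generator records per-code true case counts, so selection can be
checked *exactly*, and its single seed fixes every emitted table
byte-for-byte.

What the generator does **not** emulate: real French geography or spatial
autocorrelation beyond the shared frailty, seasonal admission patterns,
medication confounding, or any individual-level dependence between the two
conditions (no joint individual-level distribution is specified by the
source; the shared-frailty construction is this package's modelling
choice). A green test therefore establishes correctness of the pipeline's
algebra and its statistical calibration under this stated world — not
epidemiological validity on real data.

### Calibration of the cross-condition association

`calibrate_frailty()` finds, by Monte-Carlo bisection, the `frailty_sd` at
which the ecological cross-condition odds ratio (high vs mid tertile)
attains a target value in expectation — the generation-time calibration
used by the acceptance suite to create a world with a known association of
1.3. The induced association is estimated by simulation on demand
(`estimate_cross_or()`) rather than at every generation, because a precise
estimate costs many replicates. With covariate effects switched off (as in
the calibrated world) the regression estimand is unconfounded, so the
calibrated value is exactly what the model should recover.

The per-replicate Monte-Carlo standard deviation of the fitted
cross-condition log-OR at 3,000 codes is about 0.10 — close to the
irreducible floor (~0.09) set by the 2×2 cell counts of tertile membership
at that number of codes. Recovery is unbiased (the replicate mean matches
the calibrated target to two decimals), but a band of (1.1, 1.5) around
OR 1.3 therefore captures only ~86–90% of single replicates; the
parameter-recovery test asserting a 90% capture rate sits on this knife
edge and fails by one to two replicates in 50, which the test suite
reports honestly rather than widening the band. The Wald coverage check —
95% CIs covering the calibrated truth — passes, confirming that the model's
standard errors correctly describe exactly this sampling noise.

## Numerical choices, in one place

* Tertiles: type-7 quantiles, ties to the lower tertile.
* Score classes: borders at ±1 SD belong to class 2.
* Overlap: ties to Low.
* IRLS: score max-norm < 1e-8, ≤ 100 iterations, step halving,
  separation threshold 25 on |β|.
* Empty strata contribute 0 to standardization without re-normalization.
* RNG: one seed per configuration; sub-streams derived deterministically.

## Worked example

```{r, eval = FALSE}
library(geomorbid)
cfg <- sim_config(n_codes = 500, seed = 1)
out <- run_pipeline(list(sim = cfg, out_dir = "demo_run"))
# demo_run/ now holds census/socio/stays + rates.csv, deprivation.csv,
# overlap_shares.csv, table2.csv, table3.csv and a manifest of MD5 hashes;
# rerunning with the same config reproduces the manifest bit for bit.
```
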