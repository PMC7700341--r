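---
title: "Criterion validation of a pediatric obesity-risk screener: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criterion validation of a pediatric obesity-risk screener: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidrisk)
```

## The problem

Short parent-report questionnaires are attractive screeners for pediatric
obesity risk: they are cheap, fast, and usable in community programs serving
families with limited literacy. But a questionnaire is only useful if its
score relates to objective measures of the child's state — anthropometry
(BMI-for-age, central adiposity) and blood biomarkers of metabolic, lipid and
inflammatory status. `kidrisk` implements that criterion-validation workflow
end to end: score the instrument, derive the objective outcomes, reduce a
candidate item pool to a parsimonious tool, and test score–outcome
associations nonparametrically. Because human-subjects data of this kind are
not shareable, the package also ships a synthetic dyad-cohort generator whose
statistical structure mirrors the study design the workflow targets, so every
stage is exercised by tests without any download.

## Instrument scoring

A codebook defines each item's construct and its map from response options to
scores. Scores live on a half-point grid in $[1, 5]$, with 5 the healthiest
behaviour; an 18-item instrument therefore totals between 18 and 90. The grid
is half-point rather than integer because observed totals in this family of
instruments take values such as 51.5 — some items are scored as averages of
sub-responses. The grid is validated at load time and configurable in the
sense that any multiple of 0.5 in range is accepted.

Totals over a chosen item subset are complete-case: a respondent who skipped
any subset item is flagged `complete = FALSE` and excluded from group
assignment. No imputation is attempted — with 45 short items, incompleteness
is rare and imputation would add model assumptions the downstream rank tests
do not need.

Dichotomization at a threshold $t$ (default 75) sends totals $\ge t$ to the
`high` group, everything below to `low`; exactly one boundary point maps to
`high`. A two-group split, rather than tertiles, suits skewed score
distributions in which few respondents reach the top of the range.

## Anthropometry

BMI is weight/height$^2$ (kg/m$^2$) with repeat height and waist measures
averaged first. Age- and sex-specific BMI z-scores use the LMS method: with
reference power $L$, median $M$ and coefficient of variation $S$,

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad z = \frac{\log(x/M)}{S} \text{ at } L = 0,$$

with $L$, $M$, $S$ interpolated linearly in age within sex (exact at table
knots). Percentiles are $100\,\Phi(z)$ — the normal-CDF convention, not an
empirical rank. Weight categories use the standard cut points: obesity at or
above the 95th percentile, overweight 85–95, normal 5–85, underweight below
the 5th. Waist-to-height ratio is $100 \times \text{waist}/\text{height}$.

The packaged reference table (`lms_bmi_synthetic.csv`) is **synthetic**:
smooth, plausible BMI-for-age curves for 24–84 months, both sexes. It exists
so the package tests and examples run offline; analyses of real children
should load a genuine CDC table via `load_lms_reference()`, which accepts the
same `sex, agemos, L, M, S` layout. Extended/modified z-scores for very high
BMI are out of scope, and the synthetic generator truncates simulated
z-scores to $\pm 4$, the support where the Box–Cox inverse is defined for
typical $L, S$ values.

## Laboratory quality control

Immunoassay analytes arrive as triplicates (duplicates for IGFBP-1) with a
plate id. Replicate selection follows the best-2-of-3 rule: if the CV
(sample SD/mean) of all replicates is under the threshold (5% by default,
10% for IGFBP-1), their mean is used; otherwise the minimum-CV pair is
taken, flagged `best_pair` if it passes and `fail` if not. Failing values
are retained and flagged, never silently dropped — exclusion is an explicit
analyst decision. Ties in pair CV break toward the larger pair mean, which
makes the choice invariant to replicate order.

Plate-to-plate variability is removed with each plate's internal control
under a multiplicative error model: values are scaled by the ratio of the
geometric mean of all plate controls to the own-plate control. The geometric
mean (rather than arithmetic) is the natural center for multiplicative
immunoassay error, and it makes the correction factors multiply to one
across plates.

Outliers are defined by Tukey fences — beyond $1.5 \times \mathrm{IQR}$
outside the quartiles — with quartiles computed by linear interpolation
between order statistics (`quantile` type 7), the single quartile convention
used package-wide. Outliers are flagged and reported, not removed.

Derived biomarkers: Friedewald LDL-C ($TC - HDL - TG/5$, withheld with a
validity flag at $TG \ge 400$ mg/dL), non-HDL-C, HOMA-IR
($\text{insulin} \times \text{glucose}_{mmol/L} / 22.5$ with glucose
converted from mg/dL by 0.0555), cholesterol:HDL, TG:HDL, and
leptin:adiponectin with adiponectin harmonized from µg/mL to ng/mL before
the ratio.

## Composite indices

Single biomarkers are noisy; summing standardized biomarkers into a
metabolic, a lipid and an anti-inflammatory index pools signal across
correlated markers of the same process. Each component is z-standardized
(sample SD, $n-1$) over the dyads where it is present — so every component
uses its full available n, which is why per-index complete-case counts vary —
and combined with sign corrections: HDL-C is negated in the lipid index, CRP
and resistin in the anti-inflammatory index, so that each index increases
with its named construct. A `complete_case` standardization option restricts
the standardization set to dyads with every component present, making the
index mean exactly zero over the scored set.

Two scalings are provided. `zsum` is the plain sum of signed z-scores, mean
~0. `tscore` maps each component to $50 + 10\,s\,z$ before summing, so a
$k$-component index centers at $50k$ (250–300 for the default indices);
published two-group tables in this literature show index medians in the
250–310 range, consistent with the T-score form. The two scalings are
affinely equivalent and rank dyads identically, so all rank-based inference
is unaffected by the choice; `zsum` is the default.

## Item reduction

The reference procedure for trimming a 45-item pool judged boxplots of each
anthropometric marker across item-score categories, keeping items whose
higher scores tracked lower markers. A visual rule is not reproducible, so
the package operationalizes it as a signed rank-correlation screen: for each
marker, Spearman's $\rho$ between item score and marker; an item is kept
when at least one marker shows $\rho \le -\rho_{\min}$ *and* a one-sided
normal-approximation p-value at or below $\alpha_{screen}$ (defaults 0.05
and 0.05).

The significance gate deserves a note, because a raw magnitude threshold
alone behaves badly at realistic sample sizes: the null SD of Spearman's
$\rho$ at $n = 200$ is about $1/\sqrt{n-1} \approx 0.07$, so a pure
$\rho \le -0.05$ rule would admit roughly a quarter of pure-noise items per
marker. Requiring the trend to be distinguishable from zero keeps the
noise-admission rate near the nominal 5% while still recovering items with
true loadings of about 0.3 at $n \approx 200$. Setting `alpha_screen = 1`
recovers the raw-threshold rule for users who want it. Because BMI
percentile is a monotone transform of BMI z, those two markers are
rank-identical; waist-to-height contributes the genuinely second look.

Pool reduction keeps all passing items, then — if more pass than the target
maximum (default range 16–20) — prunes the weakest (least negative best
$\rho$), honouring optional per-construct caps first, with lexicographic
item-id tie-breaks for determinism. Fewer passing items than the range
minimum are returned whole with an `under_minimum` flag rather than padded.

## Validation statistics

Score groups are compared on each outcome (BMI percentile, BMI z,
waist-to-height, and the three indices) with the Kruskal–Wallis test on
midranks with the tie correction — with two groups this is algebraically the
two-sided Wilcoxon rank-sum normal approximation, an identity the test suite
verifies to $10^{-9}$. Ties are always corrected for: the indices are
continuous but anthropometric edge cases tie. The degenerate all-identical
sample is reported as $H = 0$, $p = 1$. Descriptives are median/IQR per
group (quartile convention as above); $\alpha = 0.05$ per outcome with no
multiplicity adjustment, matching per-outcome reporting practice for this
design. A one-way ANOVA p-value is available as a parametric cross-check,
never a decision rule. Attrition checks compare retained and dropped
participants with Pearson chi-square (categorical) and Welch t-tests
(continuous), skipping single-level variables with a reason.

## The synthetic cohort

`simulate_cohort()` emulates the study design the workflow targets: 273
enrolled parent/child dyads with ~206 completing, 45 pool items, child age
uniform on 36–72 months with balanced sex, ~200 completers with
anthropometry, ~190 blood donors, 7 immunoassay plates.

Per dyad a latent factor $U \sim N(0,1)$ drives everything. Informative
items (default 18, spread over all 10 constructs) follow an ordered 5-level
probit model: latent propensity $a_i + \lambda U + \sqrt{1-\lambda^2}\,
\varepsilon$ cut at fixed thresholds whose baseline masses put roughly
(2, 7, 28, 45, 18)% in options 1–5 — most responses in options 3 and 4, as
observed for this instrument family — with per-item intercepts $a_i$ cycling
over a fixed pattern so item means spread realistically (about 2.9–4.3).
$\lambda$ is a standardized loading (correlation scale, default 0.3). Every
third item maps its options to half-point scores, putting totals on the
half-point grid; defaults were calibrated once so 18-item totals center near
68 with SD ≈ 5.5, reproducing the observed 51.5–80.5 window and a high-score
group of roughly 15–30 of ~200 at the 75-point cut.

The child's BMI z is
$0.6 + 1.1\,(-\beta \tilde S + \sqrt{1-\beta^2}\,\epsilon)$, where
$\tilde S$ is the standardized realized informative-item total (the "score
signal") and $\beta$ the criterion-validity effect (default 0.5; 0 gives an
exact null for calibration). The 0.6/1.1 margin reproduces a cohort skewed
toward overweight (≈17% obesity). BMI z is realized to height/weight through
the inverse LMS transform; waist tracks a waist-to-height ratio centered at
50.5 correlated 0.6 with BMI z. Log-normal biomarkers shift on the log scale
by signed loadings times standardized BMI z — positive for risk markers,
negative for HDL-C, adiponectin, IGFBP-1 and IL-10 (default magnitude 0.5,
0.3 for total cholesterol). Immunoassay values then acquire a multiplicative
log-normal plate effect (SD 0.08) shared with that plate's internal control,
and replicate noise at CV 4%.

Missingness is MCAR by default: dropout at rate $1 - 206/273$, one skipped
item for ~2% of completers, anthropometry missing for ~3%, blood donated by
~92%. Per-assay missingness is *clustered*: a donor is "short sample" with
probability 0.25, and only then each analyte is missing with probability
0.55. Independent per-analyte missingness cannot simultaneously match
per-analyte counts of ~160/190 and per-index complete-case counts of
~140–150; the clustered model matches both, reflecting the real mechanism
(insufficient blood volume affects many assays at once). An optional MAR
switch ties dropout to parent age and employment for attrition-test power
checks.

The `truth` table (latent factor, score signal, true BMI z) is emitted for
test oracles only and is never consumed by analysis modules.

### What the generator does and does not show

Passing tests on this cohort demonstrate that the pipeline recovers the
directions and calibration built into the generative model: under the null
the full score→group→Kruskal–Wallis chain rejects at ~5% per outcome; under
$\beta = 0.5$ the high-score group shows lower BMI percentile and
metabolic/lipid indices and a higher anti-inflammatory index in ≥90% of
seeds; the item screen recovers ≥80% of items with loading 0.3 while
admitting <10% of noise items. The generator is deliberately simple: a
single latent factor, probit items, log-normal biomarkers, MCAR missingness.
Real cohorts have multi-factor behaviour structure, measurement drift,
informative missingness and cultural response styles the generator does not
model, so these results validate the *software and the procedure's operating
characteristics*, not any claim about real children.

## Numerical choices and problem sizes

Quartiles: `quantile` type 7 everywhere. Sample SD ($n-1$) in all
standardization. LMS continuity at $L = 0$ is handled by an explicit log
branch ($|L| < 10^{-12}$); the inverse checks $1 + LSz > 0$. Spearman
p-values use the normal approximation ($z = \rho\sqrt{n-1}$), robust to the
heavy ties of 5-level items. Stochastic checks in the test suite and the
acceptance script use 200 cohorts for null calibration and 20 for the
direction and screen checks at the study's own size (n = 273 enrolled) —
large enough that the reported rates have binomial SEs of ~1.5% and ~7%
respectively, small enough that the full suite runs in about a minute.

## Known limitations

* The packaged LMS table is synthetic; real analyses must supply a genuine
  reference.
* The screen's significance gate means exact dyad duplication can flip a
  borderline keep/drop decision (the correlation itself is unchanged); the
  raw-threshold rule (`alpha_screen = 1`) is duplication-invariant but far
  more permissive to noise.
* Composite indices are unweighted sums of z-scores; PCA- or
  reliability-weighted composites and external-norm standardization are out
  of scope.
* No multiplicity adjustment across outcomes, matching per-outcome reporting
  in the target design; users testing many instruments should adjust.
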