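---
title: "Models and design choices in coachgx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in coachgx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coachgx)
```

# The analysis problem

Coached wellness cohorts collect irregularly timed clinical measurements
(blood draws roughly every six months, with substantial jitter) alongside
genotypes. Three questions drive the analysis: how much do clinical markers
change over the first year of the program; how much baseline variation do
polygenic scores (PGSs) and single SNPs explain; and does genetic
predisposition modify the *rate of change* under coaching. `coachgx`
implements all three as a pipeline of small, separately testable stages.

# Polygenic scores

Scores are built by pruning and thresholding. The Benjamini–Hochberg
step-up rule is applied to all GWAS p-values at FDR level $q$ (default
0.05): with order statistics $p_{(1)} \le \dots \le p_{(m)}$, select every
p-value at or below $p_{(k)}$ where $k = \max\{i : p_{(i)} \le iq/m\}$.
The surviving SNPs are LD-pruned greedily: take the most significant
remaining SNP, discard every remaining SNP with squared dosage correlation
$r^2 \ge 0.2$ against it, repeat. The retained set is mutually uncorrelated
($r^2 < 0.2$ for all pairs, strictly). Two conventions are deliberate and
recorded in output provenance because the procedure itself does not fix
them:

* **Greedy visit order** is ascending p-value (most significant seed
  first). "Keep the smaller p-value of each correlated pair, repeat" does
  not define a visit order; significance-first is the standard
  pruning-and-thresholding convention and is deterministic.
* **Ties** in p are broken lexicographically by SNP id, so results are
  identical across platforms and runs.

Scoring is the weighted effect-allele dosage sum; missing genotypes impute
to $2 \times \mathrm{EAF}$ (the Hardy–Weinberg mean dosage), so a fully
missing individual scores at the population mean. Dosage orientation is
resolved against the stored allele pair and flipped ($d \to 2-d$) when the
file counts the other allele; an allele pair matching neither model allele
is an error rather than a silent skip. Quartile strata use
$\mathrm{Q1} < 25$th percentile and $\mathrm{Q4} \ge 75$th percentile of
the analysis population, with Q2/Q3 as reference; whether published
analyses used $<$ or $\le$ at the boundaries is generally unstated, so the
convention is recorded in provenance. Rule-based scores (used for
homocysteine in some programs) are supported through a user-supplied
genotype-pattern rule table (`score_by_rules`) rather than hard-coded
rules.

# Filtering and baseline strata

A participant enters the analysis of a marker with a baseline measurement
within 30 days of their first draw and at least one follow-up between 90
days and 15 months; later records are excluded. We read all three window
boundaries inclusively and interpret 15 months as 456 days
($15 \times 30.4$); both choices are configurable
(`pipeline_config()$filters`). When several records fall in the baseline
window, the earliest is the baseline and the rest are discarded — counting
them as follow-ups would create near-duplicate baseline/follow-up pairs a
few days apart. Non-fasting draws are dropped for blood markers;
medication-specific exclusions apply per marker class (lipids, diabetes
markers, blood pressure); type-1 diabetes is a participant-level flag
excluding diabetes markers.

Baseline strata (low / normal / high) compare the baseline value to
clinical reference ranges, sex-specific where the range is. Ranges ship as
an editable TSV (`inst/extdata/reference_ranges.tsv`) because reference
ranges are vendor-specific in practice. Strata under 50 participants are
flagged not estimable and dropped from stratified fits.

# Longitudinal change models

The outcome model is a Gaussian linear mixed model with a per-participant
random intercept, fitted by REML through `lme4`. Time in program is
continuous, entered through a truncated-line (piecewise-linear) basis
anchored at day 0: with a knot at $k$, the columns are $\min(t, k)$ and
$\max(t - k, 0)$, so every fitted trajectory passes through zero change at
baseline by construction, and the adjusted change at a horizon is a linear
contrast of the basis coefficients — $(183, 0)$ at 6 months, $(183, 182)$
at 12 — with Wald 95% intervals from the coefficient covariance.

Choices worth knowing:

* **Knot at day 183, evaluation at days 183/365.** One interior knot is
  the least structure that lets 0–6 and 6–12 month slopes differ; knot
  count and placement are configurable, and sensitivity to them should be
  checked when trajectories look strongly nonlinear.
* **Gaussian identity link for all markers.** The outcomes here are
  continuous lab values; no other family is implied by the design.
* **Random intercept only.** Repeated measures within a participant are
  exchangeable around a personal level; with two or three visits per
  person, random slopes are rarely identifiable and are not fitted.
* **Wald intervals with normal quantiles**, matching the large-n reporting
  convention; no small-sample correction.
* Fixed covariates default to age at baseline, sex, enrollment channel,
  genetic ancestry, observation season, and observation vendor. Season is
  a 4-level factor from visit day-of-year quartiles; channel and vendor
  are 2-level factors; ancestry is a single continuous axis. Constant
  covariates are dropped automatically; genuinely collinear designs error
  naming the offending columns.

Stratified trajectories add stratum main effects and stratum × basis
interactions. Genetic effects on change use the same machinery on
follow-up observations only, with the observed baseline value as a
covariate — conditioning, not double-counting the baseline as outcome —
plus genetic stratum and stratum × basis terms; the differential change at
12 months is the interaction contrast at day 365. Because follow-ups alone
span only ~90–456 days, this design yields wider interaction CIs than a
model that kept baseline in the outcome; we accept that cost to keep the
baseline strictly on the conditioning side. The baseline coefficient
estimates below 1 are expected: the observed baseline contains measurement
noise, so its slope approaches
$\sigma^2_u / (\sigma^2_u + \sigma^2_\varepsilon)$ after covariates.

Baseline genetic association uses plain linear models: partial
$r^2 = (\mathrm{SSE}_{\mathrm{red}} - \mathrm{SSE}_{\mathrm{full}}) /
\mathrm{SSE}_{\mathrm{red}}$ against the covariate-only reduced model (the
covariate-adjusted definition, since the published quantities are from
covariate-adjusted regressions), with per-stratum coefficients versus the
reference. SNP strata are treated categorically to match per-genotype
reporting; an additive coding is available by passing the dosage as a
numeric feature. BH adjustment families default to one family per results
table and are a declared configuration choice.

# The synthetic cohort

The generator exists so that every estimator can be validated by parameter
recovery. Per participant, the latent baseline is

$$b_i = \mu + x_i^\top\gamma + g_i + u_i,$$

with covariate effects centered so $\mu$ is the population mean, $g_i$
either a continuous true score rescaled to explain exactly `baseline_h2`
of $\sigma^2_{\mathrm{total}}$ in the generated sample, or categorical
stratum offsets in marker units; $u_i$ the person-level intercept; and
each observation adds the true population trajectory (piecewise-linear
with the same day-183 knot the models use), a stratum differential change
accruing linearly to its configured 12-month value, and independent
measurement noise. The variance budget is explicit: genetic + covariate +
intercept + noise components sum to `baseline_sd`²; the intercept absorbs
the remainder and a configuration that over-commits the budget errors.
Default measurement noise is 30% of the baseline SD; within-person
reliability of repeated labs is not published for this design, so it is an
exposed parameter rather than an asserted value.

Genotypes are two independent haplotypes thresholded from a latent AR(1)
Gaussian per LD block — the minimal construction giving tunable LD decay
and exact Hardy–Weinberg sampling. Thresholding attenuates correlation:
at latent $\rho = 0.9$ the adjacent-SNP dosage $r^2$ is about 0.4–0.5
depending on allele frequency (verified by direct simulation), not 0.8.
Summary statistics are drawn per SNP around the true effects with the
analytic standard error $\mathrm{SE} = s_y / (s_g \sqrt{n})$, so null SNPs
get uniform p-values and effects/p-values are mutually consistent.
Monomorphic SNPs are flagged and excluded. Visit days follow the program
design: baseline uniform in [0, 30], follow-ups Gaussian around days 180
and 360 (SD 45) clipped to [90, 456], reproducing the observed ~180-day
mean spacing between draws.

What the generator deliberately does **not** emulate: real human LD maps
or reference panels; joint multi-marker outcomes (one marker per run);
non-Gaussian marker distributions (triglycerides and CRP are skewed in
reality); informative missingness or dropout; coaching-intensity
heterogeneity. Passing recovery tests therefore demonstrates estimator
correctness under the assumed data-generating process, not robustness to
these real-data features.

Because the observed baseline contains measurement noise while the person
level persists, stratifying on the observed baseline mechanically produces
regression to the mean: under zero true change, the baseline-high stratum
shows spurious decline while the whole-population estimate stays null. The
package treats this as a diagnostic to reproduce — it is the reason
whole-population estimates are the trustworthy ones in baseline-stratified
tables — and the test suite asserts the pattern rather than hiding it.

# Numerical and test-scale choices

Mixed models are fitted with `lmerControl(calc.derivs = FALSE)` (the Wald
inference used here does not need the finite-difference Hessian check).
Degenerate inputs fail loudly: empty post-filter PGS models, empty genetic
strata, quartile assignment under heavy ties, zero residual variance in
the reduced model, missing LD entries, and horizons beyond the observed
day range are all errors, not warnings. The step-up filter, greedy
pruning, and scoring identities are checked against independent oracles
(exhaustive/counting oracles, a simulated-GWAS regression, closed-form
imputation identities).

Recovery test scales are chosen to keep the full suite within a few
minutes while leaving Monte-Carlo error well inside the asserted
tolerances: single cohorts of 400–3,000 participants for unit tests;
200-replicate coverage runs at the published sample sizes (1,800–2,085)
for the headline recovery checks; 500 replicates for the
false-discovery-rate control check. The acceptance script averages 50–200
replicates per quantity at those same sizes.

# Known limitations

* The caching layer one might want around the mixed-model stage is not
  implemented; synthetic runs finish in seconds, so `run_pipeline` simply
  recomputes. Re-rendering from a saved result is `render_tables()`.
* `fit_strata_interaction` assumes strata are time-constant (defined at
  baseline); time-varying stratum membership is out of scope.
* The pipeline analyzes one marker per run; multi-marker reports are
  produced by repeated invocation, and cross-marker BH families must then
  be assembled by the caller.
* Whether published interaction contrasts are evaluated at 12 months or
  averaged along the trajectory is ambiguous in most reports; 12 months
  (day 365) is the implemented default, configurable via `horizon`.
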