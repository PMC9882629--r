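---
title: "Models and methods behind dialvax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dialvax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dialvax analyses the immune response to two-dose mRNA vaccination in a
maintenance-hemodialysis (HD) cohort against healthy controls (HC),
from gene-level RNA-seq counts and serology plates through to
predictor models of antibody titers. This vignette records the models
the package implements, the parameters that matter, and the design
choices made where more than one reasonable construction existed.

## Study layout and the nested design

Each cohort is sampled at six time points: before each of two vaccine
doses (V1D0, V2D0), one week after each dose (V1D7, V2D7), and at an
early post-dose day that differs by cohort (day 1 for controls, day 2
for HD — a consequence of dialysis scheduling). Subjects are nested
within groups: subject HD03 and subject HC03 are different people, and
each subject contributes up to six libraries.

`nested_design()` encodes this as

* an intercept and a group main effect;
* `group:subject_within_group` columns absorbing each subject's
  baseline expression (the paired structure of the data);
* `group:timepoint` interaction columns carrying the per-group
  condition effects, with V1D0 as the global reference.

Combinations that never occur (an HC sample at V1D2, unused subject
indices when group sizes differ) expand to all-zero columns and are
dropped, along with any remaining aliased columns found by QR, so the
matrix handed to the GLM is always full rank.

Within-group contrasts compare each post-dose day to its own dose's
baseline — V1-day effects against V1D0 and V2-day effects against
V2D0 — as differences of timepoint coefficients from one joint fit.
Between-group comparisons at the shared D7 days are interaction
contrasts (the difference of the two groups' change-from-baseline
coefficients). Both groups are fit jointly by default: a single model
shares dispersion information across all samples and supplies every
contrast; per-group fits remain possible by subsetting the inputs.

## The negative-binomial engine

Counts are modelled as \(y_{gj} \sim \mathrm{NB}(\mu_{gj},
\alpha_g)\) with \(\log \mu_{gj} = \log s_j + x_j^\top \beta_g\).

**Size factors** are median-of-ratios: for genes with positive counts
everywhere, the median over genes of \(y_{gj}\) divided by the gene's
geometric mean. Factors are defined only up to one overall constant —
scaling a sample by \(c\) multiplies its factor by \(c\) and the whole
vector by \(c^{-1/m}\) through the geometric means — which is why the
equivariance tests assert the ratio form.

**Dispersions** are estimated in three stages. Gene-wise estimates
maximise the Cox–Reid adjusted profile likelihood
\(\ell(\alpha) - \tfrac12 \log\det(X^\top W X)\), alternating twice
with mean refits. A parametric trend \(\alpha_{tr}(\mu) = a_0 +
a_1/\mu\) is fit to the gene-wise values by iterated gamma-family
regression with ratio-outlier exclusion. Finally each gene's estimate
is shrunk toward the log trend under a log-normal prior whose variance
is the excess of the mad-squared log residuals over the expected
sampling variance \(\psi'((m-p)/2)\), floored at 0.25; gene-wise
estimates more than two prior standard deviations above the trend are
kept unshrunk (real dispersion outliers should not be pulled down).

**Fitting** is IRLS on the log link with offsets \(\log s_j\), at most
500 iterations, declaring convergence when the relative deviance
change falls below 1e-6 (with a coefficient-change backstop of 1e-10
for the near-Poisson regime, where the deviance difference is
numerically noisy). Standard errors come from the information matrix
\(X^\top W X\) at the fit. Wald statistics for a contrast \(c\) are
\(c^\top\beta / \sqrt{c^\top \Sigma c}\), two-sided normal p-values,
Benjamini–Hochberg FDR per contrast (matching per-timepoint DEG
reporting). Non-converged and all-zero genes carry NA statistics and
never enter DEG counts. Genes with fewer than 10 total counts are
excluded before dispersion estimation (configurable; the cutoff
stabilises the gene-wise stage and is deliberately the only filtering
step — no independent filtering or outlier replacement is applied, for
transparency).

**VST.** For the trend \(\alpha(\mu) = a_0 + a_1/\mu\) the
variance-stabilising transform has the closed form
\[
v(q) = \log_2 \frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}
{4 a_0},
\]
the antiderivative of \(1/\sqrt{\mu(1+a_1) + a_0\mu^2}\) rescaled to
approach \(\log_2 q\) for large counts. It is strictly increasing, and
on simulated data spanning means 10–10000 the per-gene standard
deviation varies by well under 25% across mean deciles. If the fitted
asymptote is non-positive there is nothing to stabilise against and
the function falls back to \(\log_2(q+1)\) with a warning.

## Module enrichment and family summaries

Per-gene Wald statistics are tested against blood transcription
modules (BTMs). The default method is a two-sided competitive rank
test — Wilcoxon rank-sum of member vs non-member statistics with
normal approximation and tie correction — chosen because it is exact,
fast, and easy to verify. A conventional preranked running-sum method
with seeded gene-permutation p-values (>= 10^4 permutations) is
available as `method = "gsea"`. Both report through the same table
with BH FDR across the sets of one contrast. Sets with fewer than 5
members present are skipped and listed; the FDR is computed across the
sets actually tested.

Direction of enrichment is the sign of the median member Wald
statistic; an exactly zero median reports "+" with a tie flag. Family
summaries count, for each family, timepoint, and direction, the
percentage of the family's modules significantly enriched — the
denominator is always the family's size in the full collection, so a
family whose modules drop below the size filter reports conservative
percentages. Family labels ship as an editable CSV; the myeloid /
inflammation and T / NK cell families are held separate by default
because merged labels are ambiguous.

## Eigengenes and predictor models

A module's eigengene is the first principal component of its member
rows of the VST matrix across the samples of one dose window, computed
on per-gene centered values without variance scaling (variance
scaling would let low-information genes dominate the component). The
sign is fixed in three steps: compute the per-sample median expression
over member genes; correlate the eigengene with that median profile;
negate the eigengene if the correlation is negative. After fixing,
higher member-gene expression always maps to higher scores. V1 and V2
windows are computed independently and never compared across windows —
principal components from different sample sets live on different
scales. Single-member sets fall back to the centered gene itself with
the sign rule still applied.

Change scores are post-minus-pre per subject; subjects missing either
sample are excluded and listed. Per-module titer models regress log
anti-spike IgG at V2D7 on the change score, controlling for
SARS-CoV-2 history, with BH FDR across the timepoint's enriched module
list only. Clinical models follow the same template: baseline
predictors are pre-vaccination medians of up to three monthly labs
(ferritin entering as its risk band — 200–1200 ng/mL inclusive is low
risk, outside is high risk; the bounds are inclusive by choice since
no convention was available, and the 200–1200 band is the one
associated with lowest all-cause mortality on dialysis); post-dose
predictors are natural-log fold changes from baseline (the base only
rescales slopes; natural log is fixed and documented), with SARS-CoV-2
history and the day of lab collection as default covariates. The
covariate set is configurable per analyte because reasonable variants
exist (e.g. adjusting a lymphocyte model for baseline titers instead);
no single set is canonical.

## Serology calculus

**ELISA.** Standard curves are four-parameter logistic,
\(y = d + (a-d)/(1+(x/c)^b)\), fitted by nonlinear least squares on
the mean of duplicate standard ODs at each ladder concentration
(weighting schemes are deliberately not applied), with multi-start
initialisation from a linearised logit and data quantiles. Inversion
uses the closed form with a 5% guard band of the asymptote range: ODs
above it signal re-assay at higher dilution, below it below-LLOQ.
Sample concentrations multiply the back-calculated value by the total
dilution (1:100 stage × the 1:10 on-plate buffer dilution = ×1000;
1:2000 stage = ×20000) and report the mean of duplicate
concentrations — averaging concentrations rather than ODs, so the
reported value is linear in the quantity of interest.

**Neutralization.** Percent neutralization is exactly
\(100\,(V_0 - V_s)/V_0\) against the virus-only control, unclipped
(enhancement stays visible); no cell-only background subtraction by
default, matching the formula as used, with subtraction available as
an option. ID50 is estimated by fitting a logistic in log reciprocal
dilution (noise-robust), falling back to deterministic linear
interpolation between the bracketing pair in log-dilution; curves
never reaching 50% anywhere are censored at the 1:20 input dilution,
stored as the value 20 with a censoring flag rather than an imputed
half-LLOQ (downstream rank tests then treat censored values as ties
at 20).

**TCID50.** Reed–Muench: infected wells accumulate toward higher
concentration, uninfected toward lower; the 50% endpoint interpolates
between the bracketing dilutions by proportionate distance on the
log10 scale, and all-infected / all-uninfected ladders return
bound-only results.

## Cohort statistics

Titer time courses are tested per group by Kruskal–Wallis (H with tie
correction, chi-square reference) across V1D0 / V2D7 / M6, with
pairwise two-sided Wilcoxon rank-sum tests and BH correction across
the three pairs. The rank-sum (unpaired) form follows the named test
even though the comparisons are within-subject; a paired signed-rank
variant sits behind a flag, off by default — fidelity over statistical
preference, and the choice is visible in the interface. Exact
enumeration is used when the combined sample is at most 12 and
tie-free. Demographic tables use two-sided Fisher's exact tests
(defined as the total probability of tables no more likely than the
one observed) for categorical rows and Welch's t for continuous rows.
Titer models are OLS on log titers with reference coding (HC, male,
most frequent race category).

## The synthetic cohort

No raw data accompany the study design this package targets, so the
generator is a first-class module: every downstream stage is exercised
on data whose truth is known and serialised. Defaults are the study
conditions: 20 subjects per group, the six-timepoint layout above,
baseline log-means N(4, 1.5) (mean counts centred near 55 with a
realistic spread), dispersion trend \(\alpha(\mu) = 0.05 + 2/\mu\)
(asymptotic biological CV ~22%), log-normal subject intercepts with
sd 0.3, and per-sample size factors log-uniform in [0.5, 2]. Modules
are sampled disjoint by default so recovery tests are clean;
user-supplied memberships are checked against a maximum overlap
fraction. Clinical labs draw from the published HD cohort
means/SDs (ferritin 838 (550) ng/mL, URR 0.74 (0.052), WBC 6.0 (2.1)
k/uL, ...) truncated at physiologic zero.

Planted effects act at chosen group/timepoint combinations and are
modulated per subject (multiplier N(1, 0.3)), and the titer model
reads exactly those realised per-subject module changes: log IgG at
V2D7 = intercept + slopes · module changes + history offset + noise
(sd 0.6, offset 1.5 — within the spread such cohorts show between
infection-experienced and naive subjects). This makes transcriptome →
titer recovery a genuine end-to-end test rather than two disconnected
simulations. ELISA plates are generated from a known 4PL (a = 0.05,
b = 1.2, c = 13000, d = 3.8 OD over the 150,000 units/mL two-fold
standard ladder), neutralization plates from a logistic with Hill
slope 1.5 over a 1:20-start three-fold series, and titration plates
from a Poisson single-hit model in which one TCID50 infects half the
wells.

What the generator does **not** emulate: batch effects, library-size
composition bias beyond a scalar factor, zero inflation or dropout,
gene–gene correlation outside planted modules, assay drift between
plates, and missing-visit patterns beyond simple M6 missingness. A
green test suite therefore shows the pipeline's statistics behave as
designed under their own assumptions — not that those assumptions
exhaust real cohort data.

## Numerical choices and verification sizes

* IRLS: deviance computed with `log1p` (the naive form loses all
  precision near the Poisson limit); coefficients clipped at ±30 on
  the natural-log scale to stop transient divergence; Cholesky solves
  with a tiny jitter fallback.
* Dispersion optimisation on the log scale over [1e-8, 50]; genes with
  zero mean take the trend value and are flagged.
* 4PL fits refuse standard series whose response range is under 0.5
  OD (a ladder on one asymptote cannot identify the inflection).
* Ties: zero median Wald reports "+" with a flag; censored ID50s enter
  rank tests as ties at 20.
* Verification problem sizes (chosen once as realistic desk-scale
  analyses): oracle equivalence on 50 genes × 16 samples; null
  calibration on 10 simulated cohorts of 2000 genes with 20 subjects
  per group over two timepoints; planted-module recovery on 10 cohorts
  of 1000 genes with 20 subjects per group; titer-model recovery on
  the default 40-subject cohort, with the dispersion trend for its VST
  estimated on a ~500-gene subsample (the trend has two parameters;
  a subsample estimates it to well within the accuracy that matters
  for variance stabilisation).

## Known limitations

* The Wald test relies on its asymptotic normal reference; at very
  small group sizes it can run slightly anticonservative, as all
  NB-GLM Wald pipelines do.
* No shrinkage of fold-change estimates is applied for ranking;
  `log2fc` is the MLE.
* The permutation GSEA method permutes genes, not samples, so
  inter-gene correlation within modules can make its p-values
  optimistic; the default rank test shares this competitive-test
  caveat.
* Eigengene change scores are on the component scale of their window;
  comparing slopes across modules requires the per-module scale
  factor, as the acceptance checks do via the generator's ground
  truth.
* Censoring is handled by LLOQ ties in rank tests, not by parametric
  censored-data likelihoods.
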