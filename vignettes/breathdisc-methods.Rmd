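---
title: "Methods: discrimination analysis of breathomics feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrimination analysis of breathomics feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathdisc)
```

# The analysis problem

Untargeted LC-MS profiling of exhaled breath condensate (EBC) produces a
samples × features intensity table, each feature identified by retention
time and m/z ("time@mass"). The scientific questions this package
addresses are (i) which features discriminate a clinical group from
controls, with an honest estimate of how well, and (ii) whether a paired
intervention (here: a course of inhaled corticosteroid between T0 and T1)
shifts the profile within subjects. EBC intensities are noisy, dilution
is uncontrolled, many cells are missing, and p ≫ n, so every step below
exists to manage one of those pathologies.

# Preprocessing

**QC CV filter.** Pooled-QC replicate injections measure pure technical
variability. A feature whose QC coefficient of variation (sample sd over
mean, n−1 denominator) exceeds 25% is removed: its technical noise rivals
any plausible biological signal. The n−1 convention is a deliberate
choice; at typical replicate counts (3–10) it is the conservative one.
Features with no usable QC signal or a zero QC mean are removed with an
explicit reason code. QC rows are dropped after the filter; they play no
further role.

**Missing-value imputation.** Each missing cell is replaced by a uniform
draw in (0, minimum observed value of that feature). This rule models
missingness as *left-censoring* — the value existed but fell below the
effective detection level. "A random number between zero and the minimum"
is read as uniform, the least-informative distribution on that interval.
Observed values are never touched, so within-feature rank order is
preserved. Draws are seeded for reproducibility.

**PQN.** Probabilistic quotient normalization divides each sample by the
median of its feature-wise quotients to a reference spectrum (default:
the median spectrum of the study samples). The median quotient is the
most probable single dilution factor; the normalization is exactly
invariant to rescaling any one sample. PQN requires complete, strictly
positive data, which is why imputation precedes it — attempting PQN or
the log transform on incomplete data raises an error that points to the
imputation step, enforcing the chain
*filter → impute → PQN → log-center*. Whether imputation or PQN comes
first is genuinely open; imputing first was chosen so that the quotient
median is computed over complete spectra rather than feature subsets that
differ per sample.

**Log + center.** Natural log, then per-feature mean centering. The log
base is a configuration knob because centered projection models are
invariant to it up to scale.

**Targeted branch.** Quantified analyte panels instead get below-LOQ
imputation (uniform in (0, LOQ)) and autoscaling (mean 0, sd 1 with the
n−1 convention; constant analytes are dropped with a warning), since
analytes live on incomparable concentration scales.

# Univariate screening

Per feature, a two-sided Mann–Whitney test (unpaired contrasts) or
Wilcoxon signed-rank test on T1−T0 differences (paired contrast), then
Benjamini–Hochberg FDR control at δ = 0.10. The exact null distribution
is used when the combined n ≤ 20 and the feature is tie-free; otherwise
the normal approximation with tie correction — at the default study size
(26 vs 16) the asymptotic form is the operative one. Zero differences are
dropped (the classical signed-rank convention) and a feature whose
differences are all zero gets p = 1. Two-sided p is
min(1, 2·min(tail probabilities)). These are standard tests; the package
delegates them to `stats::wilcox.test` / `stats::p.adjust` and validates
both against brute-force enumeration oracles in its test suite.

# PCA outlier screening

Per group, a PCA on centered data with the component count chosen as the
smallest A reaching 80% cumulative explained variance (capped to keep a
residual space; configurable). A sample is flagged when it exceeds either
the Hotelling T² limit, `A(n−1)(n+1)/(n(n−A)) · F(A, n−A; 1−α)`, or the
Q (squared prediction error) limit from the Jackson–Mudholkar
approximation, at α = 0.05. These limits are derived for a *future*
in-control observation; applied to the training samples themselves they
are conservative, which is the desired behaviour for outlier exclusion
(flag only gross anomalies). The calibration checks in the test suite
therefore score held-out samples through a fitted model, in a regime with
genuine low-rank structure and enough training samples (n = 300, p = 40,
3 strong factors) that eigenvalue estimation bias is negligible; there
both false-alarm rates sit near α. In the paired contrast, flagging one
timepoint of a subject removes the whole subject, preserving the pairing.

# PLS-DA, VIP and post-transformation

Two classes are coded −1/+1 and a single-response PLS regression is
fitted by NIPALS on column-centered data: per component, the weight
vector is the normalized covariance X'y, scores t = Xw, X is deflated by
its rank-one reconstruction, y by its projection on t. A single-response
model is exactly equivalent to the two-column dummy coding for two
classes and simpler. Predicted class is the sign of the fitted response.
At full rank the fit reproduces ordinary least squares, a property the
tests exploit as an oracle.

VIP_j = √( p Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a ) with
SSY_a = q_a² t_a't_a; Σ_j VIP_j² = p identically, so VIP > 1 means
"above-average contribution".

**Post-transformation** rotates the A-dimensional score space into one
predictive direction and A−1 directions exactly uncorrelated with the
coded response. Because the scores are mutually orthogonal,
cov(Tv, y) = v'u with u_a = q_a t_a't_a, so the predictive direction is
u/‖u‖ and any orthogonal completion (computed by QR) has zero response
covariance. The rotation is a change of basis only: fitted responses and
predictions are unchanged (verified to < 1e−10), but score plots become
interpretable — class separation lives on one axis, structured
class-unrelated variation on the others. As a diagnostic for such
structured noise, the share of score-space variation carried by the
orthogonal components can be compared with a permutation baseline; the
package keeps VIP as the importance measure throughout, which is
appropriate when that diagnostic is unremarkable.

**Number of latent variables.** Default: the smallest A in 1..5
maximizing the 5-fold cross-validated MCC; a fixed A (typically 2, which
is also what the score plots show) can be set in the configuration.

# Validation statistics

**MCC** summarizes a confusion table symmetrically in both classes and is
0 for any degenerate margin (convention). **MCCcv** comes from stratified
5-fold cross-validation in which centering is re-estimated inside each
training fold (no information leak) and held-out predictions are pooled
into one confusion. **The permutation test** recomputes MCCcv under
`n_perm = 1000` label permutations; p = (1 + #{null ≥ observed})/(1 +
n_perm), so the smallest attainable p is 1/1001.

# Stability selection

For each of B = 200 stratified bootstrap subsamples (drawn with
replacement within class, so both classes are always represented), a
PLS-DA model is fitted in-bag and features with VIP > 1 are "selected";
the out-of-bag samples are predicted by that model. A feature's selection
frequency is the fraction of subsamples selecting it. The relevance call
must separate genuinely stable features from the substantial frequency a
null feature can reach by chance, so the identical procedure is run on
`n_null = 20` label-permuted copies of the data and the observed
frequencies are compared with the (1−α) quantile of the pooled null
frequencies (α = 0.05). On null data this calibration yields relevant
sets averaging at most α·p features — the behaviour the test suite
verifies over hundreds of simulated studies. The VIP > 1 cut, α, B and
`n_null` are all configuration knobs; the frequency-versus-permutation
calibration is this package's operationalization of a significance level
for stability selection, since rank-based alternatives exist.

Each sample's out-of-bag class is the majority vote over subsamples that
left it out, ties broken by the mean out-of-bag fitted response, and
**MCCoob** is the MCC of those votes against the truth — an overfitting-
resistant performance summary complementary to MCCcv.

# Multilevel (paired) analysis

For the T0-vs-T1 contrast each subject contributes x(T1)−x(T0) labeled
"+" and its mirror labeled "−". Between-subject variation cancels exactly;
a classifier that separates the labels has found a treatment direction
consistent across subjects. Two consequences are handled explicitly:
resampling and cross-validation folds operate on *subjects*, never on
rows, because a row and its mirror are perfectly anti-correlated and
splitting them would leak; and the permutation null swaps the two labels
within randomly chosen subjects, the exchangeability operation of the
paired design. With whole subjects per fold the training set stays
exactly antisymmetric, so held-out mirror rows receive mirrored
predictions and MCC effectively counts correctly-signed subjects.

# The synthetic study generator

`generate_study()` emulates: two clinical groups (defaults 26 cases, 16
controls — pilot-study scale for pediatric EBC work), cases sampled at T0
and T1 with a subject random intercept (ICC 0.5 on the log scale),
log-normal intensities (log-sd 0.5, a mid-range spread for untargeted
EBC features), exactly `n_discriminating` features shifted between groups
by `effect_size` standard deviations on the log scale, an optional
T0→T1 shift in the case group on the same features, pooled-QC replicates
(default 5) with per-feature technical CV 0.10 except a 10% tranche at
CV 0.40 to exercise the filter, and missing values at rate 0.05.

**Missingness mechanism.** The default is intensity-dependent
left-censoring (cells are lost with probability increasing sharply as
intensity decreases), with a completely-at-random mode available
(`censor = FALSE`). The generator's job is to produce data with the
structure the analysis assumes, and the below-minimum imputation rule
assumes missing values sit below the detection level. Under MCAR,
imputing a randomly missing *high* cell with a draw near zero creates an
extreme log-scale outlier; that combination is internally inconsistent
and unrepresentative of LC-MS practice, where missingness is
predominantly censoring. Left-censoring is therefore the default, and
the MCAR mode remains available precisely to study that robustness
question.

What the generator does *not* emulate: chromatographic peak shape, batch
or injection-order drift, correlated feature blocks (adducts/isotopes of
one compound), heavy-tailed contamination. Passing tests therefore
certify the statistical machinery under the stated model, not performance
on any real instrument's quirks.

# Numerical and testing choices

Seeded operations save and restore the caller's RNG state. Reruns of the
whole pipeline under a fixed configuration are byte-identical, which the
tests check on serialized JSON. Degenerate inputs fail loudly and early:
nonpositive entries before the log, unmatched subjects in paired designs,
all-missing features, confusion tables with zero totals.

Test problem sizes were chosen to make the suite informative at desk
scale: oracle equivalence on ≥1000 random small instances per statistic;
type-I behaviour on 200 simulated null studies at the default design
(26 vs 16, p = 108) with B = 50 bootstrap subsamples and 10 calibration
permutations (a scaled-down ensemble — selection frequencies are means,
so B affects vote noise far more than calibration location); power on 50
studies with 10 planted features at standardized effect 1.5, where the
pipeline is expected to reach recall ≥ 0.7 and MCCoob ≥ 0.5 in at least
80% of runs, paired and unpaired alike; and paired null studies, where
median MCCoob and MCCcv stay below 0.1.

# Known limitations

Only two-class problems; no O-PLS-style fitting (post-transformation of a
fitted PLS-DA covers the interpretability need); no alternative
importance measure for the structured-noise regime; annotation is
accurate-mass-only (level 3) against a local table — isomers are
indistinguishable and identities remain putative; the bundled metabolite
table is a small synthetic fixture whose neutral masses were
back-computed from reported ion masses, not a spectral library.
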