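---
title: "Osteometric sex estimation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osteometric sex estimation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosex)
```

## The problem

Biological sex is a cornerstone of the skeletal biological profile. The
metric route estimates it from standard linear measurements of the
postcranial skeleton, exploiting sexual size dimorphism — male dimensions
average roughly 8–20 % larger, most markedly at joint surfaces, which
correlate with body mass and muscularity. Because the degree and pattern
of dimorphism vary between populations, classification standards are
population-specific: `osteosex` packages the published Italian postcranial
standards (developed on a documented modern cemetery collection, 200 males
and 200 females, split 75/25 into training and validation subsets) and
implements the methodology itself, so equivalent standards can be
developed for any collection.

Two classifier families are supported, chosen for field practicality
rather than statistical novelty:

* **Sectioning points.** For a single measurement, the cutoff is the
  midpoint of the male and female training means,
  $SP = (\bar{x}_M + \bar{x}_F)/2$. A value above $SP$ is called male,
  below female, exactly equal indeterminate. The rule needs one number
  and one caliper reading, and applies to isolated fragments.
* **Bone-wise logistic models.** Per bone,
  $Z = \beta_0 + \sum_j \beta_j x_j$ and $p(\text{male}) = 1/(1+e^{-Z})$,
  with $p > 0.5$ calling male. Models are fitted and applied on complete
  cases only — an individual lacking any model variable is never imputed;
  the model is simply inapplicable. This mirrors fragmentary casework:
  every bone present contributes its own estimate with its own published
  validation accuracy.

## Measurement model and laterality

The registry covers 121 measurements (`V1`–`V121`) over 46 bones grouped
into eight regions (shoulder girdle, upper limb, hand, thorax, vertebral
column, pelvic girdle, lower limb, foot), all in millimetres. For paired
elements the left side is measured, falling back to the right when the
left is absent; sides are never averaged, and all variables of a bone
model are drawn from the same resolved view. Vertebrae, sternum and
sacrum are midline elements. Values must be strictly positive and finite;
excluding pathological or callus-altered measurements is a data-entry
responsibility upstream of the package. Side provenance is retained in
long-format storage, but the standards apply identically to either side —
whether right-side fallback deserves a flag downstream is unknowable from
the published material, so the package records provenance without acting
on it.

## Measurement reliability

Repeatability is summarised by the technical error of measurement over
$N$ aligned pairs of determinations,
$$\mathrm{TEM} = \sqrt{\frac{\sum_i d_i^2}{2N}}, \qquad
  \mathrm{rTEM} = 100\,\frac{\mathrm{TEM}}{\text{grand mean}}, \qquad
  R = 1 - \frac{\mathrm{TEM}^2}{s^2},$$
with $d_i$ the within-pair difference and $s^2$ the sample variance
(denominator $2N-1$) of all $2N$ raw values. The variance entering $R$ is
computed over the raw pooled values rather than per-individual means; the
anthropometric literature is not unanimous here, and this choice is
recorded as open rather than settled. Acceptability thresholds follow the
conventions for these measurements: rTEM < 1.5 % intra-observer, < 2.0 %
inter-observer (with the broader < 5 % literature bound also reported) and
$R > 0.95$. Flags are advisory only — no measurement is ever excluded
automatically, matching the reference protocol. Negative $R$ (possible
when between-subject variance vanishes) is reported as computed, never
clamped: surfacing a degenerate design beats hiding it. A multi-session
generalisation `tem_multi()` is provided as an extension; the packaged
standards used exactly two determinations per test.

## Screening and sectioning points

Each measurement is screened on the training subset: Shapiro–Wilk per sex
at $\alpha = 0.05$ (samples beyond the test's 5000-value limit are
truncated; power is ample there), then a pooled-variance Student's t-test
when both sexes look normal, otherwise a Mann–Whitney U test. "Student's
t" is deliberately the classical equal-variance test, not Welch, for
fidelity to the methodology being reproduced. The normality gate is
applied per sex — the published description is silent on per-sex versus
pooled testing, and per-sex is the stricter reading. No multiple-testing
correction is applied across the 121 screens by default, again matching
the source protocol; a Holm adjustment is available behind
`p_adjust = "holm"` as an explicit extension.

Only measurements that screen significant with males larger receive
sectioning points; female-larger variables (minimum pubis length,
ischiopubic ramus length, anterior sacral breadth in the reference
collection — obstetric adaptations of the female pelvis) are excluded
from univariate standards, though they may still enter logistic models.

Accuracy is reported per sex (%M, %F), overall, and as class
discrimination bias %M − %F with the recommended ±5-point band.
Indeterminate calls count as incorrect — the convention is not stated in
the source material, and counting boundary cases as successes would
flatter the standards. Two overall-accuracy conventions are provided:
`balanced` (mean of the per-sex rates, the stated rule) and `pooled`
(total correct over total n). They differ when per-measurement sample
sizes are unbalanced, and some published overall values are consistent
only with the pooled form; the package therefore offers both and asserts
neither for those cells.

## The packaged standards bundle

The bundle transcribes the published tables: 118 sectioning points (121
measurements minus the three excluded above) with their per-sex training
means, sample sizes and train/test performance, and 43 logistic models
covering 32 bones (metacarpals and metatarsals, carrying a single length
measurement of modest accuracy, received no models). Coefficients are
stored as decimal strings and parsed at load, preserving the printed
digits bit-exactly. Two transcription anomalies are worth knowing about:
one carpal row's printed per-sex counts do not sum to its printed total,
and the first-rib model lists two variables in its performance table but
carries a single printed coefficient (maximum chord); the packaged model
follows the coefficients, keeping the printed performance as provenance.

Validation at load re-checks every invariant: known codes, one
coefficient per variable, variables drawn from the model's bone, male
mean above female mean, and the midpoint identity
$|SP - (\bar{x}_M+\bar{x}_F)/2| \le$ `sp_tolerance`. The default
tolerance is 0.05 mm — half the printed 0.1 mm resolution — because
published means rounded to one decimal cannot reproduce a half-way
midpoint exactly, and about half of the printed sectioning points fall on
such half-way points (rounded inconsistently, some up, some down).
Bundles emitted by `develop_standards()` carry full-precision values and
pass `sp_tolerance = 0` (well, `1e-9`) checks. Display rounding uses
half-away-from-zero (`round_half_up()`), the tabular convention; stored
values are never rounded.

The casework applicator reports every applicable standard and lists every
inapplicable one with its missing codes. No cross-bone aggregation is
performed by default because the published methodology defines none; an
accuracy-weighted majority vote is available behind `vote = TRUE`,
clearly labelled an extension. The fourth-rib standard carries an
age-trend caution (its width increases with age, and the reference
collection skews old), surfaced verbatim in reports.

## Synthetic data: what it emulates, and what it does not

The generator draws, per sex and per bone, from a multivariate normal
with the packaged training means, $\sigma = cv \cdot \mu$, and
equicorrelation $\rho$ within each bone block, truncated at zero by
redraw (preserving positivity without a point mass at a clip boundary).
Whole-bone loss (taphonomy) and per-measurement MCAR missingness are
applied on top. Defaults: $cv = 0.05$, a typical coefficient of variation
for adult osteometric dimensions — the source publishes no per-measurement
standard deviations, so this is a modelling assumption, stated as such —
and $\rho = 0.6$, reflecting the strong shared size signal of
measurements on one bone. Repeat-measurement sessions add independent
Gaussian error with SD equal to a configurable percentage of the true
value (default 1 %), which makes TEM converge to that error SD and rTEM
to that percentage.

Consequences worth stating plainly: synthetic accuracies are driven by
the assumed $cv$, so they can be compared to closed forms (for
equal-variance normal sexes with mean separation $\delta$, the midpoint
rule's per-sex accuracy converges to $\Phi(\delta/2\sigma)$) but **not**
to the published accuracies, which depend on the real collection's
unpublished dispersions. The generator also omits age structure, secular
trends, measurement-correlated missingness and between-bone correlation
beyond sex. Passing pipeline tests on synthetic data therefore validate
the algorithmic machinery, not the anthropological performance of the
standards.

## Numerical and reproducibility choices

Logistic fitting uses unpenalised maximum likelihood (`stats::glm`,
binomial), epsilon $10^{-8}$, a 100-iteration cap and a zero start, so
refits on identical data are bit-reproducible. Complete separation is
detected from saturated fitted probabilities and flagged on the model
rather than silently accepted. A minimum of 10 complete cases per sex
(configurable) is required per bone model. Scores at exactly $p = 0.5$
are indeterminate; the boundary has measure zero in practice and is kept
for logical completeness.

All stochastic components (generation, splitting) consume explicit seeds
and restore the caller's RNG state; `develop_standards()` derives its
stage behaviour from one master seed, so a rerun with the same data,
seed and configuration emits a byte-identical bundle (numbers are
serialised as full-precision decimal strings for exactly this reason).
The stratified split assigns `round(fraction * n)` per sex — 150/150
training and 50/50 test individuals from a 200/200 collection at the
default 0.75.

The test suite exercises the closed-form accuracy check at 5000
individuals per sex, logistic parameter recovery at 20 000, and the full
development pipeline on a 400-individual synthetic collection with 5 %
measurement missingness and 5 % bone loss — sizes chosen to hold
Monte-Carlo error comfortably below the tested tolerances while keeping
the suite quick.

## Known limitations

The packaged standards are population-specific (Northern Italian,
20th century) and should not be transferred to other populations without
revalidation. The package reproduces the published decision rules
exactly, including their conservative conventions (no imputation, no
aggregation, indeterminate-as-incorrect); it does not attempt ROC-optimal
cutpoints, probability recalibration, or machine-learning alternatives,
all of which are out of scope by design. Reliability statistics require
the unpublished repeat-measurement raw data to be reproduced numerically;
the package therefore verifies its TEM/rTEM/R implementation against
brute-force oracles and simulated observer error instead.
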