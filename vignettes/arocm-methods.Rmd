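---
title: "Methylation aging rates and maximum lifespan: models and methods"
author: "arocm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation aging rates and maximum lifespan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arocm)
```

## The problem

When the same aging biomarker is measured in many species, its per-year
rate of change almost inevitably correlates with the inverse of maximum
lifespan — not necessarily because biology couples the two, but because
the rate is *defined* per year while species live very different numbers
of years. `arocm` implements the estimation framework that separates the
arithmetic part of this relation from the biological part, for DNA
methylation measured as beta values on a conserved-CpG array, with the
stratum (species × tissue, or dog breed) as the estimation unit.

## The model

Within one stratum with `n` samples, mean methylation over a chosen CpG
set is averaged per sample (`Methyl_i`), standardized to mean 0 and
population SD 1 (`ScaledM_i`), and regressed on chronological age. The
slope of that regression is the AROCM. All moments in the package use the
population divisor `n`; the Pearson correlation is divisor-invariant but
the standardized values and `SD(R)` are not, and the exact identities
below only hold under one consistent convention.

With relative age `R = Age/L` (optionally `R = (Age+GT)/(L+GT)` when
prenatal samples with negative ages are present, `GT` = gestation time),
the slope decomposes exactly as

\[
\mathrm{AROCM} \;=\; \frac{\mathrm{Cor}(\mathrm{Methyl},\,\mathrm{Age})}
{\mathrm{SD}(R)\,\cdot\,L},
\]

which `estimateAROCM()` returns together with all decomposition terms.
With gestation time the denominator is `SD(R)·(L+GT)`; the tests of the
identity use `GT = 0`.

`SD(R)` reflects which ages happened to be sampled — a property of study
design. The adjustment of `adjustStats()` with power `p ∈ [0, 1]`,

\[
\mathrm{Adj.Cor}(p) = \frac{\mathrm{Cor}}{\mathrm{SD}(R)^p}, \qquad
\mathrm{Adj.AROCM}(p) = \mathrm{AROCM}\cdot \mathrm{SD}(R)^{1-p},
\]

preserves the exact identity `Adj.AROCM = Adj.Cor / L` for every `p`
(`p = 1` leaves the rate unadjusted, `p = 0` leaves the correlation
unadjusted). Because `R ⊂ [0,1]` implies `SD(R) ≤ 0.5`, the adjusted
correlation is strictly decreasing in `p` for positively correlated
strata.

### Propositions

Across `S` strata, `log Adj.AROCM = log Adj.Cor − log L` for the strata
where the logs exist (non-positive values are excluded and counted —
`propositionChecks()` reports the exclusion count rather than silently
producing NaN). If the sample correlation between `log L` and
`log Adj.Cor` is zero (condition C1), then

\[
\mathrm{Cor}(\log L,\ \log \mathrm{Adj.AROCM})
 = \frac{-1}{\sqrt{1 + \mathrm{Var}(\log \mathrm{Adj.Cor})/
 \mathrm{Var}(\log L)}} .
\]

As the variance ratio tends to 0 the correlation tends to −1 and
`Adj.AROCM ≈ c(p)/L` with `c(p) = exp(mean log Adj.Cor)`. The report also
carries the squared coefficient-of-variation ratio, the delta-method
approximation of the same quantity on the original scale. When the
adjusted correlations are constant to numerical precision, C1 is
undefined and reported as 0 (its limiting value); correlating `log L`
against pure floating-point jitter would otherwise produce an arbitrary
number.

### Choosing the adjustment power

`selectAdjustmentPower()` minimizes a dispersion objective of
`Adj.Cor(p)` over a grid (default step 0.005, ties to the smallest `p`).
The default objective is the quartile coefficient of dispersion
`(Q3−Q1)/(Q3+Q1)` of the *raw* adjusted correlations, with quartiles by
linear interpolation (`quantile()` type 7, fixed so results are
reproducible across platforms); a variant applies the QCOD to their logs
and another uses the coefficient of variation. The raw-value default was
chosen because it is well-defined whenever the correlations are positive
(the log variant can produce a non-positive denominator) and is
scale-invariant, which is exactly the property that makes the objective
flat — and the power unidentifiable — when `SD(R)` is constant across
strata; that situation is detected and flagged rather than silently
returning an arbitrary grid point. No inference (standard errors,
cross-validation) is attached to the selected power: the selection is a
descriptive minimization and is known to risk overfitting, which is why
pipelines should report adjusted and unadjusted results side by side.

## The life-course model

Methylation trajectories are non-linear over the full life course but
close to linear in the transformed relative age

\[
g(R) = \begin{cases} R/k - 1 & R \ge k \\ \log(R/k) & R < k \end{cases}
\qquad k = 0.1,
\]

which is continuous with continuous derivative at the knot (`g(k)=0`,
`g'(k)=1/k`). The all-logarithmic alternative `g2(R) = log(R/k)` is
provided for comparison. The natural logarithm is used throughout; the
knot is configurable for sensitivity sweeps (0.2–0.9). `fitLifeCourse()`
estimates `ScaledM = γ0 + γ1·g(R)` by least squares and warns when the
relative ages do not span both sides of the knot (the piecewise shape is
then unidentified). The derivative-based rate at reference relative age
`R0` is `γ1·g'(R0)/L` — `γ1/(R0·L)` for young references, `γ1·(1/k)/L`
for old ones — giving the within-stratum proportionality
`AROCM_young = (k/R_young)·AROCM_old`. The reference age `R0` is an
explicit argument everywhere: the model does not prescribe a canonical
midpoint, so the package does not choose one silently.

Because the response is standardized, the fitted `γ1` is unitless and,
for noiseless data, equals `1/SD(g(R))` — the generator's raw amplitude
is not recoverable after standardization, which is why the synthetic
truth table records both the raw `gamma1` and this standardized-scale
`gamma1_scaled`; recovery metrics compare against the latter.

## Quality-control filters

`filterConfig()` encodes the two published modes. Both reject `n < 3`.
The relative-age dispersion rule rejects `SD(R) < 0.1` (dog) or
`SD(R) < 0.06` (mammal; the looser threshold keeps enough of the more
numerous mammalian strata). Dog mode additionally rejects fits with
`R² < 0.2`; mammal mode rejects rates outside the open interval
`(−1, 10)` — but only after `derivedIntervalCheck()` re-estimates the
rate on the derived relative-age intervals `[0, 0.2)` and `[0, 0.3)`
within the same stratum: the stratum is declared an outlier only when
both derived rates fall back inside the range, i.e. the extreme value is
not reproduced on adjacent windows. Three design choices the published
rules leave open:

* a stratum whose derived rates are *also* out of range is kept and
  flagged for review (the literal reading of the rule), not dropped;
* if fewer than two derived rates are estimable (too few samples,
  degenerate sub-stratum), the out-of-range stratum is rejected
  conservatively with reason `arocm_range_unverifiable`;
* rules are evaluated independently and all violations reported —
  decisions are pure, deterministic functions of (view, stats, config),
  and loosening any threshold can only keep more strata.

## Comparative layer

Species-level values are tissue medians over kept strata. Lifespan
correlations are available raw, log-log (with the power-law slope),
against `a/L` (with `a = c(p)` for adjusted metrics) and as Spearman
against `1/L`; two-sided p-values use the t approximation
`t = r·sqrt((n−2)/(1−r²))` for both Pearson and Spearman, matching the
convention of reporting a single test family throughout. Lifespan groups
are `<10`, `10–19`, `20–24`, `25–39`, `≥40` years with boundaries
assigned upward. The Mann–Kendall trend statistic is computed on group
ranks (within-group pairs contribute zero), with the full tie correction
for ties in both rankings and a continuity-corrected normal
approximation; it is hand-implemented because no trend-test package is
among the dependencies, and the tests verify `S` against brute-force
pair enumeration up to `n = 50`. Models M1–M4 are ordinary least squares
on the log scale; M4's tissue indicators (brain, blood, skin, liver,
muscle, tail) require at least one stratum outside those categories, or
the design is collinear with the intercept and rejected with an error.

## The synthetic generator

`simulateStudy()` emulates the features of consortium-style data that
the estimators are sensitive to, with defaults chosen once as a
realistic mammalian-study regime:

* lifespans log-uniform on 2–80 years (shrew-to-elephant range);
* per-stratum uniform relative-age windows, starts in [0.02, 0.3] and
  widths in [0.3, 0.7] — window geometry, not biology, generates the
  `SD(R)` heterogeneity (for a uniform window `[a,b]`,
  `SD(R) = (b−a)/√12`, which the tests verify);
* two CpG groups of 20 probes: a low-baseline (0.1–0.2) group with
  positive amplitudes and a high-baseline (0.8–0.9) group with negative
  amplitudes, so negative-rate strata exist and the non-positive-
  correlation exclusion paths are exercised;
* per-probe beta amplitudes 0.02–0.04 and life-course amplitudes
  `γ1 ∈ [0.5, 1.5]` — a few percent of methylation change over a
  lifetime, typical of age-gaining low-methylated states;
* probe-level noise SD 0.01 and sample-level noise SD 0.005 on the beta
  scale; betas clipped to [0,1] with the clipping rate reported (the
  default regime clips essentially nothing);
* windows and amplitudes drawn independently of lifespan, so condition
  C1 holds by design as `S` grows.

What it does **not** emulate: probe chemistry and cross-species
mappability, tissue-specific effects beyond stratum labels, phylogenetic
correlation between strata, and the exact generative distributions of
any external simulation study. Consequently, passing recovery tests
demonstrate that the estimators are correct under the stated model — not
that real consortium data satisfy that model.

`makeCorStratum()` complements the generator with a deterministic
construction: a methylation vector with an *exact* prescribed Pearson
correlation with age (a standardized age component plus an orthogonal
alternating component). This is what lets the proposition checks be
tested against closed forms at tolerance `1e-8` rather than
Monte-Carlo error.

One deliberately included artifact: on pure-noise data (zero
amplitudes), selecting probes *post hoc* by their realized positive age
correlation within each stratum manufactures positive rates of size
`∝ 1/(SD(R)·L)`, producing a strong spurious correlation with `1/L`
from nothing. The test suite asserts this inflation relative to
state-based (annotation-driven) selection on the same data — the reason
the package selects CpGs by chromatin state, never by age correlation.

## Numerical conventions and problem sizes

Degenerate strata (constant ages or methylation, `n < 2`) raise typed
conditions (`arocm_degenerate_stratum`) with a reason code rather than
returning NaN, so batch estimation can log them; `estimateStrata()`
collects skipped strata in an attribute. Probes and samples are kept in
lexicographic order so floating-point sums are bit-reproducible on one
platform, and output tables are written at full precision (`%.17g`), so
`read.csv(write...)` round-trips exactly. Identity tests run at
`1e-9`/`1e-10`; closed-form proposition constructions at `1e-8`. The
test suite uses up to 1,000 random strata for the identity sweep, 200
strata for the C1 design, and 50 strata × 200 samples for noisy
parameter recovery — sizes at which every Monte-Carlo margin in the
suite is comfortable while the whole suite runs in well under a minute.

## Limitations

The adjustment power is selected by minimizing an in-sample dispersion
and can overfit; report adjusted and unadjusted results together. The
inverse-lifespan law is chromatin-context dependent — in high-methylation
contexts rates are negative and the relation weakens or reverses — and
the package treats state labels as opaque annotation, performing no
chromatin-state inference. Phylogenetic non-independence between species
is out of scope (no phylogeny is consumed), as are array preprocessing
and normalization: inputs are assumed to be cleaned beta values.
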