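---
title: "Decomposing RT-qPCR technical noise and optimizing sampling plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing RT-qPCR technical noise and optimizing sampling plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrdesign)
```

## The measurement model

A Cq value produced by an RT-qPCR workflow carries noise from every
preparative stage, not just the amplification itself. qpcrdesign models a
single stratum — one subject, one tissue, one gene — as a fully nested
Gaussian random-effects model:

$$Cq_{ijk} = \mu + a_i + b_{j(i)} + c_{k(ij)}$$

where $a_i \sim N(0, \sigma^2_i)$ is the effect of the $i$-th RNA
sampling/extraction, $b_{j(i)} \sim N(0, \sigma^2_j)$ the effect of the
$j$-th RT reaction prepared from extraction $i$, and
$c_{k(ij)} \sim N(0, \sigma^2_k)$ the effect of the $k$-th qPCR run from
that cDNA. The model's key assumptions are (a) effects at different levels
are independent, so the variance of a single measurement is the plain sum
$\sigma^2_{Cq} = \sigma^2_i + \sigma^2_j + \sigma^2_k$; (b) noise is
additive and Gaussian on the Cq (cycle) scale, which is a log scale for
template abundance; and (c) within one treatment group there are no fixed
effects left — the stratum mean $\mu$ absorbs everything systematic.

A nested pilot experiment — split each tissue sample into several
extractions, each extraction into several RTs, each RT into several qPCR
wells — makes all three components identifiable from Cq values alone.

## Estimation: unbalanced nested ANOVA by the method of moments

`nested_anova()` computes sequential (Type-I) nested sums of squares from
group means, and `estimate_components()` solves the expected-mean-square
(EMS) equations bottom-up:

$$\hat\sigma^2_k = MS_{qpcr}, \qquad
  \hat\sigma^2_j = \frac{MS_{rt} - MS_{qpcr}}{c_1}, \qquad
  \hat\sigma^2_i = \frac{MS_{sampling} - MS_{qpcr} - c_2\hat\sigma^2_j}{c_3}.$$

The coefficients $c_1, c_2, c_3$ are recomputed from the realized group
sizes, so missing reactions (excluded complete-case) and unbalanced layouts
are handled exactly; in a balanced design with $n_j$ RTs per extraction and
$n_k$ qPCRs per RT they reduce to $n_k$, $n_k$ and $n_j n_k$, giving
$(3, 3, 12)$ for the default 4 × 4 × 3 layout. This estimator is the
classical method-of-moments nested ANOVA (the computation performed by
SAS's PROC NESTED); REML was deliberately not used, both to match the
established computation for this design and because the method-of-moments
solution is available in closed form and unbiased on the variance scale.

Numerical choices worth knowing about:

* **Negative raw solutions.** Method-of-moments differences can go
  negative when a component is small relative to downstream noise. The raw
  RT solution is carried (untruncated) into the sampling equation, then all
  final solutions are truncated at zero and the truncated levels recorded;
  `truncate = FALSE` preserves the raw values for diagnostics.
* **Zero sums of squares.** Sums of squares below $10^{-12}$ cycles² are
  set to exactly zero to stop floating-point cancellation from producing
  spurious tiny negative components on constant input.
* **Estimability.** A level with zero degrees of freedom (one extraction;
  every RT with a single well) is flagged, not silently zeroed;
  `validate_hierarchy()` reports such strata before estimation.
* **Subject level.** The model has no subject term, so each subject's
  stratum is estimated separately (`estimate_by_group()`), and
  `average_components()` averages the SD estimates across subjects of the
  same tissue × gene. Pooled multi-subject estimation is not offered: it
  would require a fourth nesting level the model does not contain.

## Noise calculus

`total_noise()` combines components into the total SD of a single
measurement and per-step percentage contributions; `se_of_mean()` applies
the $\sigma/\sqrt{N}$ averaging rule for replicate means; `cq_to_fold()`
converts Cq differences to fold changes, $(1+E)^{\Delta Cq}$ with perfect
doubling $E = 1$ by default; `three_five_ratio()` implements the
comparative-Cq 3′:5′ RNA-integrity check with the conventional 4.5-fold
adequacy threshold.

Note that the *empirical* SD of pooled Cq values across subjects can
legitimately exceed the combination of the three step components, because
it also contains between-subject spread. Decompose reports therefore carry
both numbers, labeled `sd_total_steps` (the three-component combination)
and `sd_empirical` (the observed per-stratum SD).

## Planning: expected variance of a group mean

For a balanced plan with $n_i$ extractions per subject, $n_j$ RTs per
extraction and $n_k$ qPCRs per RT, each subject's mean Cq has expected
variance

$$\sigma^2_{Cq_g} = \frac{v_{sampling}}{n_i} + \frac{v_{rt}}{n_i n_j}
 + \frac{v_{qpcr}}{n_i n_j n_k},$$

and averaging over $n_s$ subjects divides the total by $n_s$ (plus an
optional between-subject term $v_{subject}/n_s$, default 0). Upstream
replicates are therefore worth more than downstream ones: an extra
extraction averages all three components at once, an extra qPCR well only
the last.

**The scale declaration.** `step_noise()` refuses to guess whether its
inputs are SDs or variances: published step-noise tables are sometimes
used unsquared in exactly this plan arithmetic, and silently squaring (or
not) is the easiest way to be wrong by an order of magnitude. The declared
scale is recorded in the object and echoed in reports. Reproducing the
bundled pilot's published plan tables requires declaring the table values
as `variance`.

## Budget-constrained optimization

`optimize_plan()` enumerates every balanced integer plan whose cost

$$n_s\,(C_{subject} + n_i (C_{sampling} + n_j (C_{rt} + n_k\,C_{qpcr})))
  \times n_{conditions}$$

fits the budget, subject to a floor on biological replicates
(`min_subjects`, default 3 — fewer biological replicates would satisfy the
variance criterion while undermining any biological conclusion, so the
floor is applied by default and echoed in reports). Upper bounds per count
are derived from the budget; a level with zero marginal cost must be given
an explicit bound because the objective strictly decreases in every count
above a positive component.

**Comparison precision.** The optimizer compares plan variances at the
reporting precision (2 decimals by default, `tie_digits`), breaking ties by
lower cost, then fewer qPCR reactions per condition, then lexicographic
order. The rationale: step components estimated from a small pilot (3–15
degrees of freedom per level) carry sampling error far larger than
third-decimal differences in a predicted variance, so plans whose
predictions agree at that precision are practically indistinguishable, and
preferring the cheaper/smaller one is the sensible tie-break. With exact
comparison (`tie_digits = NULL`) the optimizer instead returns the exact
minimizer, which may be a marginally "better" plan with substantially more
reactions. Enumeration is exhaustive either way — the search spaces
realistic budgets produce are tiny, so no relaxation is needed.

## The simulator

`simulate_stratum()` and `simulate_study()` generate datasets directly
from the measurement model: Gaussian effects drawn once per extraction,
RT and well, summed with the stratum mean, with optional
missing-completely-at-random knockouts. Design defaults (4 extractions ×
4 RTs × 3 qPCRs) and the bundled `pilot_presets()` noise magnitudes mirror
a real nested pilot in blueberry tissues, so a default two-plant,
three-tissue, three-gene study yields 864 reactions in 18 strata.

What the simulator deliberately does *not* emulate: amplification curves
and per-well efficiencies, non-Gaussian or heteroscedastic noise,
informative missingness (dropout correlated with high Cq), and
between-run/plate effects. Passing parameter-recovery tests on simulated
data therefore demonstrates that the estimator inverts the model
correctly, not that real data satisfy the model; with real data the
usual caveats about outliers and efficiency differences apply before the
Gaussian decomposition is meaningful.

One practical wrinkle: with `missing_rate > 0` the knockout pattern is
redrawn (up to 100 times) if it would leave a stratum with no observed
record, so generated datasets always pass dataset validation; at realistic
missing rates this distorts the MCAR mechanism negligibly.

## Parameter recovery, and how it is measured

The package's recovery tests simulate 500 strata at the default 4 × 4 × 3
design with step SDs (0.45, 0.73, 0.32) and require the recovered SDs to
lie within 10% of truth. Recovery is aggregated on the **variance scale**
(the recovered SD is the square root of the mean estimated variance): the
method-of-moments estimator is unbiased for variances, whereas the mean of
per-replicate SD estimates is biased low at few degrees of freedom (the
square root is concave — at 3 sampling-level df the bias is near −18%
even though the variance estimates are centered correctly). Averaging
variances and then taking the root is the aggregation under which
"recovery" measures estimator correctness rather than small-sample
concavity.

Problem sizes used by the test suite — 500 × 48-record strata for
recovery, 30-replicate RMSE comparisons at 4 × 4 × 3 vs 20 × 20 × 10, one
200 × 200 × 10 stratum for large-sample checks — were chosen to make the
Monte-Carlo error comfortably smaller than the asserted tolerances while
keeping the default test run fast.

## Known limitations

* Point estimates only: no confidence intervals on components and no
  power analysis for detecting a stated fold change.
* Complete-case handling assumes missingness is unrelated to the Cq value;
  systematically censored high-Cq reactions would bias components low.
* Only balanced plans are enumerated; unbalanced allocations (different
  RT counts per extraction, say) are out of scope.
* The comparative-Cq fold conversion assumes a single efficiency for both
  amplicons; per-assay efficiencies can be passed but are not bundled.
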