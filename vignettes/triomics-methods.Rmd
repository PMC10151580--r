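---
title: "Small-cohort trans-omics correlation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-cohort trans-omics correlation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## The setting

The package targets a study design that is common in post-mortem brain
research and awkward for standard omics statistics: a handful of subjects
(typically 3 cases and 3 controls) measured on several omics layers —
lipid species, differentially expressed genes, proteins — with the goal of
finding factors that co-vary *across* layers, and of asking which factor in
a correlated triple drives the other two. Nothing in the procedure is
specific to brains or schizophrenia; it applies to any multi-layer design
with very few shared samples.

At these sample sizes the only defensible inferential tools are exact ones.
The pipeline therefore rests on three classical ingredients — the
correlation t-test inverted into a critical coefficient, Dixon's Q outlier
test with tabulated critical values, and the first-order partial
correlation — assembled into a deterministic, fully reportable procedure.

## The model and its assumptions

Each layer is a factor × sample matrix of real-valued, already-quantified
measurements (signal intensities, FPKM, quantitative protein signal). The
procedure assumes nothing about their marginal distributions beyond what
the Pearson t-test assumes (approximate bivariate normality under the
null), and treats the 6 subjects as a single group: cases and controls are
pooled, which means a strong group separation can itself produce a
cross-layer correlation. That is a known property of the design, not a bug;
the covariate stage exists to probe exactly this kind of driving variable.

### Exact critical coefficients

For a coefficient $r$ on $n$ pairwise-complete samples,
$t = |r|\sqrt{n-2}/\sqrt{1-r^2}$ has a $t_{n-2}$ null distribution.
`critical_thresholds(alpha, df)` inverts this:
$r_{\mathrm{crit}} = t_{\mathrm{crit}}/\sqrt{t_{\mathrm{crit}}^2 +
\mathrm{df}}$ with $t_{\mathrm{crit}}$ the two-sided upper quantile. Two
consequences shape everything downstream:

* at $\alpha = 0.01$, $\mathrm{df} = 4$ (six samples):
  $t_{\mathrm{crit}} = 4.604$, $r_{\mathrm{crit}} = 0.91719$;
* at $\mathrm{df} = 2$ (four samples) the $t_2$ CDF has the closed form
  $\tfrac12 + t/(2\sqrt{2+t^2})$, so $r_{\mathrm{crit}}(\alpha) = 1-\alpha$
  *exactly*: 0.99. Factors sharing only four samples essentially cannot
  reach significance, and the screen reports them with their own stricter
  threshold rather than a global one.

Reports quote $r_{\mathrm{crit}}$ truncated (not rounded) at five decimals
— hence 0.91719 rather than the rounded 0.91720 of the full-precision value
0.9171997 — so a printed threshold never exceeds the exact one. All
comparisons use full precision.

Every pair is tested at the per-pair level with **no multiplicity
correction**: with ~10² tests and $\alpha = 0.01$ the expected number of
false flags is of order one, and the screen reports the number of tests so
users can correct if they prefer. The test suite verifies the calibration
directly: on ≥50,000 independent Gaussian pairs at $n = 6$ the flagged
fraction is 0.01 within Monte-Carlo error.

### Outlier screening

`dixon_q()` implements the classic r10 (gap/range) statistic on a factor's
pooled values: $q_{\mathrm{high}} = (x_{(n)}-x_{(n-1)})/(x_{(n)}-x_{(1)})$,
$q_{\mathrm{low}} = (x_{(2)}-x_{(1)})/(x_{(n)}-x_{(1)})$, the larger of the
two compared with Rorabacher's two-tailed critical values (embedded for
$n = 3\ldots30$; 0.90/0.95/0.99 confidence, default 0.99). Choices made
where the convention is genuinely open:

* the test is applied **once per factor over all pooled samples**, not per
  diagnosis group — matching a whole-group correlation analysis — and not
  iterated after a removal (single exclusion round);
* at most one value is flagged per factor and call; on a tie between the
  low and high side, the high side is tested (an arbitrary but fixed
  choice);
* sorting is stable by value then sample ID, so outputs are deterministic
  under ties.

What "excluded from the analysis" should mean is ambiguous at the cell vs
factor level, so the policy is explicit: `drop-value` (default) blanks the
flagged cell and lets the factor continue with reduced pairwise n;
`drop-factor` removes it entirely; `keep` only records the flag. Whatever
the policy, the report carries a sensitivity table giving each flagged
factor's cross-layer correlations both with and without the flagged value,
so the reader sees what the exclusion did.

### Mediation triangulation

`find_triads()` enumerates triples, one factor per layer, whose three
cross-layer correlations are all flagged. For each triad
`mediation_profile()` computes, on the triple-complete samples, the three
marginals and the three first-order partials
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$.

Partials carry **no significance test** — at $n \le 6$ any such test would
be decorative — so classification compares magnitudes against two
thresholds: a pair has *collapsed* when its partial magnitude falls below
`drop_threshold` (default 0.30) and *retained* at or above
`retain_threshold` (default 0.50). The defaults were chosen to reproduce
the verbal convention of calling 0.11 "poor" and 0.60–0.71 "strong" in this
kind of analysis; both are user-configurable and the report prints them.
The rule set:

* *mediated-by-z*: $|r_{xy\cdot z}|$ collapsed, both partials involving z
  retained (and cyclically for x, y); two simultaneous firings are
  *indeterminate*;
* *direct*: every strongly correlated pair ($|r| \ge$ retain) keeps a
  retained partial;
* otherwise *indeterminate*.

The rule is symmetric under relabeling — permuting (x, y, z) permutes the
classification accordingly — which the tests assert, and triad slots follow
lexicographic layer order, so the mediator's slot depends on the layer
names, not on any privileged position.

### Covariate adjustment

`covariate_analysis()` correlates each triad factor with each clinical
covariate and recomputes each factor-pair correlation as a partial
controlling the covariate. Covariate conventions: `CPeq`
(chlorpromazine-equivalent antipsychotic dose, mg/day) is 0 for every
control; a missing dose for a control is imputed as that 0, while a missing
dose for a case is an error rather than a silent guess. `AoD` is age at
death in years; any other numeric metadata column can be named directly. A
covariate constant over the analyzed samples is a hard error ("degenerate
covariate"), not a NaN.

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` emulate the target design: 3 + 3
subjects, layers of 2 / 7 / 17 factors by default, with one planted
structure and everything else independent unit Gaussian noise. All planted
factors are scaled to unit population variance, so loadings *are*
population correlations — under `mediated` with loadings $a, b$:
$\rho_{xz} = a$, $\rho_{yz} = b$, $\rho_{xy} = ab$ — which makes every
recovery target analytic. Structures: `mediated` (x, y driven by a
mediator z in the third layer), `direct` (y driven by x, z independent),
`confounded` (x, y driven by the standardized dose covariate), `null`.

Defaults chosen once, as study conditions:

* loadings 0.95 (a strong planted signal of the size the screening
  threshold is designed to catch at moderate n);
* `group_shift = 0`: the default cohort is a pure correlation structure
  with no case-control offset, so empirical correlations estimate the
  loadings directly. A nonzero shift (available as a parameter) adds the
  group-separation component real case-control data would have;
* SCZ doses uniform on 200–1200 mg/day — a realistic chlorpromazine-
  equivalent range for chronically medicated patients — and 0 for controls;
* ages uniform on 60–90 years, PMI on 4–45 h, matching the spread of
  typical post-mortem cohorts.

One root seed drives deterministic per-component substreams (metadata,
planted structure, one per layer), so adding a layer never perturbs the
existing ones and every written file is byte-reproducible. A truth record
(YAML) stores the planted factors, loadings, residual SDs and every
injected outlier with its original value; tests read the truth record and
never reverse-engineer the generator.

What the generator deliberately does **not** emulate: heteroscedastic or
count-based noise, batch effects, correlated background factors, realistic
lipid/transcript dynamic ranges. Passing tests therefore demonstrate that
the *procedure* recovers planted linear structure under clean Gaussian
conditions — not that real post-mortem data meet those conditions.

## Numerical choices and degenerate inputs

* t quantiles come from `qt()` (R's incomplete-beta inversion, accurate to
  machine precision); no p-values are reported anywhere, by design — the
  fixed-α threshold is the inferential object.
* Correlations are clamped to $[-1, 1]$ against floating-point overshoot;
  $|r| = 1$ yields an infinite t, reported as such in screens, while the
  scalar `t_from_r()` signals it as a distinct error class.
* Pairwise-complete deletion everywhere; a pair with fewer than 3 complete
  samples (4 for a partial) is reported as skipped with a reason, never
  silently dropped. Zero-variance factors and collinear controls are
  distinct error classes.
* Sample order is canonical everywhere (metadata row order), sorts are
  stable, and all output files are written with fixed formats — identical
  inputs give byte-identical bundles.

## Problem sizes in the test suite

The suite exercises the design size ($n = 6$) for distributional claims
and $n = 1000$ (500 + 500) where a property should hold with near
certainty: planted-loading recovery within ±0.03, mediation recovery and
direct/mediated discrimination across 100 seeds each, type-I calibration
on 50,176 null pairs, and the $n = 6$ marginal-vs-partial mediation
signature across 200 seeds. These sizes keep the whole suite under a
minute on one CPU while leaving Monte-Carlo error well inside every
asserted band.

## Known limitations

* With ~150 correlated tests at α = 0.01 and no multiplicity correction,
  occasional spurious triangles are expected and are reported alongside
  genuine ones; the mediation profile, not the screen, is what
  discriminates them.
* First-order partials only: higher-order adjustment (two controls at
  once) is out of scope, as is any formal causal mediation machinery
  (Sobel tests, bootstrap CIs, SEM) — magnitudes are compared, nothing
  more is claimed.
* Dixon's Q tests a single outlier per factor; masked multiple outliers
  require different tools.
* Within-layer correlation structure is never screened; the procedure is
  strictly cross-layer.
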