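---
title: "Activity regulation and metabolic scaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity regulation and metabolic scaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antscale)
library(dplyr)
```

`antscale` analyses activity regulation in social-insect colonies from
short tracked videos. The observational unit is a colony of `N*` workers,
of which `N` are visually trackable (about 85% in the design the package
assumes), filmed for 30 s in a 248 mm square enclosure at 15 frames/s with
positions recorded every 5th frame (90 samples per worker at 3 Hz). From
these trajectories the package derives, per colony: the mean and median
per-worker path length `L`, the number of active workers `A`, the
time-averaged interaction count `E` of the spatial proximity network, and
the spanned area; and it fits two models that connect these quantities to
colony size and to whole-colony metabolic rate.

## From trajectories to summaries

**Activity.** A worker is *active* when its average speed over the video
strictly exceeds 0.1 mm/s — equivalently, when it travels more than 3 mm in
30 s. The strict inequality matters only for workers exactly at the
threshold, but it is fixed so the boundary case is reproducible. Path
lengths are summed over the 3 Hz samples with no interpolation to the full
frame rate, matching the resolution at which identities exist. Partially
tracked workers are kept and flagged; their speed uses their own observed
time span (span plus one sampling interval) so that a half-length track of
the same gait gets the same speed.

**Proximity network.** At each sampled frame, two workers are linked when
their Euclidean distance is at most `d = 6` mm (about one body length; the
comparison is inclusive, which is immaterial for continuous positions but
fixed for reproducibility). `E` is the arithmetic mean of the per-frame
edge counts, and the mean degree is `⟨k⟩ = 2E/N` with `N` the colony's
tracked count — workers missing from a frame contribute no edges but stay
in the denominator, since `⟨k⟩` is a colony-level quantity. The
time-aggregated network (pair weight = frames in proximity) is exported as
a weighted edge list.

**Spanned area.** The enclosure is divided into a 24×24 grid; a cell is
visited if any sample of any worker (active or not) falls in it, and the
area is the visited count times the cell area. Two cell-length conventions
are provided: the default tiles the enclosure exactly (248/24 ≈ 10.33 mm),
while an override forces a fixed length such as 10.6 mm, whose square
matches the interaction disc area `π d²`. The two conventions cannot
coincide — 24 × 10.6 mm = 254.4 mm overruns a 248 mm enclosure — so the
package exposes both rather than asserting either; with the override, the
grid's outermost cells extend past the far wall. Grid cells are anchored at
the origin, boundary points belong to the higher-index cell, and the far
enclosure edge belongs to the last cell, so no sample is ever unbinned.

## Fitting conventions

Scaling laws (`E ∝ N^βE`, `Area ∝ N^βArea`, `B ∝ M^βB`) are fitted by OLS
on natural-log-transformed variables, with `R²` computed on the log
residuals; linear relations (`L` vs `N`, the balance statistic vs `N`) are
fitted on raw variables with `R²` on raw residuals. Confidence intervals
and two-sided p-values use the t distribution with the residual degrees of
freedom (`n − 2` with an intercept; 14 for a 16-colony design). Exponent
CIs are symmetric in log space and are not back-transformed. Zero
responses cannot enter a log fit and are dropped with a warning rather
than silently offset. Prediction quality against a model (as opposed to a
regression) is reported as `1 − SS_res/SS_tot`, on raw or log scale as
appropriate to the comparison, and may be negative.

## The reverse-contagion balance

Reverse social contagion is deactivation through contact: when two active
workers meet, one tends to stop. Under complete mixing each worker meets
`⟨k⟩` others per unit observation, each active with probability `A/N`, so
active–active encounters scale as `⟨k⟩A²/N`. Balancing them against
spontaneous activation at a size-proportional rate gives

\[ \langle k \rangle A^2 / N = q N, \]

and substituting the fitted interaction scaling `⟨k⟩ = 2E_0N^{\beta_E-1}`
yields the activity law

\[ A(N) = \sqrt{q/(2E_0)}\, N^{(3-\beta_E)/2}. \]

Hypermetric interaction scaling (`βE > 1`) therefore forces hypometric
activity scaling, regardless of the numerical values of `q` and `E0`;
`contagion_params()` warns when `βE ≤ 1`. The rate `q` is estimated as the
slope of the balance statistic against `N`. The default regression keeps
an intercept — its p-value is the natural diagnostic of the balance's
through-the-origin form — with a `zero_intercept` option for the
model-faithful alternative. Predictions are at tracked scale; rescaling by
`N*/N` happens only where metabolic inputs are needed.

A mean-field corollary: if workers mixed uniformly over the spanned area,
`E = N² a / (2\,\mathrm{Area})`, so the fitted prefactors imply an
effective per-worker interaction area `a = 2\,\mathrm{Area}_0 E_0`.
`effective_interaction_area()` reports it next to the two limiting
geometries, `π d²` (a stationary worker's disc) and `2 d L` (the ribbon
swept by steady motion).

## The Cobb–Douglas metabolic model

Colony metabolic rate is modelled as a degree-one homogeneous production
function of the scaled active and inactive counts,

\[ B = B_0 (A^*)^{\alpha_B} (I^*)^{1-\alpha_B}, \qquad
   A^* = A\,N^*/N,\quad I^* = N^* - A^*, \]

treating active workers as the colony's labour input and inactive workers
as its capital. The starred variables let untracked workers contribute in
proportion to the tracked activity fraction. Because `A*` and `I*` are
collinear across colonies, the fit is the univariate regression
`ln(B/I*) = ln B0 + αB ln(A*/I*)`. Marginal products follow by
differentiation (`αB B/A*` and `(1−αB) B/I*`) and satisfy Euler's identity
`A* MP(A*) + I* MP(I*) = B` exactly, which the tests verify numerically.

Composing the two models gives a parametric prediction of metabolic rate
from colony size alone (`predict_metabolic_rate()`), and, with mass
proportional to worker count, the derived scaling exponent

\[ B \propto M^{(1-\beta_E)\alpha_B/2 + 1}. \]

At `βE = 1.47` and `αB = 0.85` this is 0.80, a Kleiber-like hypometric
exponent; at `βE = 1` it degenerates to isometry. The composition is only
defined while the predicted active fraction is below one; for smaller
colonies the function raises a domain error instead of clipping, because a
clipped value would be a fabricated prediction outside the model's
validity.

## The synthetic-data generator

Real tracked videos are not shipped with the package, so the generator
produces colonies with the statistical structure the analysis assumes, in
two deliberately different modes.

**Summary mode** draws the derived quantities directly: `N*` log-uniform
on [40, 400] across 16 colonies, 85% tracked; `E` and `Area` from their
power laws with multiplicative lognormal noise (default σ = 0.2, a
residual scatter consistent with a log-space `R²` near 0.9 at these
ranges); `A` solving the balance with the colony's *own* noisy `E` (so the
balance relation stays internally consistent rather than holding only in
expectation); `B` from the Cobb–Douglas function of the scaled counts with
the same noise; mass proportional to `N*` (9 mg per worker, a plausible
wet mass per capita for a small harvester-ant colony with brood, σ = 0.1);
and `L` drawn size-independently (lognormal about 77 mm, the value
consistent with the steady-motion interaction ribbon). Summary mode is the
sharp instrument: exponent-recovery tests run here, because the generating
values are imposed exactly.

**Trajectory mode** emits positions. Each colony receives a handful of
attractor sites (default 6) with heavy-tailed occupation weights —
emulating aggregation around a brood pile, food and water — and workers
are assigned to sites. Inactive workers jitter in place (0.01 mm per-axis
noise, total apparent path well under the 3 mm threshold); active workers
walk between sites at a size-independent mean speed calibrated to a ~77 mm
path. Spatial scaling here is *emergent*: more workers pile into the same
few clusters, so interactions grow superlinearly and area sublinearly, but
no target exponent is imposed and none is guaranteed. Trajectory mode
therefore backs integration and qualitative (hypermetric/hypometric)
tests, never sharp recovery tests. Features of real colonies it does not
emulate include pheromone-mediated trail formation, activity bouts and
refractory periods within the 30 s window (activity labels are static, as
a 30 s average cannot resolve them), body orientation, and antennal
contacts as distinct from proximity.

Reproducibility: one root seed, with a deterministic per-colony child
stream derived from it, so adding colonies never perturbs earlier ones and
identical configurations are byte-identical.

```{r example}
gs <- generate_summaries(generator_config(seed = 7))
fit_power_law(gs$summaries, n_tracked, E)
estimate_q(gs$summaries)
```

## Numerical choices and degenerate inputs

- Natural logs throughout; the base only shifts the intercept and is
  normalised out when the prefactor is recovered.
- Strict `>` for the activity threshold; inclusive `≤ d` for proximity.
- Duplicate time stamps within a worker are an error (they are
  indistinguishable from non-monotone tracking); row order is otherwise
  immaterial after canonical sorting.
- Out-of-bounds positions: strict mode rejects, lenient mode clips to the
  enclosure with a warning. Default strict, because silent clipping can
  hide unit mistakes (pixels vs mm).
- The generated active count is rounded to an integer and capped at `N`;
  for a deliberately all-inactive colony the Cobb–Douglas input is floored
  at half a worker so the generated metabolic rate stays positive.
- Degenerate regressors (constant `N`, `A*/I*` constant across colonies,
  zero-variance x) raise errors rather than returning unstable fits.

## Problem sizes and limitations

The test suite simulates 16-colony designs for summary-mode recovery (50
replicates in the calibration checks) and smaller trajectory-mode designs
(4–8 colonies, 40–250 workers) for end-to-end and emergence checks; these
sizes keep the full suite fast while leaving the statistical conclusions
unchanged at larger sizes.

Known limitations. With 16 colonies, the sampling variance of the
univariate Cobb–Douglas slope is substantial (standard error ≈ 0.11 at
σ = 0.2), so single-replicate estimates of `αB` scatter more widely than
the scaling exponents do; recovery statements for it are correspondingly
weaker than for `βE` or `βArea`. Trajectory mode's emergent exponents
depend on the cluster geometry and are checked only qualitatively. The
balance model assumes complete mixing and static rates; species with
rhythmic synchronised activity would need time-varying parameters, which
the package does not model. Passing tests on generator output demonstrate
correctness of the pipeline and self-consistency of the models, not that
any particular real colony obeys them.
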