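---
title: "Multi-attribute value appraisal with MACBETH elicitation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-attribute value appraisal with MACBETH elicitation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavtkit)
```

## The model

`mavtkit` evaluates a set of options against an explicit set of weighted
criteria using an additive multi-attribute value function

$$V(a) = \sum_{i=1}^{m} w_i \, v_i(a),$$

where $v_i(a)$ is option $a$'s *partial preference value* on attribute
$i$ and $w_i$ are non-negative weights normalized to sum to one.  The
additive form assumes preferential independence between attributes:
trade-offs between any two criteria must not depend on the levels of the
others.  Where that fails, attributes have to be merged or a
non-additive aggregation used — neither is in scope here.

Each attribute carries two **reference levels**: a *lower* reference
$x_l$ (partial value 0) and a *higher* reference $x_h$ (partial value
100).  These are deliberate benchmarks — typically "satisfactory
performance" (proxied by best supportive care in the packaged oncology
case) and "best plausible performance" — rather than the endpoints of
the observed range.  Because the value scale is an interval scale,
anchoring at interior benchmarks is an admissible linear transform, and
options performing worse than the lower reference legitimately score
*below zero*.  That is not an edge case: in the packaged appraisal one
treatment's Grade 4 adverse-event rate (21% of patients against a 10%
lower reference) scores −117.9, which single-handedly explains its last
place.

## Value functions

Partial value functions are piecewise linear through elicited anchor
points `(performance, score)`, with plain level→score lookups for
ordinal and binary attributes.  Three rules are enforced at
construction:

* the anchors must include $(x_l, 0)$ and $(x_h, 100)$ exactly;
* anchors must be weakly monotone in the stated preference direction
  (strict monotonicity is typical; flat segments are allowed because
  elicited data can be flat);
* the anchors must cover the declared attribute range, and evaluation
  outside the covered range is an **error**, never a linear extension.

The no-extrapolation rule is a substantive choice, not a convenience:
in the packaged case study the elicited score at 21% Grade 4 AEs is
−117.9, while linear extension of the adjacent segment would give −110.
Elicited value beyond the anchors is simply unknown.

## MACBETH elicitation

Where cardinal scores are not given directly, they are elicited from
qualitative pairwise judgments: for each pair of stimuli the assessor
states the *difference of attractiveness* on the seven-category scale
*no / very weak / weak / moderate / strong / very strong / extreme*
(coded 0–6).  A judgment matrix is converted into a cardinal scale by a
linear program:

* variables $v(x)$, bottom stimulus fixed at 0;
* each pair judged in category $k \ge 1$ satisfies
  $v(a) - v(b) \ge k\,\delta$ with $\delta = 1$;
* pairs judged "no difference" are constrained equal;
* for any two pairs with categories $k_1 > k_2 \ge 1$, the first pair's
  difference exceeds the second's by at least $(k_1 - k_2)\,\delta$;
* objective: minimize the top stimulus' score.

Any positive $\delta$ gives the same scale after anchoring (anchoring is
invariant to positive affine transforms), so $\delta = 1$ is purely a
unit choice.  The published variants of MACBETH software do not document
their exact objective; ours returns the *tightest* (minimal-top) scale,
so unanchored intermediate scores may differ from other implementations
while anchored endpoints cannot.

Consistency is checked at two levels.  The *ordinal* check requires that
a pair nested inside another (spanning fewer ranks) never carries a
strictly larger category.  The *cardinal* check is feasibility of the LP
itself.  Violations are reported cell by cell rather than thrown, and
`feasible_bounds()` reports the interval of scores one stimulus could
take with the others held fixed — the information a facilitator uses
when inviting a group to adjust a suggested score.

### Numerical solution

The LP's integer right-hand sides make its vertices massively
degenerate (many redundant active constraints), which textbook simplex
implementations handle poorly.  The solver used here is the dual
active-set quadratic programming method (the `quadprog` package),
minimizing $\lambda\, c^\top v + \tfrac12 \lVert v \rVert^2$ with
$\lambda = 10^5$, far above any attainable score, so the solution lies
on the LP-optimal face and the norm term deterministically selects its
minimum-norm point.  Inequality rows are deduplicated and their
right-hand sides loosened lexicographically by $10^{-9}$ per row to
break exact ties in the active-set selection; the worst resulting
constraint violation observed over thousands of random systems is
about $2\times10^{-7}$, well inside every tolerance used in the tests.
Linearly dependent equality rows (an all-ties matrix has more equality
rows than variables) are reduced to an independent subset and the
dropped rows verified against the solution afterwards.

## Swing weighting

Weights are elicited by comparing the *swings* $x_l \to x_h$ across
attributes, with a fictitious *null swing* (no improvement) required as
the bottom stimulus of the judgment matrix — the zero anchor without
which swing scores are not ratio-comparable.  The derived swing scores,
normalized to sum to one, are the weights.  Cluster weights carry no
information of their own; they are sums of member-attribute weights.

The packaged appraisal bypasses elicitation and stores the baseline
weights directly, at two precisions: the one-decimal set
(OS 28.9, Grade 4 AEs 23.3, HRQoL 12.8, Medical costs 11.6, Posology
7.0, ATC L4 5.8, PFS 4.8, Marketing authorisation 3.5, Phase 3 2.3),
with HRQoL as the residual closing the sum to exactly 100, and the
published integer set (29/23/13/12/7/6/5/3/2).  The one-decimal set is
the default because it reproduces the published overall scores to
±0.15; the integer set is selectable (`weight_set = "printed"`) and is
the one under which the therapeutic/safety/socioeconomic cluster sums
are exactly 47/23/12.  The two largest weights alone total 52.2 of 100
— more than all other criteria together.

## Sensitivity analysis

One-way weight sensitivity asks: at what weight $w^*$ for attribute $i$
do two options' overall values equalize, when all other weights are
rescaled proportionally to keep the vector normalized?  Writing
$a = v_A(i)$, $b = v_B(i)$, $w_0 = w_i$ and rest-values
$R_X = (V_X - w_0 x)/(1 - w_0)$, each option's value is linear in the
varying weight, $V_X(w) = w\,x + (1 - w) R_X$, giving the closed form

$$w^* = \frac{R_B - R_A}{(a - b) - (R_A - R_B)}$$

reported when $w^* \in [0, 1]$.  Two degenerate situations return "no
reversal": equal partial scores (the only root is $w = 1$, where every
other weight vanishes) and parallel value lines.  Every reported
threshold is verifiable by substitution — the implementation is tested
against an independent bisection oracle to $10^{-6}$.

The *robustness margin* is the smallest relative change
$|w^* - w_0| / w_0$ over all attributes and adjacent-rank pairs.  For
the packaged appraisal it is 0.57 (the ATC L4 weight falling from 5.8
to ~2.5), so no single weight change of 50% or less alters any rank;
the most sensitive *increases* are Posology (+69%) and Medical costs
impact (+81%) on the closest-ranked comparison.

A second robustness check perturbs scores rather than weights.  The
semantics are this package's own definition (the corresponding
published software function is undocumented): for each attribute
independently, every option's score on that attribute may shift by up
to $\delta$ value points in either direction, worst case against the
current ranking; an adjacent pair (A above B) can swap exactly when
$V_A - V_B < 2\delta w_i$.  A simultaneous all-attribute adversarial
shift is deliberately *not* used — it is strictly stronger, and already
at $\delta = 5$ it would overturn any ranking whose closest gap is
below $10 \sum_i w_i = 10$ points, making it uninformative for
appraisals of this shape.  The packaged ranking is stable at
$\delta = 5$ under the per-attribute semantics.

## Value for money

Purchasing and administration costs stay *outside* the value model —
only attributes of benefit act as criteria; the broader resource
footprint enters through the Medical-costs-impact attribute, which
excludes the drug's own purchase price.  Each option's efficiency is
its total cost divided by its overall value (GBP per value point), and
dominance on the (value, cost) plane is classified pairwise: A
dominates B when it has at least as much value for no more cost, with
one strict.  The incremental cost-value ratio
$(c_A - c_B)/(V_A - V_B)$ is reported only for genuine trade-offs.

Two reporting conventions matter for reproducing the published
figures.  First, the cost profiles carry both exact components
(12,824 + 5,191; 23,643 + 3,374; 17,750 + 11,630 GBP) and the rounded
totals (18,000; 27,000; 29,400) used in the published ratios; ratios
use the rounded totals.  Second, overall values are reported at one
decimal throughout the output tables (full precision is kept
internally), and the efficiency report divides by the reported
one-decimal value — mirroring the published table, where the ratio row
sits directly beneath the one-decimal value row.  For the two
higher-value options the choice is immaterial (394 and 638 GBP per
value point either way); for the lowest-value option it moves the
ratio from 2057 to 2056 against a published 2046, the residual being
one-decimal rounding of the published inputs that both conventions
inherit.

## The packaged case study

The fixture encodes a real appraisal exercise: three second-line
biological treatments for metastatic colorectal cancer (cetuximab,
panitumumab, aflibercept + FOLFIRI) on nine attributes in four value
clusters (therapeutic impact, safety profile, innovation level,
socioeconomic impact).  Two reconstruction choices deserve emphasis:

* **Value-function anchors are reconstructed, not elicited.**  The
  elicited functions were published only for two example attributes, so
  each attribute's function is encoded by taking every option's
  observed (performance, published partial score) pair as an anchor,
  plus the two reference anchors.  Scoring the fixture therefore
  reproduces the published partial-score table *exactly*, by
  construction — a regression harness, not an independent elicitation.
* **Two published survival scores disagree slightly with linearity.**
  The overall-survival function was reported as linear, and the
  published score at 13.5 months (83.9) is exactly linear between the
  references; but the published 44.4/48.9 at 10/10.4 months differ from
  linear interpolation (43.7/48.3), most plausibly because the
  performances were rounded for publication.  The fixture stores the
  published scores and flags the discrepancy rather than guessing
  unrounded performances.

The pre-workshop model (18 attributes, original reference-level
definitions) ships as a second, never-evaluated fixture documenting how
the appraisal workshop halved the tree and swapped the clinical
lower references from "worst plausible" to "satisfactory (BSC-based)"
performance.

## The synthetic generator

`generate_problem()` produces decision problems with the structure the
pipeline assumes: per attribute a random range, a strictly monotone
piecewise-linear latent value function with 3–6 knots, a lower
reference placed strictly inside the range (so worse-than-satisfactory
performances score below zero, as in the appraisal), a higher reference
at the preferred range end, Gamma-drawn positive weights normalized to
one, and performances uniform within ranges.  About 30% of attributes
are decreasing-preference, echoing the mix of benefit and harm
criteria.  `generate_judgments()` bins latent value differences into
the six positive categories by equal-width binning over (0, max
difference] — any strictly monotone binning supports recovery, and
equal-width is the assumption-free choice.

What passing tests on these problems do show: scoring, aggregation,
decomposition and the sensitivity closed form are exact on problems
with known truth; judgment matrices generated without corruption are
always consistent; scale derivation recovers the latent *ordering*
exactly.  What they cannot show: anything about real elicitation
behaviour — group dynamics, anchoring biases, disagreement resolution —
and only limited cardinal fidelity: categories carry latent differences
at bin resolution only, and the minimal-top objective returns the
tightest compatible scale, so anchored derived scores agree with the
anchored latent scale only to about 1.5 bin widths (~25 points on the
0–100 scale) in the worst case, with exact agreement impossible to
guarantee from six categories.

## Numerical choices and degenerate inputs

* Judgment unit $\delta = 1$; solver bias $\lambda = 10^5$;
  lexicographic inequality loosening $10^{-9}$ per row.
* Exact ties in overall values are grouped at $|\Delta V| < 10^{-6}$
  and broken lexicographically by option id, so output is
  deterministic.
* Equal-scoring attributes and parallel value lines return "no
  reversal" rather than boundary roots; a weight of 1 on one attribute
  makes proportional renormalization undefined and is an error.
* Cost-per-value is undefined (error) for options with non-positive
  overall value.
* All-zero weight vectors, degenerate reference intervals
  ($x_l = x_h$), non-monotone anchors, and performances outside the
  anchor coverage are rejected with typed errors.
* Problem sizes in the test-suite property sweeps — 500 judgment
  matrices of 3–6 stimuli, 100 random 3×4 problems for the sensitivity
  oracle, 20 problems for decomposition — are the sizes typical of
  facilitated appraisals (a handful of options, about ten criteria),
  where these checks are exhaustive in minutes on a laptop.

## Limitations

* One cluster layer only; no deeper weight hierarchies.
* No probabilistic sensitivity (SMAA-style acceptability), no fuzzy or
  interval judgments ("weak-to-moderate"), and no group-disagreement
  modelling — one matrix speaks with one voice.
* The additive model stands or falls with preferential independence;
  the package checks structure, not preference axioms.
* Reconstructed value functions make the packaged case study a
  faithful *reproduction*, not a re-elicitation; conclusions about the
  underlying appraisal inherit the one-decimal precision of its
  published inputs.
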