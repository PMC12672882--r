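---
title: "Assessing age-friendly community parks: BWM weights, aspiration-gap VIKOR, and method concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing age-friendly community parks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agepark)
```

## The problem

Community parks are protective environments for older adults' mental
health, but renovation budgets are finite: planners need to know *which*
environmental attributes matter most for alleviating late-life depression
and *which* parks fall furthest short on the attributes that matter. This
package implements a two-stage expert-judgment pipeline for exactly that
question, built around eight physical-environment criteria (access points,
pathways, facilities for different activities, open space, amenities,
natural features, sunlight, incivilities):

1. **Weighting** — each expert fills in a Best-Worst Method (BWM)
   questionnaire; weights are solved per expert by linear programming,
   inconsistent experts are dropped, and the retained panel is averaged.
2. **Ranking and diagnosis** — expert performance ratings of each park are
   converted to aspiration-level gap scores and synthesized by a Modified
   VIKOR compromise index; per-criterion weighted gaps double as
   improvement priorities. Four comparator aggregations (classical VIKOR,
   SAW, TOPSIS, PROMETHEE II) and a Spearman concordance matrix situate
   the compromise ranking among the standard alternatives.

## The weighting model

A BWM questionnaire asks an expert to name the most important (best, $B$)
and least important (worst, $W$) criterion, then to rate, on a 1–9
integer scale, the best criterion against every criterion
($a_{Bj}$, Best-to-Others) and every criterion against the worst
($a_{jW}$, Others-to-Worst). A perfectly coherent expert would satisfy
$a_{Bj} = w_B / w_j$ for some weight vector $w$; real experts do not, so
the weights are taken as the solution of the linearized min–max programme

$$\min \xi \quad \text{s.t.} \quad |w_B - a_{Bj} w_j| \le \xi,\;\;
|w_j - a_{jW} w_W| \le \xi \;\;\forall j,\qquad \sum_j w_j = 1,\; w_j \ge 0.$$

The optimal objective $\xi^L$ is the expert's *consistency value*: zero
for coherent ratios, growing with internal contradiction. `solve_bwm()`
solves this exactly with the simplex method (`boot::simplex`); the
programme is feasible for every valid questionnaire, and for three
criteria the package's test suite checks the optimum against an
independent dense grid search over the weight simplex.

Two modelling points deserve note:

* **Degeneracy.** The linearized programme can have a face, not a point,
  of optimal weight vectors. `solve_bwm()` returns the solver's vertex
  and sets a `degenerate` flag when a probe solve (maximizing $w_B$ at
  the optimal $\xi$) finds a materially different optimum. Aggregation
  across a panel averages over experts, which stabilizes the final
  scheme under this choice.
* **Consistency filter.** Experts with $\xi^L$ above 0.1 are excluded;
  the boundary is inclusive ($\xi^L = 0.1$ is retained), since only
  values *above* the threshold indicate insufficient consistency. The
  retained experts' weight vectors are combined by unweighted arithmetic
  mean (`aggregate_weights()`; a geometric-mean switch exists but is not
  the default) and renormalized.

## The ranking model

Parks are rated 1–10 per criterion by each expert; `aggregate_ratings()`
averages raters per cell (logging per-cell dispersion, since the
combination rule across raters is a design choice, not a given). The key
modification relative to classical VIKOR is the reference frame: scores
are measured against the *theoretical* scale anchors — aspired level 10,
worst level 1 — rather than against the best and worst alternatives in
the sample:

$$r_{kj} = \frac{10 - f_{kj}}{10 - 1} \in [0, 1], \qquad
g_{kj} = w_j\, r_{kj},$$

so a park is never flattered merely because its competitors are poor.
Per alternative,

$$S_k = \sum_j g_{kj}, \qquad R_k = \max_j g_{kj}, \qquad
V_k = \delta S_k + (1 - \delta) R_k,$$

with $\delta = 0.5$ by default: equal emphasis on total weighted
shortfall (group utility) and on the single worst weighted gap
(individual regret). Lower $V$ is better; the aspiration point has
$S = R = V = 0$. The per-criterion $g_{kj}$, sorted per park, are the
improvement priorities.

**The regret convention.** Textbook VIKOR takes the regret maximum over
*weighted* gap terms; a literal reading of some presentations suggests the
raw $r_{kj}$ instead. The two disagree materially whenever the weights are
uneven. This package defaults to the weighted form, $R_k = \max_j g_{kj}$,
because it is the only convention that reproduces the bundled published
table: on the bundled nine-park evaluation, the weighted reading matches
all eight trusted synthesized gaps within propagated rounding, while the
unweighted reading misses all eight by an order of magnitude more
(`repro_report(run_config(regret = "unweighted"))` shows the failure).
The unweighted form remains available as an explicit option.

**Comparators.** `classical_vikor()` normalizes $S$ and $R$ against the
sample extremes ($Q_k \in [0,1]$, degenerate terms defined as 0). `saw()`
is the additive utility $1 - S_k$ — an exact complement, which the test
suite asserts as an identity. `topsis()` uses min–max normalization on
the assessment scale by default (consistent with the aspired/worst
anchors; vector normalization is an option) with per-criterion sample
extremes as ideals. `promethee2()` uses the usual (step) preference
function and unnormalized net flows in $[-(m-1), m-1]$, with a linear
preference function available behind a threshold parameter. The published
comparison table's TOPSIS and PROMETHEE performance values are *not*
reproduction targets — the original normalization and preference settings
are not recoverable — so only their structural properties (dominance,
zero-sum) and rank behaviour are asserted.

**Rank convention.** All rank columns assign rank 1 to the smallest
performance value, matching the published tables; each `rank_vector`
carries an orientation flag saying whether rank 1 is best (gap-oriented
methods) or worst (utility-oriented methods). Ties get average ranks.

## Concordance

Gap-oriented and utility-oriented rankings are antitonic, so
`correlation_matrix()` first maps every rank vector to a common
orientation ($r \mapsto m + 1 - r$), then computes Spearman correlations
(`stats::cor`; the closed form $1 - 6\sum d^2 / (m(m^2-1))$ is the
independent check in the tests). Alignment rather than absolute value is
the default because it preserves genuine disagreement as a negative sign;
`align = FALSE` exposes the raw signed matrix. The per-method average
correlation is the plain column mean *including* the unit diagonal — the
convention under which the bundled average row reproduces. Exact
permutation p-values are available through `p_values = TRUE`
(`stats::cor.test`, exact null for small tie-free vectors).

## The synthetic-study generator

`synthetic_study()` plants ground truth — a weight vector on the simplex
with max/min ratio at most 9 (the representability limit of the 1–9
scale) and an alternatives × criteria quality matrix on $[1, 10]$ — and
generates what an expert panel would report about it:

* questionnaires: best/worst from the planted weights (lowest index wins
  ties), comparison entries
  $\mathrm{clamp}(\mathrm{round}(\exp(\log(w_B/w_j) + \varepsilon)), 1, 9)$
  with $\varepsilon \sim N(0, \texttt{bwm\_noise})$, then the
  best-versus-worst entry forced consistent across the two vectors;
* ratings: planted quality plus $N(0, \texttt{rating\_noise})$, clamped
  to $[1, 10]$.

Defaults mirror the empirical panel the package was built around: 23
experts, 9 parks, 8 criteria, with the bundled final weight scheme as the
planted weights. The noise defaults (`bwm_noise = 0.15` on the log-ratio
scale, `rating_noise = 1.0` scale points) are one-time choices of a
plausibly noisy but informative panel: 0.15 keeps most rounded ratios
within one integer step of truth, and ±1 point is a realistic rater
disagreement on a 10-point scale. They are illustrative, not calibrated —
in particular, no attempt is made to tune the noise so that the retention
rate matches any particular panel's 13-of-23 outcome, which a single
scalar noise level underdetermines.

Log-normal multiplicative noise on ratios and additive Gaussian noise on
scores are minimal models that respect the scale constraints via
clamping; they do **not** emulate systematic expert biases (halo effects,
criterion confusion, correlated errors across experts), so passing
recovery tests demonstrates correctness of the pipeline arithmetic, not
robustness to structured disagreement in real panels.

Each expert draws from a sub-stream at a fixed offset from the study
seed, so enlarging the panel never perturbs earlier experts' data.

What the generator guarantees, and the suite verifies end to end: with
zero noise and integer-representable planted ratios the pipeline returns
the planted weights exactly and the planted ranking identically; with
noise, mean weight-recovery error grows monotonically in `bwm_noise`
(checked at three levels × 200 replicates on a small 4-criterion,
3-expert study — sizes chosen to make the replicated check quick while
leaving the monotone signal clearly visible).

## Numerical choices and degenerate inputs

* The LP is solved in exact simplex arithmetic on $n + 1$ variables and
  $4n + 1$ constraints; weights are clamped at zero on output and sum to
  1 within $10^{-9}$.
* Fixture weight schemes transcribed from rounded percentages must
  pre-sum to within $[0.99, 1.01]$ and are renormalized exactly.
* Printed-table comparisons use propagated-rounding tolerances: a value
  recomputed from $k$ cells rounded to 3 decimals is compared within
  $k \times 0.0005$ of its printed counterpart (e.g. 0.0025 for a
  synthesized gap at $\delta = 0.5$, 0.004 for a SAW complement); ranks
  are compared exactly. One bundled gap row is flagged corrupt — its
  per-criterion entries duplicate another case's verbatim while its
  synthesized gap differs — and is excluded from gap-based reproduction
  while its printed ranks remain in rank-based checks.
* A criterion constant across all alternatives contributes zero to both
  TOPSIS distances (no NaN); all-equal $S$ or $R$ makes the corresponding
  classical-VIKOR term zero; ties anywhere receive average ranks.

## A worked example

```{r example}
cfg <- synthetic_study(n_experts = 10, seed = 42)
qs <- generate_questionnaires(cfg)
ratings <- generate_ratings(cfg)
ev <- evaluate_study(qs, ratings)
ev
```

The reproduction report recomputes the bundled published evaluation from
its own printed inputs:

```{r repro}
repro_report()
```

## Limitations

* The package evaluates; it does not elicit. Questionnaire quality
  control beyond the consistency value (e.g. attention checks,
  test–retest) is out of scope.
* Only the linearized BWM is implemented — no Bayesian, interval or fuzzy
  variants — and no sensitivity analysis over $\delta$ beyond exposing
  the parameter.
* Spearman is the only concordance statistic; Kendall's $\tau$ and
  weighted rank correlations are deliberate non-goals.
* Per-expert weight vectors underlying a published aggregate scheme are
  generally not recoverable from the aggregate; the bundled weight table
  is a fixture for downstream stages, not a reproduction target.
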