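---
title: "Prescribing games, information coarsening, and when stewardship is self-enforcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescribing games, information coarsening, and when stewardship is self-enforcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarsegame)
```

## The model

Two physicians repeatedly receive patients who may have a bacterial
infection. Before culture results are available, each physician observes a
private signal about their own patient: the posterior probability `p` of a
bacterial infection, distributed across patients with density `f(p)` on
`[0, 1]`. The prior probability of bacterial infection is the mean of this
distribution, `P(B) = E(p)`.

Antibiotic effectiveness is a depletable common resource. The state of the
game is the *effectiveness state* `k` (doses left); current effectiveness is
`e = k·α`, and every administered dose lowers next period's state by one
(two simultaneous prescriptions lower it by two). The game ends at `k ≤ 0`.

Payoffs are net expected utilities of treatment relative to withholding.
With outcome utilities `r1 < r2 < r3` (untreated bacterial < treated
bacterial < non-bacterial) and no direct treatment risk (`c = 0`, the
assumption of the dynamic analysis), treating a patient with signal `p` at
state `k` yields `p · k · α · (r2 − r1) = p·k·U`; withholding yields 0. The
static module additionally supports `c > 0`, under which the classical
treatment-threshold probability becomes
`T = c(r3−r1) / (e(r2−r1) + c(r3−r1))`; at `c = 0` the threshold is 0 and
the *myopic* policy — optimizing each patient in isolation — treats
everyone.

Strategies are stationary Markov threshold rules `d^k`: treat iff
`p ≥ d^k`. The cumulative value of a symmetric profile satisfies, with
`F = F(d^k)` and `PE(a) = ∫_a^1 p f(p) dp`,

$$
v^k \;=\; \frac{kU\,PE(d^k) + 2F(1-F)\,v^{k-1} + (1-F)^2\,v^{k-2}}{1-F^2},
\qquad v^k = 0 \;(k \le 0),
$$

the denominator accounting for the stage repeating while both physicians
withhold. Deviation payoffs replace the treat probabilities by the
asymmetric products; `deviation_value()` implements the solved (explicit)
form — never fixed-point iteration, since the self-referential form divides
out exactly.

## Planner and equilibrium

`solve_social_optimum()` computes the symmetric policy maximizing each
physician's (equivalently, the total) expected payoff by backward dynamic
programming. The stage objective may attain its supremum only in the limit
of vanishing treatment; the boundary rule (`d = 1` when the support reaches
1) is included with its continuity value `kU/2 + v^{k-1}`. As `k` grows the
optimal threshold approaches 1: with ample effectiveness it is worth
waiting for patients whose infection is near certain.

`solve_mpe()` constructs a symmetric pure-strategy Markov perfect
equilibrium state by state. At each `k` it first checks whether treating
everyone survives all upward one-stage deviations (it always does at
`k = 1`); otherwise it locates, by bisection, the threshold at which the
*marginal* one-stage deviation gain
`G(d) = ∂v^k(d̄, d)/∂d̄ |_{d̄=d}` changes sign. Strong unimodality of the
deviation payoff in `d̄` makes the marginal test sufficient and guarantees
the bisection target is the stage equilibrium. `verify_mpe()` certifies any
candidate strategy by exhaustive deviation grids per state.

Two robust qualitative facts, both reproduced by the test suite: the
equilibrium thresholds never exceed the planner's (equilibrium *overuse* of
antibiotics), and they stay bounded away from 1 while the planner's tend
to 1.

## Coarsening and stability

Replacing the continuous signal with a dichotomous one at threshold `T`
(`coarsen()`) leaves each stage only two rules: treat everyone, or treat
only high-signal patients. The induced posteriors are the truncated means
`p_H = PE(T)/(1−F(T))` and `p_L = (E(p) − PE(T))/F(T)`, with
`q_H p_H + q_L p_L = E(p)` (total expectation). The fixed policy "treat
only high-signal patients at every state" is an MPE of the coarsened game
**iff**

$$
p_H - p_L \;\ge\; E(p),
$$

a condition on the information system alone. `stability_gap()` returns the
slack `h(T) − E(p)` with `h = p_H − p_L`; `min_stable_threshold()` scans a
grid (step `1e-3`) and refines the infimum of the stable set by bisection;
`threshold_profile()` tabulates the full diagnostic curve. The per-state
stage conditions (both for treat-everyone and treat-high-only) are exposed
by `dichotomous_stage_equilibrium()`, and `coarse_mpe_agreement()`
cross-checks the distribution-level criterion against them — the binding
state is `k = 1`, where the continuation difference vanishes.

Typical scenarios: a bimodal Beta(1/2, 1/2) signal (clinical pictures that
either strongly indicate or strongly rule out bacterial infection) is
stable at *every* positive threshold; the uniform signal sits exactly at
the boundary (`h(T) = 1/2 = E(p)` for all `T`), so every threshold is
(weakly) stable; a concentrated Beta(20, 20) signal (every case ambiguous)
admits no stable threshold at all; a right-skewed Beta(1, 5) signal leaves
wide freedom in choosing `T`.

## Parameters and defaults

* `M` — number of effectiveness states. Unit tests use `M ≤ 50`;
  the asymptotic-trend checks use `M = 200`. Real drugs have very large
  `M`; the qualitative results stabilize long before 200.
* `alpha` — per-dose depletion; defaults to `1/M` so that the initial
  effectiveness is `e0 = M·α = 1`.
* `r1, r2, r3` — default `0, 1, 2` (only `r2 − r1` matters once `c = 0`;
  `r3` enters the static analysis). The net-benefit unit is
  `U = α(r2 − r1)`.
* Solver tolerances — planner refinement `1e-8`; MPE bisection `1e-10` on
  the threshold; certification default `1e-8` in payoff units; marginal
  gains use central differences with step `1e-6`. Deviation grids always
  include the endpoints 0 and `support_max − 1e-9`.
* Planner ties are broken toward the *larger* threshold (less treatment),
  which matters when the objective is flat — e.g. the one-dose uniform
  stage, where every rule yields `U/2`.

## Numerical design

All tail quantities are computed from survival functions rather than CDF
complements: `1 − pbeta(T, a, b)` loses all precision once
`pbeta ≈ 1` (for Beta(20, 20) this happens by `T ≈ 0.93`), which corrupts
the conditional mean `p_H` exactly where stability is decided. The beta
family uses `pbeta(..., lower.tail = FALSE)` and the incomplete-moment
identity `PE(a) = E(p)·pbeta(a, α+1, β, lower.tail = FALSE)`; the value
recursions are algebraically rearranged so that only `S = 1 − F` appears
(`1 − F(d̄)F(d) = S_d + S_s − S_d S_s`, `1 − F² = S(2 − S)`). Empirical
distributions tabulate density, CDF, survival and partial expectation on a
4001-point grid, with the survival and partial-expectation columns
accumulated from the right end for the same reason.

Degenerate inputs are rejected explicitly: coarsening requires
`0 < F(T) < 1`; both physicians withholding almost surely
(`F(d̄) = F(d) = 1`) has no well-defined value and raises an error;
strategy thresholds are confined to `[0, support_max]`, with `d = 1`
admitted only in the symmetric planner problem via its continuity limit.

## The synthetic cohort

The motivating clinical example is a cohort of 1202 children hospitalized
with RSV bronchiolitis, of whom 235 also had bacterial pneumonia, with a
classifier supplying each patient's posterior probability of bacterial
co-infection. Since those records cannot be redistributed and the
classifier is standard machinery, the package starts where the analysis
proper starts: at the posteriors. `generate_cohort()` draws true posteriors
from Beta(0.8, shape2) with `shape2` solved so the mean equals the
prevalence (0.8 gives a right-skewed density concentrated at low
probabilities, qualitatively matching the clinical picture; the choice is a
stated convention of this package). Labels are drawn `Bernoulli(p)` *from*
the posteriors, so calibration holds by construction — which is exactly
what "`p` is a posterior" means, and lets decile-calibration checks verify
the generator rather than assume it.

`estimate_signal_density()` smooths the posteriors with a Gaussian kernel
on the logit scale (avoiding boundary bias), Silverman bandwidth by
default, then adds a floor constant (`1e-4`) and renormalizes so the
support is all of `(0, 1)`. The smoothing method and bandwidth are this
package's conventions; no claim is made that any synthetic configuration
reproduces results obtained on the real records.

What passing the pipeline tests shows — and does not show. The recovery
test demonstrates that with `n = 1202`, smoothing noise moves the estimated
minimal stable threshold by only a few times `1e-4` when the truth is at
the bottom of the scale. It does not certify behavior for distributions
whose stability boundary falls in a low-density region, nor for real
posteriors exhibiting features the beta family lacks (point masses, strong
multimodality). One artifact deserves note: the floor constant extends the
support to 1, so whenever the sample mean is below 1/2 the stability gap
tends to `1 − 2E(p) > 0` as `T → 1`, creating a small stable set of extreme
thresholds that condition on the (vanishingly rare) floor tail alone. Such
thresholds are mathematically valid but practically vacuous — effectively
"never treat"; profiles should be read over the bulk of the data.

## Simulation oracle

`simulate_game()` plays the game forward exactly as specified: i.i.d.
signals each period, simultaneous threshold decisions, state decrements by
the number of treatments, termination at `k ≤ 0` (a period cap guards
non-depleting profiles, and capped runs are flagged, never silently
truncated). Payoffs default to the expected form `p·k·U`, matching the
model's payoff definition; the realized-outcome mode (Bernoulli infection
and effectiveness draws) is exploratory and agrees in expectation.
`mc_value_estimate()` restarts the simulation from every state and is the
package's independent check of the recursions — agreement within three
standard errors at `1e5` replicates is part of the acceptance suite.

## Known limitations

* Only symmetric pure-strategy equilibria are computed; the construction
  yields one MPE and does not enumerate others, nor mixed or asymmetric
  equilibria.
* Coarsening is dichotomous only; finer discretizations and
  welfare-optimal choice of `T` are out of scope.
* The two-physician recursion is implemented; the n-physician extension is
  not.
* Resistance dynamics are approximated by deterministic effectiveness
  depletion — no mechanistic epidemiology, no effectiveness recovery.
* Coarsening can also stabilize undesirable equilibria (e.g. treat-everyone
  can be a stage equilibrium alongside treat-high);
  `dichotomous_stage_equilibrium()` reports both conditions per state so
  the tension is visible.
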