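---
title: "Moiety-model deconvolution and robust model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moiety-model deconvolution and robust model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moietyfit)
```

## The model

A metabolite is decomposed into moieties — substructures that acquire
isotope label as units through their biosynthetic routes. Moiety `j` has
labeling states with isotope counts `c_{j,1} < c_{j,2} < …` and fractional
abundances that sum to 1, so a moiety with `s_j` states contributes
`s_j − 1` free parameters; sharing constraints (several states forced to
one common fraction) remove one parameter per extra member. The calculated
relative intensity at isotopologue index `x` is the sum over all
combinations of one state per moiety whose isotope contents add to `x` of
the product of the chosen fractions — equivalently, the convolution of the
per-moiety count distributions, which is how `calc_isotopologues()`
evaluates it (the test suite checks it against brute-force enumeration).

Fitting minimizes one of four objectives between observed and calculated
profiles: absolute difference (suits additive error), absolute difference
of logs (suits proportional error; both arguments floored at `epsilon`,
default `1e-12`, natural log), squared difference (the RSS itself), or an
AIC-shaped objective `2k + n·log(RSS/n)`. For several time points the
parameters are time-dependent — one vector per time point — and the
combined loss is the sum of per-profile losses. Model ranking uses AIC,
AICc and BIC computed from `(k, n, RSS)`, where `k` counts every time
point's parameter set and `n` counts every isotopologue entry
`0..capacity` per profile, zeros included, so `n` is identical across
candidates of equal capacity. Over repeated stochastic fits the RSS is
averaged first and the criterion computed once — stable under the log —
rather than averaging per-run criteria. Ties in ranking are broken
lexicographically by model name, with a warning.

### Assumptions

* Profiles are relative intensities (natural-abundance-corrected and
  normalized upstream; `renormalize()` only rescales to unit sum).
* Missing isotopologue indices are zeros up to the model capacity: MS
  reports observed peaks only, while the equations cover the full range.
* States of one moiety are exchangeable only through the data: the model
  carries no prior on which states are plausible.

## Numerical choices

**Dependent states.** Each moiety's first state is its dependent state,
set to one minus the sum of the others. During optimization a candidate
may propose fractions summing above 1; the dependent state is then clamped
at 0 and the moiety's fractions renormalized by their sum. This keeps the
objective defined on the whole unit box, so box-constrained optimizers
need no extra constraint machinery. Sharing constraints may not include a
dependent state — the parameter map would become two-valued.

**The optimizer.** The fitting engine is a hybrid of simulated annealing
and a genetic algorithm over `[0,1]^k`, reimplemented in C++ with a
private deterministic RNG (results are bit-identical for a given seed and
never touch R's RNG). The design departs from a plain
population/crossover/replace-worst scheme, which in our experiments
converged far too slowly on this problem to be useful: the intensity map
has sloppy directions (condition numbers in the hundreds) *and* discrete
near-degenerate modes in which states with equal or overlapping isotope
contributions exchange roles (e.g. a two-carbon acetyl state against a
two-carbon uracil state). The shipped kernel therefore combines:

* per-member annealing chains (Metropolis acceptance against the child's
  own parent) — preserves mode diversity far longer than replace-worst;
* block crossover — for multi-time-point fits one block is one time
  point's parameter set, so good per-time-point solutions are exchanged
  as units; crossover ramps in linearly over the run;
* jump mutations (a fresh uniform draw on one coordinate) alongside
  temperature-scaled perturbations, with geometric cooling restarted over
  `anneal_cycles` cycles;
* for objectives that are sums over profiles (all but the AIC-shaped
  one), per-block Metropolis acceptance with a per-block incumbent and a
  small diversity archive, followed by a refinement phase: the second
  half of the budget greedily polishes the incumbent *and its pairwise
  coordinate-swap variants* with a compass (pattern) search that includes
  compensating two-coordinate moves. Swapping two coordinates hops
  directly between exchange-degenerate modes, and polishing each mode to
  its true depth before comparing them is what makes zero-noise parameter
  recovery reliable.

The step budget semantics are preserved: `steps` counts candidate
evaluations after population initialization, the single knob the
over-optimization harness varies; the best-so-far loss trajectory is
non-increasing. A refinement phase that converges before exhausting its
share simply stops early. The generic `saga_optimize()` entry point (for
arbitrary R objectives) uses the joint kernel; `fit_model()` uses the
per-block kernel when the objective permits.

Defaults (`saga_config()`): population 20, final crossover rate 0.5,
start temperature 0.5 (half the box), cooling to `1e-3` of the start
temperature per cycle, 3 cycles. These are exposed but deliberately not
varied in the harness experiments, where `steps` is the only knob.

**Local optimizers.** The pluggable bounded-local contract ships
`l-bfgs-b` (via `stats::optim`, tolerance mapped to `factr`) and `nlminb`
(PORT); this environment provides no TNC or SLSQP implementation, and a
user-supplied method function can stand in for either. Failures are
flagged on the result (`converged = FALSE`), not raised, so repeated runs
proceed.

## The synthetic world

`simulate_dataset()` computes noise-free profiles from a ground-truth
parameter matrix, perturbs each intensity as
`I·(1 + cv·e1) + sd·e2` with standard normal `e1, e2`, clips negatives to
zero and renormalizes — mimicking the relative-intensity datasets that
are actually fitted. The default truth schedule
(`udp_glcnac_truth()`) is a biologically structured time course: glucose,
ribose and acetyl — directly fed by glycolysis, the pentose phosphate
pathway and pyruvate dehydrogenase — enrich quickly (0.30/0.25/0.20 at
the first time point rising to 0.75/0.70/0.60), while uracil, made by
multi-step de-novo pyrimidine synthesis, stays sparsely labeled
(u1/u2/u3 from 0.06/0.04/0.03 to 0.18/0.12/0.09).

The harness candidate set (`udp_glcnac_candidate_models()`) is the expert
model plus five add-state variants (g5, g4, r4, r3, a1), each with seven
free parameters. Hand-crafted competitor sets for this metabolite carry
at least as many parameters as the expert model, and that property is
load-bearing: the over-optimization mechanism under study is *extra
parameters absorbing measurement error*. We originally included
remove-state and share-state (five-parameter) candidates; those dominate
at small step budgets — under-optimization favors the smallest model
because all models misfit about equally — which inverts the phenomenon
and tells you about a different failure mode. The mixed-edit rules remain
available through `perturb_model()`.

Noise levels: selection-sanity experiments use additive sd 0.005 (about
the reproducibility of well-measured relative intensities); the
over-optimization and information-quantity experiments use 0.05, a
deliberately harsh regime in which fits chase error. At 0.05 in this
synthetic world, selection failures concentrate at *small* budgets
(stochastic under-optimization across only five competitors with
Gaussian noise) rather than at large budgets as on real data with
hundreds of competitor-parameter combinations and structured error; the
harness reports the failure pattern either way. This is a known limit of
the synthetic twin: a green information-quantity test establishes the
*direction* of the effect (uninformative time points lower the median
failure step), not the paper-scale magnitudes.

## What a green test establishes

* The intensity equations agree with brute-force enumeration to 1e-12
  and conserve total intensity.
* The criteria obey their exact algebra (`AICc − AIC`, `BIC − AIC`).
* Zero-noise fits at 50 000 steps recover every generating parameter
  within 0.02 (per-parameter median over 10 seeds) — the exchange modes
  are resolved, not merely averaged over.
* At additive sd 0.005 and 20 000 steps, AICc picks the generating model
  in ≥ 8/10 worlds; at sd 0.05 finite failure points appear and mean loss
  is non-increasing in the budget; adding two unlabeled time points
  lowers the median failure step (10 replicates, right-censored at the
  grid maximum).
* Replicate spread trends (Spearman correlation of pair mean vs.
  absolute pair difference, raw and log scale) recover the generating
  noise type in ≥ 95/100 simulations at cv 0.2 / sd 0.01.

What the generator does *not* emulate: correlated errors across
isotopologues from natural-abundance correction, ion suppression,
platform-specific intensity-dependent error models, and kinetic coupling
of parameters across time points (each time point's truth is free).

## Known limitations

* `aic_diff` fits use the joint kernel (the objective couples profiles
  through the log of total RSS) and converge more slowly than the
  separable objectives at equal budgets.
* With noiseless data the AIC-shaped objective is undefined at RSS = 0;
  candidates reaching it are rejected as non-finite rather than declared
  optimal.
* The failure-step censoring convention (report the grid maximum,
  flagged) biases medians toward the grid maximum when most replicates
  never fail; compare variants only on identical grids.
* Exchange-degenerate modes separated by less than the measurement error
  are genuinely unresolvable; the per-parameter median across seeds then
  reflects whichever mode the data slightly favors.
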