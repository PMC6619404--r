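---
title: "Energy-landscape analysis of binarized brain dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of binarized brain dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`energyscape` implements an energy-landscape analysis of multichannel binary
state dynamics, of the kind used to characterize resting-state fMRI activity
in a small set of regions of interest (ROIs). This vignette documents the
models, the conventions, and the design decisions behind the package, in the
order the pipeline applies them.

## The pairwise maximum-entropy model

The unit of analysis is a binarized activity matrix: `T` volumes by `N` ROIs,
entries in $\{+1,-1\}$. The instantaneous activity pattern
$V = [\sigma_1,\dots,\sigma_N]$ takes one of $2^N$ values. The pairwise
maximum-entropy model (the Ising model) assigns each pattern the energy

$$E(V) = -\sum_i h_i \sigma_i - \tfrac{1}{2}\sum_{i,j} J_{ij}\sigma_i\sigma_j$$

and probability $P(V) = e^{-E(V)} / \sum_l e^{-E(V_l)}$. It is the
maximum-entropy distribution that matches the empirical first moments
$\langle\sigma_i\rangle$ and second moments
$\langle\sigma_i\sigma_j\rangle$. The bias $h_i$ captures the tendency of
ROI $i$ to be active in isolation; the symmetric zero-diagonal coupling
$J_{ij}$ the pairwise interaction. Everything downstream — the landscape,
the barriers, the basins, the transition taxonomy — derives from the fitted
energies, so the package restricts itself to exact enumeration of all $2^N$
patterns and caps $N$ at 14. Within that cap no approximation is involved
anywhere: probabilities are computed in the log domain (stable to
$|h|, |J| \approx 50$) and normalize to 1 within $10^{-12}$.

### Fitting

`fit_mem()` iterates the moment-matching updates

$$h_i \leftarrow h_i + \alpha(\langle\sigma_i\rangle_{\text{data}} -
\langle\sigma_i\rangle_{\text{model}}), \qquad
J_{ij} \leftarrow J_{ij} + \alpha(\langle\sigma_i\sigma_j\rangle_{\text{data}}
- \langle\sigma_i\sigma_j\rangle_{\text{model}}),$$

with model moments computed by exact enumeration at every step. This is
gradient descent on the Kullback–Leibler divergence from the data to the
model, so the moment mismatch is exactly the quantity the update drives to
zero, and it is also the natural convergence criterion: iteration stops when
the largest absolute mismatch falls below `tolerance` (default $10^{-6}$),
with a cap of $10^5$ iterations and a `converged` flag either way. The
learning rate defaults to $\alpha = 0.1$, the method's standard value. `J`
is re-symmetrized and its diagonal zeroed after every update, preserving the
$\tfrac12 \sum_{ij}$ parameterization. Targets with any
$|\langle\sigma_i\rangle| = 1$ (an always-active or always-inactive channel)
are rejected: no finite parameter attains them.

### Accuracy of fit

`fit_accuracy()` reports $r_D = (D_1 - D_2)/D_1$, where $D_2$ is the
base-2 KL divergence of the empirical pattern distribution from the fitted
pairwise model and $D_1$ the divergence from the *independent* model — the
maximum-entropy fit restricted to $J = 0$. The independent model has the
closed form $h_i = \operatorname{atanh}\langle\sigma_i\rangle$, which the
package uses rather than a second iterative fit. $r_D = 1$ means the
pairwise model reproduces the empirical distribution perfectly; $r_D = 0$
means the interactions add nothing over the independent baseline. Empirical
cells with zero probability contribute zero to the sums (the model has full
support, so the reverse degenerate case cannot arise); $D_1 = 0$ makes the
ratio undefined and raises an error rather than returning a sentinel.

## Landscape objects

### Conventions

Patterns are indexed $k \in [0, 2^N)$ with ROI 1 in the most significant
bit and a set bit meaning active, so index 0 is the all-inactive pattern
(`s-`) and $2^N - 1$ the all-active pattern (`s+`). Two patterns are
adjacent when they differ in exactly one ROI; every pattern has exactly `N`
neighbours. These conventions are fixed so that indices, bit-strings and
exports are reproducible across runs.

### Local minima, barriers, basins

A *local minimum* is a pattern with strictly lower energy than all `N`
neighbours. Exact energy ties between adjacent patterns make that
definition degenerate; fitted real-valued energies make ties a measure-zero
event, so the package fails loudly on them instead of silently
tie-breaking. Duplicated energies between *non-adjacent* patterns are
harmless and accepted.

The *barrier* between two minima is the lowest energy threshold at which
they remain connected when all patterns above the threshold are deleted
from the adjacency graph — equivalently the minimax path cost, the energy
of the saddle. The classical construction sweeps a threshold downward
through the realized energy values, removing patterns and recording when
pairs of minima disconnect. `disconnectivity()` runs the identical
procedure in reverse: patterns are admitted in ascending energy order into
a union–find structure, and the energy of the pattern whose admission first
joins two minima-bearing components is recorded as their barrier. The two
sweeps visit the same thresholds and give the same barriers; the ascending
form is simply the efficient direction, and the tests verify it against an
exhaustive enumeration of all simple paths. The barrier matrix is
ultrametric, which is what makes the disconnectivity *tree* well defined;
its diagonal is set to each minimum's own energy as a convention. Leaves
are ordered by energy in exports and plots (layout is presentation only).

`basins()` assigns every pattern to the minimum reached by steepest
descent: repeatedly move to the lowest-energy neighbour. A tie in that
choice raises an error naming the pattern. Because descent strictly
decreases energy, the assignment is computed in one ascending-energy pass.

## Transition taxonomy and the efficiency score

Each volume is classified into `s+`, `s-` (exactly the synchronized
patterns), `b+`, `b-` (the basin of `s+` or `s-`, excluding the minimum
itself), or `b_other` (any remaining basin). The taxonomy requires `s+` and
`s-` to be local minima of the landscape in use and errors otherwise. Group
landscapes drive individual dynamics: basins come from the pooled group
fit, the trace from the individual.

Two different counting semantics are deliberate, mirroring the method's
own phrasing:

* **Direct transitions** between `s+` and `s-` use *completed-excursion*
  counting: an event is registered each time the trace, having left one
  synchronized pattern, arrives at the other before revisiting the first.
  This is implemented as a last-synchronized-state automaton.
* **Basin transitions** between `b+` and `b-` use *consecutive-volume*
  counting: an event is a direct volume-to-volume move between the two
  basins. An excursion-style variant is available behind the
  `semantics = "excursion"` flag for sensitivity analysis; the consecutive
  reading is the default.

The *peripheral* rate is the basin rate minus the direct rate — movement
between basins that does not complete a synchronized excursion. Because the
two semantics differ, the difference can come out negative on unusual
traces; it is then floored at zero with a warning. All rates divide by the
participant's full volume count, and no event of any kind is counted across
a pooling boundary: boundaries are first-class data exactly so that a
"transition" spanning two concatenated participants can never occur.

The *efficiency score* is the ratio of the direct rate to the peripheral
rate. When the peripheral rate is zero the score is undefined and reported
as missing (`NA`), never infinity; missing scores are dropped (with their
`n`) from downstream correlations.

`simulate_mh()` provides the validation dynamics: a Metropolis–Hastings
walk that proposes one of the `N` neighbours uniformly and accepts with
$\min[1, \exp(E_{\text{current}} - E_{\text{proposed}})]$, which satisfies
detailed balance with respect to the Boltzmann distribution. The default
start is `s+`. Chains are deterministic given `seed`. The package default
of $10^6$ steps is a desk-scale choice (the tests verify stationarity at
that length using batch-means standard errors); the step count is fully
configurable.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage can be exercised end to end
without external data. It emulates two groups of participants whose
binarized dynamics differ in the ease of transitions between `s+` and `s-`:

* A latent state alternates between all-high and all-low with a
  per-participant switch probability. The group effect scales its log
  (`base_switch_rate` $\times e^{\pm \text{effect}/2}$, default base 0.05
  per volume), and a log-normal participant factor (sd 0.4) creates the
  within-group individual differences that behavioral coupling acts on.
* Every channel observes the latent state plus a *shared* AR(1)
  fluctuation (sd 0.7, lag-one autocorrelation 0.4) plus its own AR(1)
  noise (sd 0.8, autocorrelation 0.3). The shared component occasionally
  carries the whole pattern near the basin boundary, which is what
  generates peripheral `b+`/`b-` wandering at a rate that does not depend
  on a participant's switching ease. Without it, binarized traces would
  jump between the synchronized patterns within a single volume and the
  peripheral rate would degenerate to zero — piloting showed exactly that,
  which is why the component is part of the generator's definition.
* Behavioral scores are the participant's *realized*
  synchronized-transition rate (measured on the mean-binarized trace),
  standardized within group, scaled by `behavior_coupling`, plus Gaussian
  noise of sd $\sqrt{1-\rho^2}$ — so the population correlation between
  score and realized rate equals the coupling exactly. The noise sd is the
  simplest choice that makes the stated coupling attainable.

Defaults (28 participants per group, 262 volumes, 7 ROIs) mirror the scale
of the cohort study this analysis style comes from. What the generator does
*not* emulate: hemodynamics, realistic fMRI noise spectra, head motion,
inter-regional structure beyond global synchrony, or any particular
behavioral battery. Passing tests therefore demonstrate that the pipeline
recovers structure *of the kind it assumes*, not that it would recover it
from arbitrary real data.

A note on what the generator can and cannot deliver for validation: the
efficiency score is a ratio of two counting rates, so at 2,000 volumes it
carries irreducible Monte-Carlo noise (on the order of a hundred peripheral
events per participant), and the behavioral score itself carries
$\sqrt{1-0.6^2} = 0.8$ of pure noise by construction. The attainable
population correlation between measured efficiency and behavior is
therefore around 0.4–0.5, not 0.6, and a sample correlation at $n = 27$
will occasionally (order 1% of draws) come out non-positive. Group-level
contrasts average this noise away; single-group, single-replicate
correlation signs do not.

## Statistics

* `tukey_outliers()` flags values outside quartile $\pm 1.5\,$IQR, with
  quartiles by linear interpolation (R's default type 7) — fixed and
  documented because the flag set depends on the convention. Exclusion is
  applied once; on heavy-tailed data a second application can flag anew
  (the fences tighten), which is why idempotence holds for well-behaved
  score distributions but is not a theorem.
* `mean_fc()` averages pairwise Pearson correlations on the Fisher-z scale
  and transforms back. A pair at $|r| = 1$ has infinite z and indicates
  duplicated channels; it raises an error rather than being clipped.
* `efficiency_behavior_correlation()` reports the within-group Pearson r
  with the sample size actually used, dropping missing efficiency scores
  and optionally applying the Tukey exclusion first. The pipeline reports
  plain correlations and group means; formal group inference (ANOVAs,
  dependent-correlation tests) is out of scope because such numbers are
  cohort-specific.

## Problem sizes and runtimes

The test-suite experiments run at: $N \le 7$ ROIs for fitting (seconds per
fit at tolerance $10^{-6}$), $N = 4$ for the exhaustive barrier and basin
oracles (50 random landscapes), $10^6$ Metropolis–Hastings steps for
stationarity, and 100 replicate cohorts of 2 × 28 participants × 2,000
volumes for pipeline-level recovery. These sizes were chosen so the whole
suite completes in a few minutes on one CPU while keeping every check
statistically meaningful; all of them scale up by argument.

## Known limitations

* Exact enumeration caps the system at 14 ROIs; there is deliberately no
  pseudo-likelihood or mean-field path for larger systems, because the
  analysis style this package implements is defined by its exact fit.
* The landscape taxonomy requires both synchronized patterns to be local
  minima; data whose fitted landscape lacks them (possible for weakly
  synchronized systems) cannot be categorized, and the package says so
  rather than inventing a fallback.
* With only three ROIs, a landscape cannot have a third minimum alongside
  both synchronized ones (every pattern is adjacent to `s+` or `s-`), so
  `b_other` requires $N \ge 4$.
* Transition counting assumes discrete volumes; no continuous-time or
  semi-Markov structure is modeled.
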