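---
title: "A stochastic growing-and-dividing protocell: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic growing-and-dividing protocell: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocell)
```

## The model

`protocell` simulates a minimal cell-like object: a spherical lipid vesicle
whose aqueous interior hosts a catalytic polymer chemistry, whose membrane
grows in proportion to the copy numbers of selected internal catalysts, and
which divides into two daughters when the membrane reaches a threshold mass.
The package exists to study when the two processes that make such an object
viable — replication of the internal "genetic memory molecules" and growth
of the container — settle into a common pace (*synchronization*), which
molecular species survive repeated divisions, and how competing or newly
arriving autocatalytic subnetworks fare over generations and at the level of
a protocell population.

### Chemistry

Species are ordered strings over a monomer alphabet (typically `{A, B}`).
Two reaction types exist:

* **cleavage** `AB + C -> A + B + C`: one polymer is cut at a position;
* **condensation** `A + B + C -> AB + C`: two polymers are concatenated,
  through a transient catalyst–substrate complex
  (`A + C -> A:C`, `A:C -> A + C`, `A:C + B -> AB + C`).

Every reaction needs a catalyst (a species of at least three symbols); no
spontaneous or backward reactions occur. The allowed reactions are all
cleavages plus the condensations whose product does not exceed `l_max`.
A *chemistry* — one artificial world — fixes the species, the reactions, the
catalyst assignments and the rate constants. Random chemistries follow the
classic random-catalysis recipe: each eligible species is, with probability
`p`, made the catalyst of one uniformly drawn reaction
(`assign_catalysis()`, `scheme = "per_species"`). A per-(species, reaction)
Bernoulli variant is available as `scheme = "per_pair"` because both
conventions are in common use; the per-species reading follows the model
description most literally, and the emergence thresholds differ only through
the expected number of catalysis assignments.

### Membrane, permeability and transport

The membrane is semipermeable: species shorter than `l_perm` cross it,
longer ones are entrapped. We read "shorter than" strictly — a species of
length exactly `l_perm` does *not* permeate; this is one of two defensible
conventions and is applied consistently (`is_permeable()`).
Catalyst–substrate complexes are treated as transient bound states: they
never permeate and never catalyze, whatever their size.

Two transport regimes are implemented:

* **instantaneous** — diffusion across the membrane (and in both bulk
  phases) is infinitely fast, so each permeable species is *buffered*: its
  internal concentration is pinned to the external one. Buffered species
  carry no tracked copy number; reactions consume them from, and release
  them into, an infinite bath. This is the regime in which autocatalytic
  growth is exponential.
* **fick** — permeable species are tracked and exchange with the outside
  according to Fick's law, `dM/dt = D A ([M]_out − [M]_in)`, with `A` the
  inner membrane surface. The deterministic net flux is realized as two
  opposing unit-molecule jump channels (influx propensity `D A [M]_out`,
  efflux `D A x / V_r`), whose expectation reproduces the law; this keeps
  the whole simulator a pure jump process with exact stochastic semantics.
  Whether the original regime used stochastic or deterministic transport
  between reaction events is not decidable from its description; the jump
  process is the choice here, and a deterministic-flux variant would be an
  extension hook rather than a different model.

### Container geometry

The vesicle is spherical and turgid with constant membrane thickness
`delta` and constant lipid number density `rho` in the membrane. With `C`
lipids in the membrane, inverting the spherical-shell relation
`C = rho (4/3) pi ((r + delta)^3 − r^3)` gives the inner radius and hence
the internal volume

$$V_r(C) = \frac{\pi\delta^3}{6}\Big(\sqrt{\tfrac{C}{\pi\rho\delta^3} -
\tfrac{1}{3}} - 1\Big)^3 \;\sim\; O(C^{3/2})
\quad (\delta^3\rho/C \to 0).$$

`internal_volume()` is this closed form; the test suite verifies it against
an independent numeric shell inversion to 10 significant digits. Because
volume grows faster than linearly in membrane mass, a division at `C =
theta` into daughters of `theta/2` lipids each yields

```{r geometry}
daughter_volume_ratio(theta = 1, delta = 1e-4, rho = 1) # -> 2^(-3/2)
100 * lost_fraction(theta = 1, delta = 1e-4, rho = 1)   # percent lost
```

so in the thin-membrane limit each daughter holds a fraction
$2^{-3/2} = 0.3535\ldots$ of the mother's volume and, at conserved internal
concentrations, about 29.3% ("around 30%") of the internal material is lost
at every division.

Container growth is itself a stochastic channel: coupled species (rate
constants `k_cont`, assigned to non-food species with probability `p_cont`
or by hand) produce membrane lipids at a total propensity
`sum(k_cont_i x_i) / g`, each firing adding `g` lipids. Lipid precursors
are taken as abundant and buffered, and lipids join the membrane instantly,
so no precursor species is simulated. Note that the growth law stated in
concentration form, `dC/dt = sum(k_i [x_i]) V_r`, is count-proportional
(`[x_i] V_r = x_i`), which is what the channel implements.

### Stochastic kinetics

Dynamics follow the Gillespie direct method extended to a time-varying
volume: mass-action propensities (`a = k x_A x_B / V_r` bimolecular,
`k x (x−1) / V_r` for identical reactants, `k x` unimolecular, buffered
participants contributing `[ext] V_r` in place of a count) are recomputed
after *every* firing, including the geometric factors `V_r` and `A`.
Exactness is preserved because the volume changes only at discrete growth
events — between events all propensities are genuinely constant. The inner
loop is C++ (Rcpp) and draws from R's RNG, so `set.seed()` makes whole
trajectories bit-reproducible.

The elementary rate constants are free parameters of the model
(`kinetic_params()`; defaults `k_cleav = k_assoc = k_cond = 1`,
`k_diss = 0.1` in simulation units, per-reaction overrides allowed). No
published values exist for them at this level of abstraction; all
qualitative conclusions below are insensitive to their common scale, which
only sets the time unit.

### Division

When `C >= theta` the protocell divides (`divide_protocell()`). The
threshold is on the lipid count, matching the mass parameterization of the
daughter-volume formula. Each daughter receives `theta/2` lipids; every
tracked molecule is assigned independently daughter-1 / daughter-2 / lost
with probabilities `(q, q, 1 − 2q)`, `q = daughter_volume_ratio(...)`
(`trinomial_with_loss`), or 50/50 without loss (`binomial_no_loss`, the
idealization under which the probability that a daughter misses all `N`
single-copy species of an irrRAF is `alpha_single_copies(N) = 1/2^N`).
Conservation is exact per species. Lineages follow one daughter
(`follow_rule`), because per-lineage records are what the generation plots
need; population-level questions are handled by the deterministic maps
below rather than by simulating the exponentially growing tree.

## RAF sets and the catalyst–product graph

A reaction subset is *reflexively autocatalytic and food-generated* (RAF)
when every substrate lies in the food closure of the subset and every
reaction has a catalyst in that closure. `max_raf()` computes the maximal
RAF by the standard iterative reduction; `food_closure()` deliberately does
*not* require catalysts — catalysis is enforced only for reaction
retention, which is the standard closure semantics for this algorithm.
`find_irr_rafs()` returns the minimal ("irreducible") RAFs: exactly, by
subset enumeration, when the maximal RAF has at most 12 reactions, and by
randomized deletion orders above that (deduplicated, capped, flagged
incomplete). Each minimal core is then extended with its dependent
"tentacles": reactions of the maximal RAF that become supported one at a
time once the core runs. Greedy single-reaction extension cannot jump into
a *different* self-sustaining cycle (whose catalysts only exist once its
own reactions run), so disjoint irrRAFs stay separate while genuine
dependent chains are included.

The condensation sub-steps are collapsed to a single reaction node for all
graph and RAF analyses; only the kinetics layer expands them. The
catalyst–product graph (`catalyst_product_graph()`) keeps only
catalyst-to-product edges; its nontrivial strongly connected components
(`find_sccs()`, via igraph, oracle-checked in the tests) are the candidate
collective replicators, and SCCs appear at lower catalysis probability than
full RAFs because an SCC need not be supplied with substrates — a
Monte-Carlo scan in the test suite reproduces this ordering.

## Fixtures: the study conditions

`make_fixture()` builds the reference chemistries with explicit reaction
lists, so their RAF topology is exact rather than sampled, together with
the geometry and initial copy numbers used throughout the tests:

* geometry `delta = 0.1, rho = 100, theta = 20000, g = 2`. This sits near
  the thin-membrane regime (daughter/mother volume ratio 0.351) and gives
  about 5000 growth events per generation, so the Poisson noise of the
  growth channel contributes only ~1.4% to the division-time jitter.
  `g = 1` recovers the exact single-lipid channel; batching by 2 leaves
  the mean dynamics unchanged.
* food species buffered at external concentration 2, `k_cont = 0.3`. With
  these values the synchronized division-time copy numbers are of order
  10^3 per RAF species — the scale on which published lineage plots of
  this kind of model live. This matters for the convergence diagnostics: at
  O(10^2) copies the division-time series fluctuates by >5% between
  generations and no tolerance band that tight can be met; the choice of
  copy-number scale is a property of the study conditions, set once.
* `fig3_coupled_scc`: one heterogeneous irrRAF made of two SCCs of the
  catalyst–product graph coupled through substrates, the second SCC
  container-coupled, plus two inert tracer species (16 and 8 copies) that
  are neither produced nor consumed and therefore dilute away. The two
  SCCs are made *mutually* dependent (SCC-1 produces SCC-2's substrate,
  SCC-2 catalyzes production of an SCC-1 substrate) so that the unique
  minimal RAF provably contains both SCCs.
* `fig4_two_irrrafs`: two reaction-disjoint irrRAFs on disjoint foods; the
  slow one runs at 0.55 of the fast one's rate constants and is not
  container-coupled, so it dilutes toward the stochastic absorbing state.
* `fig9_permeable`: the same two-irrRAF topology with equal rates, both
  coupled, and diffusion coefficient `D = 0.15` on all permeable species
  for Fick-mode runs; at this `D` growth is transport-limited, which is
  the regime in which a late-arriving irrRAF can catch up.

What the generator emulates is the *qualitative* regime structure of this
model class: synchronization when a container-coupled RAF exists, dilution
of bystanders, dominance of the faster replicator under exponential
growth, and rescue of latecomers under transport limitation. What it does
not emulate: real reaction thermodynamics (no backward reactions, no
energy bookkeeping), structure-dependent catalysis, membrane-surface
chemistry, non-spherical division, or osmotic effects. Passing tests
therefore establish internal consistency of the model and reproduction of
its characteristic regimes, not quantitative predictions for laboratory
vesicles.

## Population maps

Once the slow member of a two-irrRAF protocell is being lost
stochastically, the population splits into carriers of one irrRAF (`X`)
and of both (`Y`). With synchronized generations the abundances follow

$$X_{t+1} = 2X_t + \alpha Y_t, \qquad Y_{t+1} = (2-\alpha)Y_t,$$

with `alpha` the per-division loss probability (`1/2^N` for `N` single-copy
species). Both grow, but the `Y` fraction decays like `((2−α)/2)^t`.
Crowding terms `−β(X+Y)X` and `−β(X+Y)Y` (`pop_step_limited()`) do not
change the outcome when `β` is common. The map is exposed with separate
`beta_X`, `beta_Y` because the coexistence result requires the two-irrRAF
carriers to resist crowding better; which subpopulation carries which
printed `β` value is ambiguous in the source description, so the package
asserts coexistence for `beta_Y < beta_X` (e.g. 5.0e-6 vs 5.88e-6), the
assignment consistent with the verbal statement that the losing irrRAF
"helps" its carriers. Abundances are continuous and deterministic; a
stochastic branching variant is out of scope.

## Numerical choices and degenerate inputs

* Propensities are recomputed after every event; no tau-leaping or hybrid
  acceleration exists apart from the lipid batching parameter `g`.
* `a0 = 0` advances time to the horizon without an event; "no division
  within the horizon" and "death by dilution" are reported outcomes of
  `run_lineage()`, not errors. A per-generation event cap (default 10^7)
  flags truncation.
* The geometry functions reject `C` below `(4/3)πρδ^3` (the membrane
  cannot exceed the sphere); `container_geometry()` additionally requires
  `theta/2` to satisfy the bound so daughters are well-formed.
* Negative counts abort the C++ loop as a consistency error; they cannot
  occur through the provided channel builders.
* The limited population map clips negative outputs to zero and flags the
  trajectory.
* Convergence of the division-time series is declared when the last five
  relative changes are below 5% (configurable); species are classified
  from the log-slope of their division-time counts over the later half of
  the run with a ±0.05 per-generation tolerance.

## Problem sizes used by the test suite

The stochastic checks run at deliberately modest sizes chosen to make the
statistics decisive: 20 seeded lineages of 20–25 generations for the
synchronization, competition and novelty scenarios; 10^3 SSA replicates for
the Poisson/ODE calibration; 10^4–2·10^4 replicate divisions for the
partitioning statistics; 200 random chemistries (≤ 8 reactions, full
subset enumeration) and 200 random digraphs for the exact RAF/SCC oracles.
These sizes are the package's own choice of experiment scale; all of them
complete in a few minutes on one core.

## Limitations

The chemistry is abstract: rate constants are free parameters, catalysis
is structure-independent, and the species universe is bounded by `l_max`.
Only one daughter of each division is followed dynamically, so
protocell–protocell interactions exist only through the deterministic
population maps. Transport-limited ("fick") runs track permeable species
explicitly and are therefore the slower mode. The irrRAF enumeration is
exact only up to 12-reaction maximal RAFs; beyond that the randomized
search can miss cores (it says so via the `incomplete` attribute).
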