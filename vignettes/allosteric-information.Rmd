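---
title: "Modeling information flow in an allosteric signaling motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling information flow in an allosteric signaling motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosinfo)
```

## The model

`allosinfo` models the smallest signaling motif that can express both
canonical forms of allosteric regulation. A single enzyme **A** converts a
substrate **S** into a product **P**; a single downstream protein **B**
reversibly sequesters the product. The enzyme carries an internal
conformational degree of freedom: a baseline conformation A and an
allosterically modified conformation A\*, each of which can bind substrate,
giving the four enzyme states

σ~A~ ∈ {A, A\*, AS, A\*S},

while the downstream protein is either free or product-bound,
σ~B~ ∈ {B, BP}. Together with the free substrate and product copy numbers
*s* and *p*, the full configuration is (σ~A~, σ~B~, *s*, *p*). Exactly one
copy each of A and B is present, so all stochasticity comes from state
switching and molecular turnover rather than enzyme copy-number noise.

The unidirectional reaction channels (15 in all, see
`reaction_channels()`) are:

* substrate production ∅ → S at rate β and degradation S → ∅ at γ~S~·s;
* substrate binding/unbinding for each conformation (k^A^~on~·s, k^A^~off~;
  k^A\*^~on~·s, k^A\*^~off~);
* conformational switching of the unbound enzyme (α: A → A\*, α\*: A\* → A)
  and of the bound complex (α~S~: AS → A\*S, α~S~\*: A\*S → AS);
* catalysis AS → A + P at ν and A\*S → A\* + P at ν\* (the bound substrate
  is consumed; it already left the free pool at binding);
* free-product degradation P → ∅ at γ~P~·p;
* sequestration B + P ⇌ BP (k^B^~on~·p, k^B^~off~); sequestered product
  does not degrade and is returned to the free pool on unbinding.

Two dimensionless ratios quantify allosteric modulation:
**ξ~K~ = k^A\*^~on~ / k^A^~on~** (K-type: binding affinity) and
**ξ~V~ = ν\*/ν** (V-type: catalytic turnover). Values above 1 are
cooperative, below 1 inhibitory.

### Parameter conventions

All rates are expressed in units of the substrate degradation rate, so
γ~S~ = 1 fixes the time unit. The default parameter set
(`default_parameters()`) is k^A^~on~ = k^A^~off~ = 1, k^A\*^~on~ = ξ~K~,
k^A\*^~off~ = 1, α = 1, α\* = 2, α~S~ = 4, α~S~\* = 1, ν = 1, ν\* = ξ~V~,
k^B^~on~ = k^B^~off~ = 1, γ~P~ = 1, with β the externally controlled input.
The four conformational rates α, α\*, α~S~, α~S~\* admit two direction
conventions; we fix the directions as above because it is the unique
assignment under which α\* = 2 > α = 1 makes the unbound baseline
conformation more stable than A\*, and α~S~ = 4 > α~S~\* = 1 makes the
bound complex A\*S more stable than AS — the hallmark thermodynamic
signature of allostery (binding stabilizes the modified conformation).

## The master equation and its truncation

The joint probability p(σ~A~, σ~B~, s, p; t) obeys a chemical master
equation, a linear ODE system p′ = Q p with Q the transition-rate matrix
assembled from all channel propensities. The copy numbers are unbounded, so
Q is built on the truncated box s ≤ s~max~, p ≤ p~max~
(8·(s~max~+1)·(p~max~+1) states). The truncation is *closed* (reflecting):
transitions leaving the box are deleted and excluded from the diagonal, so
every column of Q sums to exactly zero and probability is conserved to
machine precision. Accuracy is certified *a posteriori*: `boundary_mass()`
measures the stationary probability on the box rim, and `auto_truncate()`
doubles s~max~ and/or p~max~ (independently, according to which rim carries
mass) until that mass falls below a tolerance, by default 10⁻⁸, starting
from bounds of 8 with a hard cap of 256. We chose the closed truncation
over an absorbing finite-state-projection construction because it keeps the
generator a proper rate matrix with exact conservation as a structural
invariant; the boundary-mass certificate is equally rigorous.

### Stationary solver

`steady_state()` pins the probability of the reference state (A, B, 0, 0)
at 1, solves the sparse system obtained by deleting that state's balance
equation and column, and renormalizes. For a chain with a unique stationary
law whose closed class contains the reference state this system is
nonsingular, and the reference state of this network is recurrent for every
admissible parameter set (including β = 0). We preferred this pinned-state
formulation over appending a dense normalization row because the dense row
causes severe fill-in in the sparse LU factorization: at ~17,000 states the
pinned solve is roughly 25× faster while agreeing with the replace-row
solution to 10⁻¹⁶. If the direct solve fails or its residual exceeds
10⁻¹⁰, the solver falls back to power iteration on the uniformized chain
P = I + Q/(2λ~max~) starting from the uniform distribution (the halved
uniformization rate guarantees aperiodicity). Every result is certified by
the residual ‖Qp‖~∞~ < 10⁻¹⁰; entries below −10⁻¹² are an error rather than
silently clipped.

### Transient solver

`evolve()` propagates a distribution under a piecewise-constant β(t)
(`beta_schedule()`, `square_wave_schedule()`). Within each segment the
solution is the action of the matrix exponential, computed by
*uniformization*: e^{Qt}v = Σ~k~ Pois(λt; k) P^k v with P = I + Q/λ,
λ = max outflow rate. The Poisson tail is truncated below 10⁻¹² and long
steps are split so the Poisson mean per step stays ≤ 64, which keeps the
weights representable and the mass defect per call ~10⁻¹². The
un-renormalized mass defect is monitored at every grid time and must stay
below 10⁻⁸. This route is exact up to the series tolerance, needs only
sparse matrix-vector products, and has no stiffness constraints.

## Information metrics

`marginal_ab()` collapses a full distribution to the 4 × 2 joint
q(σ~A~, σ~B~); `mutual_information()` evaluates

MI~AB~ = Σ q(σ~A~, σ~B~) ln [ q(σ~A~, σ~B~) / (q(σ~A~) q(σ~B~)) ]

in **nats** (natural logarithm), with 0·ln 0 = 0 and cells below 10⁻³⁰⁰
treated as exact zeros. Internally the identity
MI = H(σ~A~) + H(σ~B~) − H(σ~A~, σ~B~) is used, which is algebraically
identical to the double sum and robust to empty cells; the test suite
cross-checks it against a literal double-sum oracle. MI~AB~ is bounded by
min(H~A~, H~B~) ≤ min(ln 4, ln 2), a bound asserted on every computed
distribution.

For pulsed protocols the time-resolved MI~AB~(t) is computed from the
*instantaneous time-marginal* joint q(σ~A~, σ~B~; t) at each grid point —
not from trajectory histories. This is the natural reading of applying the
steady-state definition at each t; path-level information measures are out
of scope.

## The stochastic simulator as synthetic-data generator and oracle

`ssa_simulate()` implements the exact stochastic simulation algorithm
(direct method: exponential waiting time with the total propensity, channel
chosen proportionally). With 15 channels the O(channels) scan is
negligible, so the direct method was preferred over next-reaction variants.
Piecewise-constant schedules re-draw the waiting time at each segment
boundary, which is exact by the memoryless property. Randomness comes from
a self-contained xoshiro256++ generator seeded via splitmix64; each
trajectory owns its generator and replicate *r* of a batch uses seed
base + r, so runs are byte-for-byte reproducible and trivially parallel.

The simulator is both the synthetic-data generator — it emulates exactly
the Markov jump process the master equation describes — and the independent
oracle for every deterministic solver: stationary occupancies against
10⁵-replicate samples, transient marginals at t = 2 against the same, and
pulse-cycle ensemble means against `evolve()`. Because the SSA is
truncation-free, agreement also certifies the truncation: excursions beyond
the CME box would show up as systematic deviations.

What the generator does *not* emulate: extrinsic noise (cell-to-cell rate
variability), multiple enzyme/protein copies, spatial effects, or explicit
allosteric-ligand binding (ligand occupancy is absorbed into the
first-order conformational switching rates). Passing oracle tests
demonstrates solver correctness for this idealized motif, not realism of
the motif itself.

## Experiment drivers and their defaults

* `run_beta_sweep()` — steady-state MI~AB~, ⟨S⟩, ⟨P⟩ over a log-spaced β
  grid (default 11 points, 2⁻⁴…2⁶) for each allosteric condition (default
  pairs: (ξ~K~, ξ~V~) = (1,1), (1,0.1), (1,10), (0.1,1), (10,1)). The
  information optimum is reported as the grid argmax refined by a 3-point
  parabola in log₂β. Bounds warm-start along the ascending sweep.
* `run_xi_sweep()` — one ratio fixed at 1, the other swept over
  10⁻²…10² (default half-decade spacing) at fixed β.
* `run_pulse()` — square-wave β(t). The published protocol states only
  that β switches between zero and a high value; the amplitude, period and
  duty cycle are therefore package choices, fixed once: 0 ↔ 16·γ~S~,
  period 20/γ~S~, duty 0.5, 3 cycles, 100 grid points per cycle. The high
  level sits on the high-β side of the steady-state optimum so that
  up-switch transients are clearly visible. Each cycle runs its low phase
  first, and the initial condition is the steady state of the first
  segment's β (for the default, the β = 0 steady state), which makes
  cycles after the first periodic. All of these are config keys, not
  hard-wired constants.

Every results row carries its boundary mass; rows whose truncation hit the
hard cap are flagged (`truncation_ok = FALSE`), never dropped silently.

Observed phenomenology with the defaults, all recomputed by the test suite
and `scripts/acceptance.R` at run time: MI~AB~(β) has a strict interior
maximum for every allosteric condition; the refined optimum shifts with the
allosteric ratios (e.g. from β ≈ 2.1 at ξ~V~ = 0.1 to β ≈ 1.8 at
ξ~V~ = 10); at fixed β both strong catalytic inhibition and strong
activation raise MI~AB~ above the neutral value; and each up-switch of a
pulsed input produces a transient MI spike that decays well before the end
of the high phase. Under the default pulse configuration the *activating*
regime shows the tallest spike while the *inhibitory* regime shows the
longest-lived one; the package reports this comparison rather than
asserting a particular ordering, since it depends on the pulse parameters.

## Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| truncation tolerance | 10⁻⁸ boundary mass | MI is entropy-based; tail mass enters logs |
| truncation cap | s~max~ = p~max~ = 256 | fail loudly instead of silently biased results |
| stationary residual | ‖Qp‖~∞~ < 10⁻¹⁰ | certifies the linear solve |
| negativity floor | −10⁻¹² | clip roundoff, error on anything larger |
| uniformization tail | 10⁻¹² per call | keeps transient mass defect ≪ 10⁻⁸ |
| Poisson mean per step | ≤ 64 | avoids underflow of the Poisson weights |
| SSA burn-in (ergodic averages) | 100/γ~S~ | ≫ all relaxation times at default rates |

Problem sizes in the shipped tests and acceptance script are desk-scale by
design: state spaces of ~10³–10⁴ configurations (up to ~4,700 for the
analytic-limit checks), 10⁵ stochastic replicates for oracle comparisons,
and three pulse cycles at 100 grid points — enough to resolve every
asserted property while keeping a full run in minutes on one core.

## Known limitations

* Single copies of A and B only; no volume scaling or compartments.
* Piecewise-constant β(t) only; smoothly varying inputs would need a
  time-ordered propagator rather than per-segment exponentials.
* The closed truncation gives no *a priori* error bound; the boundary-mass
  certificate is a posteriori (and is checked on every reported row).
* MI is computed between the two internal state variables; channel
  capacity, path information and transfer entropy are out of scope.

## A minimal session

```{r example, eval = FALSE}
library(allosinfo)

pa <- default_parameters(allostery_ratios(xiK = 1, xiV = 1), beta = 1)
sp <- auto_truncate(pa, tol = 1e-8)       # certified truncation
ss <- attr(sp, "steady_state")
info_summary(ss)                          # MI in nats, <S>, <P>

sw <- run_beta_sweep()                    # the full steady-state protocol
attr(sw, "optima")                        # refined information optima

pu <- run_pulse()                         # square-wave protocol
plot_pulse(pu)
```
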