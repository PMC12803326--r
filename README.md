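# allosinfo

Stochastic modeling of **information flow through an allosteric signaling
motif**. The package is for quantitative/systems biologists who want to ask
not "how much product does an allosterically regulated enzyme make?" but
"how much *information* about the enzyme's regulatory state reaches the
downstream components, and when?"

## The model

A single enzyme A converts substrate S (produced at rate β, degraded at
γ<sub>S</sub>) into product P, which a single downstream protein B
reversibly sequesters (B + P ⇌ BP). The enzyme has a baseline conformation
A and an allosterically modified conformation A\*, each able to bind
substrate, giving four internal states σ<sub>A</sub> ∈ {A, A\*, AS, A\*S};
the downstream protein has two, σ<sub>B</sub> ∈ {B, BP}. Allosteric
modulation is summarized by two dimensionless ratios

- **ξ<sub>K</sub> = k<sup>A\*</sup><sub>on</sub> / k<sup>A</sup><sub>on</sub>**
  (K-type: substrate binding affinity),
- **ξ<sub>V</sub> = ν\*/ν** (V-type: catalytic turnover),

with ξ > 1 cooperative and ξ < 1 inhibitory. The joint distribution over
(σ<sub>A</sub>, σ<sub>B</sub>, s, p) evolves under a chemical master
equation; signaling performance is quantified by the mutual information (in
nats)

MI<sub>AB</sub> = Σ p(σ<sub>A</sub>, σ<sub>B</sub>)
ln [ p(σ<sub>A</sub>, σ<sub>B</sub>) / (p(σ<sub>A</sub>) p(σ<sub>B</sub>)) ],

evaluated at steady state or, for pulsed inputs, from the time-marginal
joint at each instant.

The package provides:

- the reaction network and validated rate parameters (`default_parameters`,
  `reaction_channels`);
- a sparse truncated master-equation engine with a posteriori truncation
  certificates (`build_generator`, `steady_state`, `evolve`,
  `auto_truncate`, `boundary_mass`);
- information metrics (`marginal_ab`, `mutual_information`,
  `info_summary`);
- an exact Gillespie simulator used as synthetic-data generator and as an
  independent oracle for every deterministic solver (`ssa_simulate`,
  `ssa_sample_at`, `ssa_ensemble_moments`);
- experiment drivers for the three standard protocols: steady-state sweeps
  over β, sweeps over one allosteric ratio, and square-wave (pulsed)
  substrate input (`run_beta_sweep`, `run_xi_sweep`, `run_pulse`), plus a
  command-line wrapper (`inst/scripts/allosinfo-cli.R`).

## Worked example

```r
library(allosinfo)

## steady state at neutral allostery, beta = 1 (rates in units of gammaS)
pa <- default_parameters(allostery_ratios(xiK = 1, xiV = 1), beta = 1)
sp <- auto_truncate(pa, tol = 1e-8)   # grows the state space until certified
ss <- attr(sp, "steady_state")
info_summary(ss)
#> MI(sigmaA; sigmaB) = 0.000262973 nats (H_A = 1.231, H_B = 0.5171)
#> <S> = 0.738615, <P> = 0.261385 molecules; boundary mass 2.51e-12
```

The mutual information is small here — at β = 1 the channel operates below
its optimum. Sweeping β shows the characteristic interior maximum and its
dependence on allostery:

```r
sw <- run_beta_sweep()   # 11-point log grid, five allosteric conditions
attr(sw, "optima")
#>    xiK  xiV beta_opt       mi_max interior
#> 1  1.0  1.0 3.061889 0.0004629296     TRUE
#> 2  1.0  0.1 2.143706 0.0012020788     TRUE
#> 3  1.0 10.0 1.754520 0.0003739170     TRUE
#> 4  0.1  1.0 3.987548 0.0004207853     TRUE
#> 5 10.0  1.0 1.707905 0.0006079793     TRUE
```

Every condition has a strict interior optimum (`interior`), and both the
optimal substrate flux `beta_opt` and the transmitted information `mi_max`
shift with the allosteric ratios: inhibitory V-type modulation
(ξ<sub>V</sub> = 0.1) nearly triples the peak information relative to the
neutral enzyme while moving the optimum to lower flux. Under a square-wave
substrate input (`run_pulse()`), each up-switch produces a transient
information spike that decays well before the end of the high phase — the
motif transmits most of its information in the moments after the input
changes, not at steady state.

Every stochastic function takes an explicit seed and is byte-for-byte
reproducible; every deterministic result carries its truncation certificate
(`boundary_mass`) and solver residual.

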