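# cpmgsa — global sensitivity analysis for Cellular Potts morphogenesis models

Morphogenesis simulators are stochastic black boxes: biophysical
parameters go in, images of cell configurations come out, and it is
genuinely hard to say which parameters — and which parameter
*interactions* — drive the outcome. `cpmgsa` is an R implementation of a
complete variance-based global sensitivity analysis (GSA) workflow for
such models, demonstrated on a Cellular Potts Model (CPM) of vascular
network formation by contact-inhibited chemotaxis.

It is intended for computational biologists who build lattice-based
morphogenesis models and want a principled, reliability-checked
alternative to one-parameter-at-a-time sweeps.

## What is inside

**The simulator.** A 2-D CPM whose energy combines differential adhesion
and a quadratic volume constraint,

    H = Σ_(x,x') J(τ(σ(x)), τ(σ(x'))) (1 − δ(σ(x), σ(x')))
        + λ_A Σ_σ (A − a(σ))²,

with Boltzmann copy dynamics at fluctuation amplitude μ. Cells secrete a
chemoattractant c that diffuses (coefficient D) and decays in the matrix
(rate ε), ∂c/∂t = α(1 − δ(σ,0)) − ε δ(σ,0) c + D∇²c, and copy attempts
at cell–matrix interfaces are biased by ΔH_chem = λ_c (c(source) −
c(target)) — switched off at cell–cell contacts (*contact inhibition*),
which is what turns a chemotacting spheroid into a branching network.

**The measures.** Compactness A_cells/A_hull of the cell mass (exact
integer hull rasterization) and the count of enclosed lacunae (medium
components not connected to the outside, at least one cell-area in
size).

**The GSA engine.** Sobol' indices from a Legendre polynomial chaos
expansion (PCE) fitted by tensor Gauss–Legendre spectral projection:
u(ξ) ≈ Σ u_i Φ_i(ξ), Var_PCE = Σ_{i≥1} u_i² ||Φ_i||², with the index of
a parameter subset J given by the variance share of the basis terms
active exactly on J. A convergence diagnostic compares Var_PCE against
the quadrature-weighted data variance (err_Var = Var_data − Var_PCE)
across truncation orders and flags the orders — if any — at which the
indices can be trusted.

**Orchestration.** Replicated design-point batches with a deterministic
seed schedule, resumable runs, 1-D/2-D parameter sweeps, JSON/CSV
reports, and a command-line front end (`exec/cpmgsa`) with subcommands
`design`, `simulate`, `measure`, `batch`, `slice`, `gsa`,
`validate-ishigami`.

## Worked example 1: is the analysis reliable?

The engine ships with the Ishigami benchmark, whose statistics are known
exactly. With 10 quadrature points per dimension (1000 evaluations):

```r
library(cpmgsa)
v <- ishigami_validation(Nq_values = c(2, 10), p_hat_max = 12)
print(v$sweeps$Nq10, digits = 2)
```

```
 Nq p_hat var_data var_pce err_var rel_err_var     S1     S2    S13 S3 S12 S23 stable converged
 10     1  13.8391  2.6420 11.1971      0.8091 1.0000 0.0000 0.0000  0   0   0  FALSE     FALSE
 ...
 10     7  13.8391 13.7241  0.1150      0.0083 0.3167 0.4377 0.2456  0   0   0  FALSE     FALSE
 10     8  13.8391 13.8366  0.0025      0.0002 0.3141 0.4423 0.2436  0   0   0   TRUE      TRUE
 10     9  13.8391 13.8391  0.0000      0.0000 0.3140 0.4422 0.2438  0   0   0   TRUE      TRUE
 10    10  13.8391 13.8391  0.0000      0.0000 0.3140 0.4422 0.2438  0   0   0   TRUE      TRUE
 10    11  13.8391 13.8391  0.0000      0.0000 0.3140 0.4422 0.2438  0   0   0   TRUE      TRUE
 10    12  13.8391 13.9518 -0.1127      0.0081 0.3115 0.4467 0.2418  0   0   0  FALSE     FALSE
Recommended truncation order: p_hat = 8
```

Reading this: the PCE variance climbs towards the data variance as the
truncation order grows; at orders 8–11 the two agree and the indices sit
still, so the sweep flags them converged — and there the indices match
the closed forms (S1 = 0.31, S2 = 0.44, S13 = 0.24, variance 13.84) to
the printed precision. Beyond order 11 aliasing noise creeps back in and
the flag drops. The same sweep at `Nq = 2` flags *nothing*: too few
points, the result cannot be trusted, and the diagnostic says so rather
than handing you confident nonsense.

## Worked example 2: one simulation, measured

```r
p <- cpm_params(n_cells = 25, A_target = 50, lattice_size = 96,
                lambda_c = 1000, D = 4.4e-14)
r <- run_simulation(p, seed = 1, n_mcs = 1500)
print(r)
diffusion_length(4.4e-14, 1e-3)
```

```
CPM run (seed 1, 1500 MCS)
 a_cells a_hull compactness lacuna_count
    1217   4123   0.2951734            1
diffusion length: 6.6 um = 3.3 sites
```

A short chemoattractant diffusion length (3.3 sites) produces a sprawling
branched mass: low compactness (0.30) and an enclosed lacuna. Raising D
towards 5e-13 m²/s lengthens the gradient, and the same spheroid stays
compact with no lacunae.

## The sensitivity study

`study_profile("desk")` bundles the scaled-down study used by the tests:
four varying parameters (λ_c ∈ [10, 3000], D ∈ [1e-14, 5e-13] m²/s,
λ_A ∈ [5, 300], J_cell,cell ∈ [0, 120]), a 4-point Gauss–Legendre rule
per dimension (256 design points), 3 replicate simulations per point on
a 96×96 lattice with 25 cells, and the Sobol' decomposition of
compactness and lacuna count:

```r
batch  <- run_batch(study_profile("desk", base_seed = 1))
report <- gsa_pipeline(batch)
print(report)
```

At this scale the diffusion coefficient dominates the lacuna count (its
total index is around 0.9) while the cell rigidity λ_A contributes
almost nothing — the directional structure of the full-scale study, at
about 1% of its cost. `study_profile("cluster")` holds the full-scale
configuration (400×400 lattice, 256 cells, 10 points per dimension, 20
replicates; 200000 simulations) for serious hardware.

The methods vignette (`vignettes/cpmgsa-methods.Rmd`) documents the
model, the engine, every tunable with its default and rationale, and
the limitations of the scaled-down profile.

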