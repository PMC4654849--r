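---
title: "Variance-based sensitivity analysis for Cellular Potts morphogenesis models"
author: "cpmgsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-based sensitivity analysis for Cellular Potts morphogenesis models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

Morphogenesis simulators are stochastic black boxes: a vector of
biophysical parameters goes in, an image of a cell configuration comes
out. `cpmgsa` implements a complete workflow for asking *which
parameters, and which parameter combinations, drive the output* of such
a model:

1. a **Cellular Potts Model (CPM)** of vascular network formation by
   contact-inhibited chemotaxis (`cpm_params()`, `run_simulation()`);
2. **morphometric output measures** on the resulting label images —
   compactness of the cell mass and the number of enclosed lacunae
   (`compactness()`, `lacuna_count()`);
3. a **variance-based global sensitivity engine** that computes Sobol'
   indices from a Legendre polynomial chaos expansion (PCE) fitted by
   tensor Gauss–Legendre spectral projection, with a built-in
   convergence diagnostic that says when the indices can be trusted
   (`build_design()`, `spectral_projection()`, `sobol_indices()`,
   `convergence_sweep()`);
4. an **orchestration layer** for replicated batches, parameter sweeps
   and report generation (`study_config()`, `run_batch()`,
   `slice_scan()`, `gsa_pipeline()`), plus the `exec/cpmgsa` command
   line front end.

The engine is validated end to end on the Ishigami benchmark function,
whose variance and Sobol' indices are known in closed form
(`ishigami_exact_stats()`).

# The vascular morphogenesis model

## Lattice, energy, dynamics

Cells live on a square lattice as patches of sites sharing an integer
identifier $\sigma(\vec x) > 0$; $\sigma = 0$ is extracellular matrix
(ECM) and an immutable one-site frame of type *border* surrounds the
interior. The configuration energy is

$$
H = \sum_{(\vec x, \vec x')} J\big(\tau(\sigma(\vec x)),
      \tau(\sigma(\vec x'))\big)\,
      \big(1 - \delta(\sigma(\vec x), \sigma(\vec x'))\big)
  + \lambda_A \sum_{\sigma} \big(A - a(\sigma)\big)^2 ,
$$

with adhesion energies $J$ between the types (cell–cell, cell–ECM, and a
repulsive cell–border contact of 100), and a quadratic volume constraint
of rigidity $\lambda_A$ pulling each cell's area $a(\sigma)$ towards the
target $A$. Both the copy attempts and the adhesion sum use the same
8-site (second-order) neighbourhood, with each unordered pair counted
once; using a single consistent adjacency for dynamics and energy keeps
the incremental energy update exactly equal to the full-lattice
difference (this identity is enforced by an oracle test on random small
configurations).

One Monte Carlo Step (MCS) performs as many copy attempts as there are
interior sites. An attempt draws a random source site and a random
8-neighbour target, and proposes copying the source identifier into the
target. Attempts between sites with equal identifiers, or involving the
frame, are skipped. A proposal with energy change $\Delta H \le 0$ is
always accepted; otherwise it is accepted with Boltzmann probability
$e^{-\Delta H/\mu}$, where $\mu$ (default 50) sets the amplitude of
random membrane fluctuations and thereby the temperature scale of all
the energy weights.

## Contact-inhibited chemotaxis

Cells secrete a chemoattractant at rate $\alpha$; the field $c$ diffuses
with coefficient $D$ and decays in the ECM at rate $\epsilon$:

$$
\frac{\partial c}{\partial t}
  = \alpha\,(1 - \delta(\sigma,0)) - \epsilon\, \delta(\sigma,0)\, c
  + D \nabla^2 c .
$$

Each copy attempt at a cell–ECM interface is biased by
$\Delta H_{\text{chem}} = \lambda_c\,\big(c(\vec x_{\text{source}}) -
c(\vec x_{\text{target}})\big)$, which makes extension towards higher
concentration favourable for $\lambda_c > 0$. The term is switched off
entirely at cell–cell interfaces (*contact inhibition*) — this is the
mechanism that turns a chemotacting spheroid into a branching network
rather than a collapsing ball.

The PDE is integrated by forward Euler with the 5-point Laplacian on the
CPM grid (spacing $\Delta x = 2\,\mu m$), 15 substeps per 30-second MCS
by default, with the frame ring held at $c = 0$ (fixed boundary). The
2-D stability limit is $D\,\Delta t/\Delta x^2 \le 1/4$, and the nominal
setting sits exactly on it at the top of the studied diffusion range
($D = 5\times 10^{-13}\,m^2/s$ gives 0.25). The package therefore
doubles the substep count automatically whenever the ratio exceeds 0.2
(the state records the adjustment); a direct `pde_step()` call with an
unstable step errors instead of silently producing garbage.

## Initial condition

`cpm_init()` places a rasterized disc of exactly
`n_cells * A_target` sites (the sites nearest the lattice centre, with a
deterministic tie-break) and partitions it into contiguous,
approximately equal cells by nearest-seed assignment from a jittered
grid of seeds inside the disc. The chemoattractant starts at zero. All
randomness — seed jitter, copy attempts, Boltzmann draws — flows from
R's global RNG in a documented order, so a `(parameters, seed)` pair
reproduces a simulation bit for bit.

## Reference parameter profile

The sensitivity studies vary four mechanism parameters over wide
physical ranges: chemotactic sensitivity $\lambda_c \in [10, 3000]$,
diffusion coefficient $D \in [10^{-14}, 5\times10^{-13}]\,m^2/s$, cell
rigidity $\lambda_A \in [5, 300]$ and cell–cell adhesion
$J_{\text{cell,cell}} \in [0, 120]$. The remaining rates are fixed, and
their defaults ($\alpha = \epsilon = 10^{-3}\,s^{-1}$,
$J_{\text{cell,ECM}} = 20$) form a reference profile chosen on two
physical grounds: the chemoattractant diffusion length
$L_D = \sqrt{D/\epsilon}$ then spans roughly 1.6–11 lattice sites
(3–22 µm) across the studied $D$ range, which is the regime in which the
full-scale model walks through the documented morphologies (spheroids at
weak chemotaxis, networks with lacunae at small $D$, compact masses at
large $D$); and the adhesion values leave cell–cell and cell–matrix
contacts energetically comparable so that the swept
$J_{\text{cell,cell}}$ range crosses the neutral point. They are
ordinary configuration entries, not measured constants, and can be
overridden in any `cpm_params()` call or study config. On dimensional
grounds the decay length of a field with diffusivity $D$ and decay rate
$\epsilon$ is $\sqrt{D/\epsilon}$ (the ratio $\epsilon/D$ has units of
inverse length squared), and `diffusion_length()` implements exactly
that; the package verifies it against the relaxed 1-D concentration
profile of a line source, which decays by $1/e$ per $L_D$.

# Output measures

**Compactness** is $A_{\text{cells}}/A_{\text{hull}}$: the number of
cell-occupied sites divided by the number of lattice sites whose centre
lies inside or on the convex hull of all cell-site centres. Hull
membership is decided with exact integer cross products and boundary
points count as inside, which makes the compactness of any solid convex
shape exactly 1 (solid discs and squares are regression-tested at
equality, and the rasterization is checked against an independent
point-in-polygon oracle). Degenerate configurations — a single site, a
collinear row of cells — fall back to counting lattice points on the
segment.

**Lacuna count** is the number of medium patches fully enclosed by
cells: 4-connected components of $\sigma = 0$ that are not connected to
the component touching the image border, counted when they hold at
least `min_size` sites (one cell area, 50 sites at the reference scale
— a hole smaller than a cell is a gap, not a lacuna). The
4-connectivity of the medium is the standard dual of the 8-connected
cell dynamics: it prevents medium components from "leaking" diagonally
through a one-site cell wall. Both measures depend only on occupancy,
never on cell identity, so a CPM cell fragmented into several patches
needs no special handling.

`make_fixture()` generates deterministic label images (discs, squares,
rings, multi-hole grids, C-shapes, corner specks) with analytically
known measure values; these serve as ground truth in the test suite.

# The sensitivity engine

## Design, expansion, projection

The $n$ varying parameters are treated as independent uniforms on their
physical ranges, mapped affinely to $\xi \in [-1,1]^n$ with joint
density $\varrho = 2^{-n}$. A scalar output $u(\xi)$ is expanded in a
truncated series of products of univariate Legendre polynomials,

$$
u(\xi) \approx \sum_{i=0}^{N} u_i\, \Phi_i(\xi), \qquad
\Phi_i(\xi) = \prod_{k=1}^{n} P_{\text{index}(i,k)}(\xi_k),
$$

over all multi-indices of total degree at most $\hat p$, so
$N + 1 = \binom{n + \hat p}{n}$. The basis is enumerated in graded
lexicographic order (total degree first, then lexicographic
tie-break), which makes the terms of any lower order a prefix of the
enumeration — a sweep over $\hat p$ therefore needs one projection at
$\hat p_{\max}$, not one per order. The polynomials are deliberately
*unnormalized*, with the squared norms
$\|\Phi_i\|^2 = \prod_k (2\,\text{index}(i,k)+1)^{-1}$ tracked
explicitly, so every formula below stays in its textbook form and the
norm constants remain visible and testable.

Coefficients come from spectral projection,
$u_i = \langle u, \Phi_i\rangle / \|\Phi_i\|^2$, with the inner product
evaluated by an $N_q^n$ tensor Gauss–Legendre rule whose 1-D weights
are rescaled by $1/2$ to the uniform density (they sum to one, and a
rule with $N_q$ points integrates polynomials to degree $2N_q - 1$
exactly — both properties are tested numerically). Only the sample
table is $O(N_q^n)$; `build_design()` refuses designs above a
configurable point cap rather than exploding silently, and documents
its enumeration order (first parameter fastest) as the alignment
contract for sample vectors.

## Moments, Sobol' indices, reliability

From the coefficients, the mean is $u_0$ and

$$
\text{Var}_{\text{PCE}} = \sum_{i \ge 1} u_i^2\, \|\Phi_i\|^2 ,
$$

a non-decreasing function of $\hat p$ for fixed samples. Because each
basis term activates a definite subset of parameters, the variance
splits exactly: the Sobol' index of subset $J$ sums
$u_i^2 \|\Phi_i\|^2$ over the terms whose active set equals $J$,
divided by $\text{Var}_{\text{PCE}}$. Indices over all non-empty
subsets are non-negative and sum to one (a property test), first-order
indices are the singletons, and a parameter's *total* index sums every
subset containing it.

Quadrature-projected coefficients of high-order terms computed from too
few points are noise, not information, and the resulting indices can be
confidently wrong. The package's reliability rule compares the PCE
variance against the quadrature-weighted variance of the raw samples,

$$
\text{err}_{\text{Var}} = \text{Var}_{\text{data}} -
\text{Var}_{\text{PCE}},
\qquad
\text{Var}_{\text{data}} = \textstyle\sum_l w_l u_l^2 -
\big(\sum_l w_l u_l\big)^2 ,
$$

across a sweep of truncation orders (`convergence_sweep()`). An order
is *stable* when the relative mismatch
$|\text{err}_{\text{Var}}|/\text{Var}_{\text{data}}$ is below
`tol_var_rel` **and** no tracked Sobol' index moved by more than
`tol_sobol` from the previous order; the *converged* flag marks orders
inside a run of at least `run_length` consecutive stable orders, and
the recommended order is the smallest flagged one. An all-false flag
column is a meaningful outcome: the analysis cannot be trusted at this
$N_q$, and more model evaluations are needed.

The defaults — `tol_var_rel = 1e-3`, `tol_sobol = 5e-3`,
`run_length = 2` — were fixed against the Ishigami benchmark, where the
truth is known. Two failure modes drove them. First, a *single* order
can look perfect by accident: on an $N_q = 2$ design the second-order
Legendre polynomial vanishes at both quadrature nodes, so the order-2
expansion reproduces the (badly underestimated) data variance exactly
and its indices are unchanged from order 1; requiring a *run* of stable
orders rejects such coincidences. Second, a loose variance tolerance of
$10^{-2}$ admits orders where the expansion has already started
absorbing aliasing noise (the variance overshoot is slow at first);
$10^{-3}$ — agreement to about the printed precision of the variance —
cuts the flagged region exactly to the orders whose indices agree with
the closed-form values to two decimals ($\hat p = 8$–$11$ at
$N_q = 10$, nothing at $N_q = 2$ or $5$). Both tolerances are exposed
as arguments, and near-threshold behaviour in the third decimal is
inherently implementation-defined.

## Validation against closed forms

The Ishigami function
$f(\xi) = \sin \xi_1 + a \sin^2 \xi_2 + b\, \xi_3^4 \sin \xi_1$ with
$a = 7$, $b = 0.1$ on $[-\pi,\pi]^3$ has variance
$\tfrac12 + \tfrac{a^2}{8} + \tfrac{b\pi^4}{5} + \tfrac{b^2\pi^8}{18}
\approx 13.84$ and index pattern $S_1 \approx 0.31$,
$S_2 \approx 0.44$, $S_{13} \approx 0.24$, all others zero — strongly
non-linear, with one pure interaction. `ishigami_validation()` runs the
whole pipeline at several $N_q$; the test suite asserts the converged
statistics to two decimals, the closed forms against an independent
high-resolution quadrature oracle to $10^{-8}$, and — for random
polynomials of total degree $\le 4$ in up to 4 dimensions, where
$2N_q - 1$ covers the degree — engine indices against exact
ANOVA components computed symbolically in the monomial basis, to
$10^{-10}$.

# Study orchestration

A `study_config()` bundles the varying space, the fixed profile, $N_q$,
$\hat p_{\max}$, the replicate count and a base seed. `run_batch()`
executes `replicates` simulations per design point with seeds from
`derive_seed(base, point, replicate)` — a pure integer-mixing function,
so any single run is reproducible in isolation, batches can be executed
in any order or in parallel, and an interrupted batch resumes from its
`runs.csv`. Per-point replicate means (and standard deviations) of the
measures feed `gsa_pipeline()`, which runs the convergence sweep per
measure and reports ranked single-parameter and interaction indices,
per-parameter totals and the interaction share $1 - \sum_j S_j$; an
unconverged sweep is still reported but flagged untrusted.
`slice_scan()` provides the complementary visual diagnostics: 1-D
sweeps (mean ± sd across replicates) and 2-D intensity grids over the
Gauss nodes, with an optional display cap for measures whose dynamic
range is dominated by one parameter (capping the lacuna count at 5
reveals the secondary structure).

## Shipped profiles and problem sizes

Two profiles are shipped. The **cluster** profile is the full-scale
study: 400×400 lattice, 256 cells of 50 sites, 5000 MCS, $N_q = 10$
(10000 design points), 20 replicates — 200000 simulations, intended for
serious hardware. The **desk** profile is the scaled-down study used by
the tests and the acceptance script: 96×96 lattice, 25 cells, 1500 MCS,
$N_q = 4$ (256 points), $\hat p \le 3$, 3 replicates — 768 simulations,
minutes on one CPU.

The desk scale was chosen as the *smallest configuration that preserves
the phenomenon*. Lacunae are mesh cells of the emerging network, with
spacing set by the diffusion length; a network must span several mesh
cells before a single closed loop can exist. With 25 cells the mass
radius is about 20 sites against mesh spacings of 7–22, so only the
small-$D$ corner of the parameter space can close loops — exactly the
qualitative signature of the full model (the lacuna count is largest at
small $D$ and zero at large $D$), at about 1% of the full-scale cost.
Shrinking further (e.g. 64×64 with 25 cells of 20 sites) pushes the
mass radius below one mesh spacing and the enclosed-lacuna count
becomes identically zero over the entire space; no sensitivity statement
about lacunae survives at such a scale, so the desk profile keeps cells
at the reference size of 50 sites and reduces their number and the
simulation length instead. Desk-scale indices are directional
diagnostics, not numeric reproductions of the full-scale study: with 3
replicates and a rare-event measure they carry substantial Monte Carlo
noise, and the convergence sweep will typically (correctly) flag them
as not converged. What the passing desk-scale test establishes is the
*ranking* — the dominance of the diffusion coefficient for the lacuna
count — not index values.

# What the synthetic data does and does not emulate

The simulator and the fixture generator are the package's only data
sources; no external datasets are involved. The CPM emulates the
spatial statistics that matter for the sensitivity question —
interfacial fluctuations, volume-constrained cell rearrangement,
autocrine chemotaxis with contact inhibition, and the resulting
spheroid/network/dispersal morphologies. It does not emulate cell
division or death, 3-D geometry, ECM remodelling, haptotaxis, or
connectivity constraints on cells; conclusions drawn from it transfer
to real vascular cultures only insofar as those mechanisms are
secondary. The geometric fixtures (`make_fixture()`) are exact by
construction and exercise the measures' edge cases (holes open to the
exterior, sub-threshold holes, collinear degeneracies) that simulator
output rarely produces.

# Numerical choices and known limitations

* **Quadrature convention.** Weights are normalized to the uniform
  density (sum one); basis norms are $\prod_k 1/(2k+1)$. All reported
  variances are therefore on the output's own scale.
* **Enumeration contracts.** Design points: odometer order, first
  parameter fastest. Basis: graded lexicographic. Both are serialization
  contracts; results are invariant to them.
* **Gauss rules are not nested**: increasing $N_q$ discards all old
  model evaluations. The convergence sweep varies $\hat p$ at fixed
  samples precisely because that direction is free.
* **PDE integration** is first-order explicit; the substep doubling
  keeps the scheme stable but the discretization error near steep
  gradients at $L_D \lesssim 2$ sites is visible (the 1-D decay-length
  test tolerates 5%).
* **Degenerate inputs.** Constant output: `sobol_indices()` errors (the
  decomposition is undefined), `data_moments()` returns variance 0.
  Images without cell sites: `compactness()` errors. Empty subsets are
  rejected.
* **Desk-scale noise.** The lacuna count at desk scale is a rare-event
  count; its indices are rank-stable but not value-stable across base
  seeds. Use the cluster profile for quantitative index values.
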