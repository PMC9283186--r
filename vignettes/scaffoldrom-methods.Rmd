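---
title: "Methods: parametric reduced-order calcium transport in scaffold pore networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric reduced-order calcium transport in scaffold pore networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Calcium-phosphate bone scaffolds release Ca²⁺ into the interstitial fluid
that percolates through their pore space; regions where the dissolved
concentration stays high are where bone formation is expected. The package
models the steady, saturation-normalized concentration $c \in [0,1]$ in the
fluid domain $\Omega$ (the pore space) as

$$-\nabla\cdot(\nu \nabla c) + \mathbf{v}\cdot\nabla c = 0
  \quad \text{in } \Omega,$$

with boundary conditions on the partition
$\partial\Omega = \overline{\Gamma_I} \cup \overline{\Gamma_O} \cup \overline{\Gamma_S}$:

* $c = 0$ on the inlet $\Gamma_I$ (fresh fluid enters; Dirichlet),
* $\nabla c \cdot \mathbf{n} = 0$ on the outlet $\Gamma_O$ (free outflow),
* $-\nu\,\partial c/\partial \mathbf{n} = r\,(c - 1)$ on the scaffold wall
  $\Gamma_S$ (Robin ion release toward saturation $c = 1$ at rate $r$).

Transient effects are deliberately not modelled: the object of study is the
steady distribution.

Six scalar parameters control the problem, with the modelled ranges used by
all samplers (`default_ranges()`):

| parameter | meaning | unit | range | default role |
|---|---|---|---|---|
| $v$ | mean interstitial speed | µm/s | [1, 60] | advection strength |
| $\gamma,\beta$ | inflow direction angles | degrees | [10, 80] | flow orientation |
| $\alpha$ | crowding exponent | – | [0, 1] | nonlinearity |
| $\eta$ | fluid viscosity | Pa·s | [5·10⁻⁴, 1.5·10⁻³] | sets $D_{SE}$ |
| $r$ | wall release rate | printed units | [0.5, 2] | Robin strength |

The diffusivity couples to the concentration (crowding slows diffusion):
$\nu(c) = D_{SE}\,10^{-\alpha c}$, with the Stokes–Einstein coefficient
$D_{SE} = k_B T / (6\pi\eta\rho)$ for an ion of radius $\rho = 114$ pm at
$T = 37\,°C$ (310.15 K). At $\alpha = 0$ the problem is linear; at
$\alpha = 1$ the diffusivity drops tenfold in fully crowded regions.

The advection field is a direction-parametrized combination of three
potential flows,
$\mathbf{v}(v,\gamma,\beta) = v\,(\sin\gamma\cos\beta\,\mathbf{v}_x +
\sin\gamma\sin\beta\,\mathbf{v}_y + \cos\gamma\,\mathbf{v}_z)$,
whose direction cosines have unit norm for any angles.

## Conventions this package had to fix

Several modelling choices are under-determined by the problem statement and
are fixed here as package conventions:

* **Velocity normalization.** Each directional field $\mathbf{v}_x,
  \mathbf{v}_y, \mathbf{v}_z$ solves Laplace's equation with unit potential
  drop across the corresponding pair of box faces (natural conditions
  elsewhere, including the scaffold wall) and is then scaled to unit
  volume-averaged speed, $(1/V_\Omega)\int_\Omega |\mathbf{v}|\,dV = 1$. The
  parameter $v$ is therefore the *mean interstitial speed*. Normalizing by
  inlet flux or maximum speed instead would change the effective Péclet
  number at a given $v$; mean speed was chosen as the most interpretable
  convention.
* **Inlet/outlet planes.** Flow enters through the three minimum-coordinate
  box faces and leaves through the three maximum-coordinate faces
  (`tag_boundaries()` defaults). Single-axis ducts for verification use
  `inlet = "xmin"` with the side walls marked as outlet (zero flux) and the
  far face as wall (Robin).
* **Units and the release-rate scale.** Internally everything is µm, s,
  µm²/s ($D_{SE}$ is converted from m²/s by 10¹²). The printed release-rate
  unit (m/s) taken literally would overwhelm every other term and turn the
  Robin condition into $c = 1$ on the wall; the solver therefore applies a
  configurable multiplier `r_scale` (default 10 µm/s per printed unit) so
  that the printed range [0.5, 2] spans Robin numbers $rL/\nu$ of order one
  on a ~200 µm pore, which is the regime where the release rate visibly
  modulates the solution. Literalists can set `r_scale` accordingly.
* **Temperature conversion.** 37 °C enters the Stokes–Einstein formula as
  310.15 K.

## Discretization and the nonlinear solve

Linear tetrahedra (P1 Galerkin): exact closed-form element matrices for the
diffusion term, one-point quadrature with the element-averaged nodal
velocity for advection, and triangle quadrature for the Robin boundary
term. Two numerical choices deserve a note:

* **Lumped Robin mass.** The consistent P1 boundary mass matrix produced
  small overshoots above $c = 1$ (up to ~3·10⁻²) on coarse meshes at high
  release rates. The lumped (diagonal) boundary mass preserves the O(h²)
  convergence order — verified against the duct closed form — and keeps
  mid-range solutions inside $[0, 1]$. `fe_structure(robin_lumped = FALSE)`
  restores the consistent matrix.
* **Stabilization.** Element Péclet numbers stay below one across the
  default parameter ranges at the fixture resolutions, so plain Galerkin is
  the default. At extreme corners (v = 60 µm/s, α = 1, η = 1.5·10⁻³ Pa·s)
  Pe reaches ~10 and bounded oscillations of order 10⁻² appear; these are
  reported (as messages), not asserted away. SUPG with the standard
  coth-rule parameter is available (`solver_settings(supg = TRUE)`).

Dirichlet conditions are imposed by symmetric elimination (drop coupled
entries, unit diagonal). The nonlinearity ($\alpha > 0$) is resolved by
Picard iteration: assemble with $\nu(c^\text{old})$, solve, repeat until
the relative Euclidean update norm falls below 10⁻⁸ (iteration cap 50,
initial guess $c = 0$). The stopping rule is update-based; for $\alpha = 0$
the loop exits on the second iteration. A converged solution is a fixed
point: one further iteration moves it by less than the tolerance.

## Synthetic geometries: what they emulate and what they do not

Real scaffold domains in this field come from micro-CT segmentation. No
such meshes ship with this package; instead two voxel generators produce
morphologically analogous stand-ins, meshed by splitting each fluid voxel
into six tetrahedra along its main diagonal (Kuhn split — conforming by
translation invariance) and filtered to the largest face-connected
component so the flow problem is well posed:

* `generate_structured()`: a woodpile of orthogonal cylindrical strands
  (alternating X- and Y-layers, vertical pitch one strand diameter),
  emulating 3D-printed scaffolds. Defaults (diameter 350 µm, spacing
  600 µm) target ~54% porosity with pores of a few hundred µm.
  Deterministic.
* `generate_foamed()`: a union of overlapping spheres with lognormal radii
  (median 113.5 µm, shape 0.25) inserted at seeded-random centres until a
  52.3% porosity target, emulating foamed scaffolds with concave,
  irregular pores. Bit-reproducible for a given seed; the porosity can
  overshoot the target by up to roughly one sphere volume fraction
  (~3% on a 600³ µm box), which is inside the ±0.03 acceptance band.

These stand-ins reproduce porosity, pore scale and the qualitative
concave-vs-rectilinear contrast, but **not** the true pore-size
distributions, wall roughness, interconnect statistics or anisotropy of
real scanned scaffolds. A green test on these fixtures therefore validates
the numerics and the qualitative physics (trends in $v$, $r$, geometry
type), never a quantitative prediction for a particular physical scaffold.
Voxel resolution `h` is the accuracy knob; fixtures in the test suite use
h = 50 µm on 600³ µm boxes (~1.3k nodes) to fit a one-CPU test budget,
which is a deliberate scale-down from production resolutions.

## Reduced-order models

Offline, full-order snapshots $c^i$ are computed on a training set —
either the 2⁶ = 64 corner combinations of the parameter ranges or a
3-level equidistant grid (729 points) — centered about their mean
(`build_snapshots()`), and compressed by SVD (`pod_basis()`). The reduced
dimension $k$ is the smallest integer with
$\sum_{i\le k}\sigma_i \ge (1-\varepsilon)\sum_i \sigma_i$ (default
$\varepsilon = 10^{-2}$); singular values below $10^{-12}\sigma_1$ count as
zero rank. Mode signs are canonicalized (largest-magnitude entry positive)
so bases are reproducible.

Online (`reduced_solve()`), each Picard iteration assembles the full-order
operator at the current reconstruction $\bar c + U^\star z$, projects it
($[U^{\star T} K U^\star] z = U^{\star T}(f - K\bar c)$) and solves the
dense $k\times k$ system. There is no hyperreduction (DEIM or similar):
cost savings are in the solve, not the assembly, and claims are framed
accordingly.

Variants (`train_basis()`):

* **local**: POD on the $n$ training snapshots nearest the query in
  range-normalized parameter distance (each coordinate divided by its
  modelled range length; ties broken by ascending snapshot index),
  centered about their *local* mean. With $n = n_S$ this reproduces the
  global basis exactly.
* **quadratic**: the centered snapshot matrix is augmented with all
  unordered componentwise (Hadamard) products including squares —
  $2n_S + n_S(n_S-1)/2$ columns — to capture curvature of the solution
  manifold. Products are of *centered* snapshots and the expanded matrix
  is not re-centered. A memory guard refuses expansions that would not
  fit (e.g. 729 snapshots predict 266 814 columns) and points to the
  local variant.
* **local-quadratic**: reduce to neighbours first, then expand.

Degenerate case: a training set whose centered matrix is identically zero
(one snapshot, or identical snapshots) yields a $k = 0$ basis whose
reconstruction is the centering vector itself; the online solve returns it
directly.

Errors are measured as $E_r = \|c_\text{rom} - c_\text{fe}\|_2 /
\|c_\text{fe}\|_2$ against the full-order solution on the same mesh. On
the 1.3k-node structured fixture with the 64-corner training set and
$\varepsilon = 10^{-2}$, global linear POD reaches $E_r \approx
1\text{–}3\cdot10^{-2}$ at held-out mid-range points with $k \approx 26$,
and the quadratic variant improves on the linear one — the same
qualitative picture the method is known for.

## Quantity of interest

$\mathrm{QoI} = 100\,V/V_\Omega$, the percentage of fluid volume where
$c > 0.9$. The sub-volume where the P1 interpolant exceeds the threshold
is computed *exactly* per tetrahedron from the distribution function of a
linear field over a simplex: with vertex excesses $y_i = c_i - t$ sorted
descending, the volume fraction above the level set is a closed-form
rational expression per sign pattern (0–4 vertices above). The two-above
case uses a factored form in which every divisor is strictly positive, so
the evaluation is cancellation-free even for tied vertex values (the naive
sum of two simple poles is catastrophically unstable when the two positive
values coincide). The cheap element-mean classifier
(`high_concentration_mask()`) is kept for figure-style masks and converges
to the exact sub-volume under refinement.

On the synthetic fixtures at mid-range parameters the QoI is small in
absolute terms (a few percent; the domains are small and three full faces
are concentration sinks), but the physical trends hold and are tested:
QoI decreases with $v$, increases with $r$, and the foamed geometry
retains a larger high-concentration fraction than the structured one at
matched parameters.

## Workspace, configuration and persistence

Run configurations are JSON (`load_config()` / `write_config()`), with
defaults mirroring the modelled setup ($\varepsilon = 10^{-2}$, Picard
tolerance 10⁻⁸, threshold 0.9, `r_scale = 10`). Pinning a parameter is
expressed as a zero-length range; corner sampling then collapses the
pinned dimensions (a 2-free-parameter toy gives 4 corners). Artifacts
(meshes, velocity bases, snapshots, reduced bases, solutions, CSV reports)
live under a workspace directory keyed by configuration hash; re-running
with the same configuration and seed reuses them, and reports are
byte-identical across repeated runs. Snapshot caching is per parameter
point, so an interrupted offline phase resumes. Persistence uses RDS for
runtime caches and VTU/CSV/JSON for interchange; meshes round-trip through
VTU (primary, with the `boundary_tag` cell field) and Gmsh MSH 2.2 ASCII.
XDMF/HDF5 is not supported: no HDF5 binding is guaranteed in the target
environment.

## Known limitations

* Plain Galerkin oscillates mildly at the most advective parameter
  corners; enable SUPG there.
* The voxel generators cannot match real pore-network statistics; they
  are stand-ins, labelled as such.
* No hyperreduction: online cost still scales with full-order assembly.
* Single species, constant release rate, rigid scaffold, steady state —
  extensions (shear-dependent release, multi-species, transient) are out
  of scope.
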