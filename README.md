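# scaffoldrom

Parametric reduced-order modelling of calcium-ion transport through the
interstitial-fluid (pore) domain of bone scaffolds.

## The problem

Calcium-phosphate scaffolds used in bone regeneration release Ca²⁺ into the
fluid percolating through their pores; regions of sustained high
concentration are where bone formation is expected (osteoinduction). The
steady, saturation-normalized concentration *c* ∈ [0, 1] in the pore space
Ω obeys an advection–diffusion balance

    −∇·(ν ∇c) + **v**·∇c = 0   in Ω,

with *c* = 0 on the inlet Γ_I, free outflow on Γ_O, and Robin ion release
−ν ∂c/∂n = r (c − 1) on the scaffold wall Γ_S. The diffusivity depends on
crowding, ν(c) = D_SE·10^(−αc), with the Stokes–Einstein coefficient
D_SE = k_B T / (6π η ρ) for a Ca²⁺ ion (ρ = 114 pm) at 37 °C. The advection
field combines three normalized potential flows,
**v** = v (sin γ cos β **v**_x + sin γ sin β **v**_y + cos γ **v**_z).

Six parameters — speed v, angles γ and β, crowding exponent α, viscosity η,
release rate r — span a design space too expensive to sweep with full-order
finite elements, so the package implements proper orthogonal decomposition
(POD) reduced-order solvers: snapshots at a corner (2⁶ = 64) or 3-level grid
(3⁶ = 729) training set are centered and compressed by SVD with the
spectrum-amplitude criterion Σ_{i≤k} σᵢ ≥ (1−ε) Σ σᵢ, and new parameter
points are solved in the k-dimensional mode subspace inside the same Picard
loop. Four variants: **global**, **local** (n nearest training points in
range-normalized parameter distance), **quadratic** (training set augmented
with Hadamard products of centered snapshots) and **local-quadratic**.

Because real scaffold geometries come from micro-CT scans that are not
distributable, the package ships voxel-based generators for the two
canonical architectures — foamed (overlapping spherical pores, ~52%
porosity) and 3D-printed woodpile (orthogonal strands, ~54% porosity) —
plus VTU/MSH mesh I/O for external meshes. The headline statistic is the
QoI: the percentage of fluid volume with c > 0.9, computed exactly per
tetrahedron from the linear level set.

Intended audience: computational tissue-engineering and biotransport
researchers prototyping scaffold designs or ROM workflows.

## Worked example

```r
library(scaffoldrom)

# synthetic 3D-printed scaffold fluid domain, 600^3 um at 50 um voxels
mesh <- generate_structured(box_spec(600, 600, 600, 50))
print(mesh)

basis <- velocity_basis(mesh)                     # potential-flow v_x, v_y, v_z
mu <- parameter_point(v = 30, gamma = 45, beta = 45,
                      alpha = 0.5, eta = 1e-3, r = 1.25)
sol <- picard_solve(mesh, mu, basis)              # full-order nonlinear solve
print(qoi_volume_ratio(mesh, sol))

# offline: 64-corner training set; online: global POD at the same point
snaps <- build_snapshots(mesh, corner_sampling(), basis)
rb <- train_basis(snaps, "global", eps = 1e-2)
rom <- reduced_solve(mesh, mu, rb, basis)
cat(sprintf("reduced dimension k = %d, E_r = %.2e\n",
            rb$k, relative_error(rom, sol)))
```

Output:

```
tet_mesh: 1349 nodes, 5616 tets, 1496 boundary facets, V = 1.17e+08 um^3
  tags: 348 inlet, 300 outlet, 848 solid
  porosity 0.542 (structured)
QoI = 0.02% of fluid volume above c = 0.9 (V = 1.895e+04 um^3)
reduced dimension k = 26, E_r = 2.56e-02
```

Reading this: the woodpile domain achieves 54.2% porosity; at mid-range
parameters the flow flushes this small, sink-bounded fixture so only 0.02%
of the fluid volume stays above 90% saturation (drop `v` or raise `r` and
the QoI climbs — those monotone trends are asserted in the test suite); the
POD basis compresses 64 snapshots into k = 26 modes and reproduces the
full-order solution to 2.6% relative error at a point far from every
training corner. At the low-velocity end (`v = 1`) the same fixture reaches
a QoI of about 13%.

The command-line interface wraps the same pipeline
(`inst/cli/scaffoldrom`):

```sh
scaffoldrom offline --config config.json
scaffoldrom online  --config config.json --mu 30,45,45,0.5,1e-3,1.25 --variant local --n 10
scaffoldrom sweep   --config config.json --param v --values 1,20,40,60
```

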