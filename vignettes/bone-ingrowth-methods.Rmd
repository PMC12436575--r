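---
title: "Modeling bone ingrowth into porous swelling bone anchors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bone ingrowth into porous swelling bone anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteogrow)
```

## The problem

Swelling bone anchors are porous co-polymer (MMA/AA) implants that absorb
interstitial fluid after implantation and expand inside the drill hole.
Confined by the surrounding bone, the expansion turns into radial contact
pressure at the bone--anchor interface: the anchor is held by friction
(expansion fit) rather than thread shear. The same pressure is a mechanical
stimulus for bone, and if the anchor is porous, new bone can grow into the
pore space, bonding the anchor to the skeleton and further raising both its
stiffness and its fixation strength.

`osteogrow` simulates this chain end to end on synthetic geometries: pore
generation, hygro-elastic swelling, mechanoregulated ingrowth, and
post-ingrowth mechanics.

## Hygro-elastic swelling

Moisture uptake is modeled as an isotropic stress-free (eigen)strain,

$$\varepsilon_{hs} = \beta_h\,(\alpha_m - \alpha_{m,\mathrm{ref}}),$$

with swelling coefficient $\beta_h = 0.9920\ \mathrm{m^3/kg}$ and
equilibrium moisture content $\alpha_m = 0.08672\ \mathrm{kg/m^3}$ for the
85/15 MMA/AA co-polymer, so $\varepsilon_{hs} = 0.0860$. The moisture
diffusion transient is not solved; the equilibrium content is imposed
uniformly in the anchor material, and the stress field follows from small-
strain linear elasticity, $\sigma = C(\varepsilon - \varepsilon_{hs})$. The
wet modulus (433 MPa, $\nu = 0.25$) is used for the swollen anchor;
surrounding bone is linear elastic (1940.48 MPa, $\nu = 0.34$); unfilled
pores carry a dummy material (0.05 MPa, $\nu = 0.3$) so they can stay in
the mesh without bearing load.

The quantity handed to the ingrowth stage is the area-averaged radial
stress over the bone--anchor interface,
$\bar\sigma_{rr} = \int \sigma_{rr}\,dA / A_\mathrm{interface}$,
implemented as a weighted mean over interface faces with weights projected
onto the nominal cylindrical interface (so the staircase discretization
integrates to the true interface area).

Two boundary conditions are available for the outer bone surface. The
default is traction-free (a finite bone collar), which reproduces the
physically expected pattern -- compressive radial stress at the interface,
tensile hoop stress in the bone. `fix_outer = TRUE` gives rigid far-field
confinement; in the limit of rigid bone the interface stress approaches the
fully confined closed form $-E\varepsilon_{hs}/(1-2\nu) = -74.5$ MPa, which
the solver matches to better than 0.1%.

## The remodeling rule and the osteoconnectivity gate

Apparent density $\rho$ (g/cm^3) evolves per element ("one element = one
basic multicellular unit") in response to the strain-energy-density
stimulus $S = U/\rho$ (J/g), with a lazy zone around the homeostatic
reference $k$:

$$\frac{d\rho}{dt} =
\begin{cases}
B\,(S - (1+\delta)k) & S > (1+\delta)k\\
0 & (1-\delta)k < S < (1+\delta)k\\
B\,(S - (1-\delta)k) & S < (1-\delta)k
\end{cases}$$

integrated by forward Euler with $\Delta t = 0.01$, $B = 1$, $k = 0.004$
J/g, $\delta = 10\%$, and densities clamped to $[0.01, 1.7]$ g/cm^3. The
unit system (mm--MPa--g/cm^3) makes the strain energy density numerically
equal to J/cm^3, so $S = U/\rho$ is in J/g with no conversion factors.

A plain SED rule would densify any sufficiently stimulated element anywhere
in the pore space. What makes ingrowth *sequential* is the
osteoconnectivity matrix: per-element neighbor lists (shared edges in 2D,
shared faces for 3D voxels). In iteration 1 only void elements on the
bone--anchor interface (open pore throats) may densify. From iteration 2
on, a void element becomes eligible once some neighbor's density exceeds
$\alpha \times$ that neighbor's initial density; eligibility is permanent.
The gate factor $\alpha$ sets the ingrowth rate: $\alpha = 1$ lets the
front advance one neighbor layer per iteration, $\alpha = 1.5$ holds it
until the previous layer has densified by 50%. Void components with no
path to an open throat ("pore islands") can never become eligible; they are
detected by `find_pore_islands()` and verifiably never grow.

Grown density maps to stiffness through a power law
$E(\rho) = 1940.48\,(\rho/0.8)^{\gamma}$ anchored at the two material
points of the model set -- dummy void (0.01 g/cm^3, 0.05 MPa) and
trabecular bone (0.8 g/cm^3, 1940.48 MPa) -- giving
$\gamma \approx 2.41$, inside the classical square-to-cube range of
density--modulus relations for trabecular bone. The law is a configurable
argument of `run_ingrowth()`.

### Load application

The swelling pressure is re-applied in the ingrowth model as a constant
pressure on the *anchor-material* faces of the interface; open pore throats
are traction-free. This is the physical contact condition -- contact
pressure exists only where polymer touches bone, and the tissue occupying a
throat is not a pressurized fluid. It also matters numerically: a dummy
element (0.05 MPa) directly carrying tens of MPa would see stimuli of order
$10^5$ J/g and jump to the density cap in a single Euler step. With
contact-only loading, throat elements are strained by the surrounding
matrix instead, and densification is gradual enough for the gate to act.
`load_faces = "all"` restores uniform loading for comparison.

The load is held constant from iteration 1 by default: swelling of these
co-polymers equilibrates within days to weeks, which is short against the
implantation timescale that remodeling iterations represent. An
exponential-saturation ramp (`ramp_iterations`) is available because
sorption kinetics are saturating in time.

### Stopping and metrics

The loop stops at homeostasis (no element changes density by more than 2%
relatively in an iteration) or at the iteration cap. Per iteration the
history records the grown-element count (non-decreasing by construction),
the ingrowth depth (maximum radial distance of any grown element inward
from the interface), the added bone mass $\sum (\rho-\rho_0)V$, and the
filled volume ratio -- the void volume fraction at or above a fill
threshold, default 0.4 g/cm^3 (half bone density; the reference analyses do
not print their definition, so the threshold is configurable).

## Synthetic porous geometries

The generator emulates NaCl-crystal leaching: pore diameters are drawn
uniformly from a band (defaults 300/450/600 +/- 100 um), centers uniformly
inside the anchor cross-section, and insertion continues until the target
porosity (default 60%) is reached, measured on an internal raster; a
candidate that would overshoot by more than 0.02 is redrawn. Pores overlap
freely -- exactly because the manufacturing method cannot enforce
interconnectivity, which is the behavior under study (pore throats and pore
islands are emergent). Everything is a deterministic function of the seed.

Meshing is voxel-style on a structured grid (default seed size 0.05 mm)
with elements labeled by centroid membership; body-fitted meshing is out of
scope. The default 2D element is a bilinear quadrilateral rather than a
triangle pair: with split triangles, crossing one grid cell costs about two
edge-adjacency steps, so a triangle front would advance at roughly half a
cell per iteration and could never reproduce the one-seed-size-per-
iteration front speed of the reference results; with quads, one adjacency
layer is one grid cell. Triangle meshes remain available
(`element = "tri"`) and are used to cross-check the adjacency builder.
3D domains (spherical pores, hexahedral voxels, face adjacency, islands)
are supported for geometry and connectivity studies; the FE solver itself
is 2D plane-strain -- plane strain rather than plane stress because the
slice is axially constrained by the adjacent anchor material.

### What the 2D cross-section does and does not capture

A quarter-annulus cross-section reproduces the governing physics -- the
swelling pressure path, sequential front propagation, gate-rate control,
island stalling -- at minute-scale runtimes. It does *not* reproduce
3D connectivity: at 60% porosity the 2D solid phase sits near its
percolation threshold, so (a) the porous anchor is much more compliant in
plane than a 3D porous cylinder is axially, (b) a substantial void fraction
is islanded in a cross-section (typically 5--30%) while the same generator
in 3D islands only ~0.2%, and (c) the ingrowth front is more tortuous.
Quantities that compare densities, depths per iteration, or qualitative
orderings transfer well; quantities that divide by the floppy pre-ingrowth
2D stiffness, or that integrate bridge areas over the interface, are
dimension-sensitive and should be read as 2D analogs, not predictions of
the 3D values.

## Post-ingrowth mechanics

**Compressive stiffness.** A displacement-controlled compression
($u_y = -\varepsilon y$ on the outer surface, symmetry planes active) gives
the apparent slope as volume-averaged axial stress over applied strain; on
a homogeneous block with $\nu = 0$ this returns the modulus exactly. Pre-
vs post-ingrowth slopes use identical meshes, differing only in the void
densities.

**Push-out.** Axial extraction of the 2 mm quarter slice is modeled as
stick--slip Coulomb friction on the anchor-material contact faces
($\mu = 0.4$ under the held swelling pressure, regularized by a 0.01 mm
elastic slip length), plus -- post-ingrowth -- the shearing of newly formed
bone bridges: interface void elements whose density reached the bonding
threshold (default 0.4 g/cm^3), treated as merged with the bone layer. A
bridge follows the quasi-static Johnson--Cook law
$\sigma_y = A + B\varepsilon^n$ ($A = 0.05$, $B = 0.1$ GPa, $n = 0.08$) in
von Mises shear over a shear zone one element long, and erodes (drops from
the load-bearing system) when its equivalent plastic strain exceeds the
erosion threshold (0.3 by default; the reference analyses print no value).
Forces are reported in newtons for the quarter slice. The pre-ingrowth peak
is the Coulomb bound $\mu p A_\mathrm{contact}$, exactly linear in $\mu$
and $p$; the post-ingrowth curve rises to friction + bridge shear, then
decays to the frictional floor as bridges erode. Because every bridge in
the cross-section shears through the same displacement, they yield nearly
simultaneously; staggered failure through thin 3D throat necks is not
represented, which biases the 2D post-ingrowth peak upward.

## Numerical choices

* Assembly: per-element 8x8 (quad) stiffness built from a unit-modulus
  reference matrix per Poisson ratio (all cells are congruent squares),
  scaled by element modulus; sparse Cholesky solve (Matrix/CHOLMOD).
* Strain energy density: 2x2 Gauss average per quad (the centroid value
  alone misses the bilinear energy modes and breaks the work--energy
  identity, which the test suite enforces to 1e-8); stress and strain are
  reported at centroids. SED uses the mechanical (eigenstrain-subtracted)
  strain conjugate to the stress; the total-strain variant is available via
  `sed_strain = "total"` since the convention during swelling-loaded steps
  is not fixed by the reference formulation.
* Stimulus division clamps density at the lower bound before dividing.
* Degenerate inputs: zero load stops at iteration 1 with zero growth; a
  porosity target of 0 is a valid solid anchor; meshes coarser than half
  the minimum pore diameter are refused; unconstrained solves raise a
  singular-system error.
* Problem sizes: the shipped analyses use the quarter-annulus at 0.05 mm
  (about 5,000 elements anchor-only, 8,000 with the bone collar), 40
  iterations and 5 seeds per pore band; property tests run on a 2 mm
  radius fixture at 0.1 mm. The 3D voxel path reproduces the study-scale
  mesh (about 200,000 hexahedra, 120,000 of them void at 60% porosity).

## Known limitations

* Linear kinematics: near-floppy void regions can reach strains far beyond
  the small-strain regime before densifying; their energies are taken at
  face value, as in any linear remodeling FE.
* No physical-time calibration: one iteration is one solve-and-update; the
  mapping to implantation time is not attempted.
* Surrounding-bone remodeling, moisture diffusion transients,
  poro-elasticity, cyclic loading and cohesive-zone debonding are out of
  scope.
* The 2D-vs-3D connectivity gap above is the dominant systematic when
  comparing to volumetric reference values.

## A minimal run

```{r example, eval = FALSE}
dom  <- generate_porous_domain(pore_spec(300, 100, 0.6, rng_seed = 1))
mesh <- mesh_domain(dom, 0.05, include_bone = FALSE)
mat  <- material_state(mesh)
hist <- run_ingrowth(mesh, mat, 22, remodeling_params(alpha_gate = 1),
                     iterations = 25)
tail(hist$metrics, 1)
```
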