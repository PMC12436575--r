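# osteogrow

Finite-element simulation of bone ingrowth into porous, hygroscopically
swelling co-polymeric bone anchors.

Swelling bone anchors (85/15 MMA/AA co-polymer) absorb interstitial fluid
after implantation and expand inside the drill hole. The confined expansion
produces radial contact pressure at the bone–anchor interface — an
expansion-fit fixation — and that pressure is also a mechanical stimulus
that can drive new bone into the anchor's pore space. `osteogrow` models
the whole chain for researchers in computational biomechanics and implant
design:

1. **Porous geometry** — synthetic salt-leached porosity: overlapping
   random pores (300/450/600 ± 100 µm, ~60% porosity) in a quarter-slice
   cylindrical anchor, voxel-meshed on a structured grid, with the element
   adjacency ("osteoconnectivity") graph and pore-island detection.
2. **Swelling** — plane-strain hygro-elastic solve of the eigenstrain
   ε_hs = β_h (α_m − α_m,ref), reporting the average radial interface
   stress σ̄_rr = ∫σ_rr dA / A.
3. **Ingrowth** — the core algorithm: iterative strain-energy-density
   remodeling, dρ/dt = B(S − (1±δ)k) outside a lazy zone with S = U/ρ,
   forward-Euler integrated and *gated by osteoconnectivity*: a void
   element may densify only after the interface (iteration 1) or a
   neighbor whose density exceeds α × its initial value (iteration ≥ 2)
   has — so new bone forms sequentially from the interface inward, and
   unconnected pores never fill.
4. **Mechanics** — apparent compressive stiffness pre/post ingrowth, and
   push-out fixation with Coulomb friction (µ = 0.4) plus Johnson–Cook
   plastic shearing (σ_y = A + Bεⁿ) and erosion of the newly formed bone
   bridges.

## Worked example

```r
library(osteogrow)

dom  <- generate_porous_domain(pore_spec(300, 100, 0.6, rng_seed = 1))
dom
#> <porous_domain> 2D quarter slice, anchor r = 4 mm, bone layer 1 mm
#>   156 pores (300 +/- 100 um), achieved porosity 0.603 (target 0.60)

mesh <- mesh_domain(dom, 0.05, include_bone = FALSE)
mesh
#> <fe_mesh> 2D quad mesh, h = 0.05 mm: 5027 elements, 5188 nodes
#>   regions: ANCHOR 1995, VOID 3032, BONE 0; interface elements 113

hist <- run_ingrowth(mesh, material_state(mesh), 22,
                     remodeling_params(alpha_gate = 1), iterations = 25)
hist
#> <ingrowth_history> 25 iterations, load 22.00 MPa
#>   grown 747 elements, depth 1.058 mm, filled ratio 0.142,
#>   added mass 0.002673 g
```

Reading: under the 22 MPa swelling-derived interface pressure and the
relaxed gate (α = 1), the ingrowth front advanced about one 0.05 mm element
layer per iteration to a depth of 1.06 mm by iteration 25; 747 of the 3032
void elements captured bone, adding 2.7 mg of bone to the quarter slice.
With a strict gate (`alpha_gate = 1.5`) the front is slower; with pore
islands present, the flagged components (`find_pore_islands(mesh)`) never
grow. `run_campaign(run_config())` chains
generate → swell → ingrow → compress → push-out over all three pore bands
and writes CSV/JSON/VTK artifacts; a thin command-line wrapper lives at
`inst/scripts/osteogrow.R`.

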