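# mscbend

Continuum mechanics of hydrophobic mismatch and local membrane bending in
the gating of the bacterial mechanosensitive channel MscL.

## The problem

MscL opens in response to forces delivered through the surrounding lipid
bilayer.  Two membrane-side quantities dominate that coupling:

* **Hydrophobic mismatch** — the difference `d_p − d_l` between the
  protein's hydrophobic length and the bilayer's hydrophobic core
  thickness.  Accommodating a mismatch deforms the annular lipid and costs
  elastic energy.
* **Local bending** — curvature on the caveolae scale (radius < 100 nm),
  e.g. produced by asymmetric insertion of conical lysolipids such as LPC
  into one leaflet.  Bending skews the transbilayer lateral pressure
  profile `P(z)`, putting one leaflet under higher tension than the other.

`mscbend` models their combined effect at desk scale for users who want a
transparent, fully scriptable alternative to black-box finite-element
suites: membrane biophysicists exploring how chain length and curvature
direction modulate MS-channel gating, and methods developers who need a
small, oracle-tested axisymmetric elastostatics kernel.

## What is inside

1. **Bilayer model** — mean-field piecewise pressure profiles for
   di-10:0, di-16:0 and di-24:1 bilayers (positive, zero, negative
   mismatch against the channel), leaflet tensions
   `γ = ∫ P(z) dz`, and the bending-induced asymmetry
   `Δσ(z) = K_A C_L z / (2T)`.
2. **Axisymmetric FE solver** — small-strain linear elasticity on
   bilinear quads with selective reduced integration (stable at the
   protein's ν → 0.5).  The channel is an hourglass-pored annulus
   (E = 40 MPa) bonded into a three-layer laminate membrane; spherical
   bending enters as a Kirchhoff plate field on the far-field clamp band.
   Verified against the patch test, the Lamé thick-walled cylinder and
   superposition.
3. **Gating energetics** — the closed form

   `G = G_H + G_B`,
   `G_H = 2 (K_A³ K_B / t⁶)^¼ · u₀² · 2π R_ave`,  `u₀ = (d_p − d_l)/2`,
   `G_B = (K/2)(C_L − C_P)² + K′(C_L*² − 2 C_L* C_P* cos 2θ + C_P*²)`,

   with `K = K′ = K_B π R_ave²` and `K_B ∝ t³`.
4. **Amphipath dose calculator** — monolayer area difference ↔ induced
   curvature ↔ LPC molecule count and molar ratio.
5. **Scenario fixtures, robustness sweeps, reporting** — the 3 × 3 study
   design as YAML-serialisable scenarios, lognormal parameter
   perturbation, CSV/JSON/VTK outputs.

## Worked example

```r
library(mscbend)

# How much LPC must insert into one leaflet to bend the membrane to
# R = 25 nm (C = 0.04 1/nm)?
lpc_dose(0.04)
#> Amphipath dose: dA = 511 A^2 -> 5 molecules (3.4% molar);
#> C = 0.04 1/nm, R = 25 nm (local)

# Gating free energy of the thin-lipid (positive mismatch) case under
# inward bending
bl <- make_bilayer("di-10:0"); ch <- make_channel("closed")
total_energy(bl, ch, curvature_state(-0.04))
#> G = 1.018e-18 J (247 kBT) = G_H 1.018e-18 J + G_B 3.956e-22 J

# Finite-element pore response: inward bending opens the hydrophobic lock
st <- equilibrate_resting(bl, ch)
bend_and_extract(bl, ch, -0.04, resting = st)
#> Bend C_L = -0.04 1/nm: lock radius 0.225 -> 0.2539 nm (delta +0.02891 nm);
#> dA = -1.68e+04 A^2
```

Reading the numbers: a ~511 Å² leaflet area difference corresponds to 5
LPC molecules (3.4% of the host POPC leaflet) and a local 25 nm bending
radius.  The mismatch term dominates the gating energy (G_H ≈ 247 k_BT
for the 0.9 nm mismatch) while the bending term at C_L = 0.04 1/nm is
well under 1 k_BT.  In the solver, the resting pressure profile squeezes
the 0.25 nm lock to 0.225 nm, and inward (cytoplasmic) bending re-opens
it by ~0.03 nm; outward bending closes it by the same amount.

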