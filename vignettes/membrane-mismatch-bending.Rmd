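---
title: "Methods: continuum mechanics of mismatch and local bending in MscL gating"
author: "mscbend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum mechanics of mismatch and local bending in MscL gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscbend)
```

# Scope and model overview

`mscbend` studies how two membrane-side stimuli — protein–lipid
hydrophobic mismatch and local (caveolae-scale) membrane bending — jointly
modulate the mechanosensitive channel MscL.  It works at three levels that
deliberately mirror one another:

1. a **mean-field bilayer model**: piecewise lateral pressure profiles
   $P(z)$, leaflet tensions and their bending-induced asymmetry;
2. an **axisymmetric linear-elastic finite-element (FE) model** of the
   channel as a representative volume element (RVE) embedded in a
   three-layer laminate membrane, from which deformed pore profiles are
   extracted;
3. a **closed-form gating free energy** $G = G_H + G_B$ combining a
   mismatch term and a Helfrich-type bending term.

Everything runs in seconds on one CPU.  No external data are consumed:
all inputs are parameter sets, generated and serialised by the
`scenario` layer.

# The bilayer: geometry, moduli, pressure profile

A bilayer is described by its hydrophobic core thickness $d_l$ (monolayer
half-thickness $t = d_l/2$), a headgroup band of thickness $h = 0.8$ nm
per side, an areal expansion modulus $K_A = 0.24$ N/m, and a bending
modulus $K_B$.  The three study bilayers are

| label | $d_l$ (nm) | mismatch sign vs the 2.7 nm channel |
|---|---|---|
| di-10:0 | 1.8 | positive (lipid thinner) |
| di-16:0 | 2.7 | zero |
| di-24:1 | 3.6 | negative (lipid thicker) |

The thicknesses are fixtures chosen so the mismatch magnitudes are
symmetric ($\pm 0.9$ nm); symmetric magnitudes make every cross-bilayer
comparison attributable to thickness alone.  $K_A$ is taken
thickness-independent, as areal elasticity varies only weakly with chain
length, while $K_B$ scales with the cube of the half-thickness
(`bending_modulus_from_thickness()`, default exponent 3 with 2 available),
anchored at $K_B = 0.85\times 10^{-19}$ J for di-16:0.

## Pressure-profile form and calibration

The mean-field profile is piecewise constant with, per leaflet, a
repulsive headgroup band, a negative interfacial-tension band at the
head/tail boundary (width $0.3\,d_l$), and a repulsive tail band; the
central tail band is split at $z = 0$ so each band lies in one leaflet.
Calibration constraints, in order of priority:

* exact zero net tension for the unloaded membrane (per leaflet:
  $P_{head} h + P_{int} w + P_{tail}(t - w) = 0$);
* all band magnitudes scale as $1/d_l$ (interfacial tension
  $0.035 \cdot 2.7/d_l$ N/m per leaflet, headgroup peak $0.009/d_l$
  N/m·nm$^{-1}$), so thicker bilayers have both flatter profiles
  (peaks fall as $1/d_l$–$1/d_l^2$, max $|P| \approx 135/60/34$ MPa
  across the fixtures) and weaker integrated band tensions — this is what
  makes the thickest bilayer deform the resting channel least.

The numerical values are fixtures in the literature range for fluid PC
bilayers (interfacial tensions of tens of mN/m, peak pressures of
hundreds of atmospheres), not reproductions of any published profile:
the upstream continuum study takes its profile from earlier work without
printing values.  Sign conventions, used consistently everywhere:
$z = 0$ at the midplane, $+z$ extracellular; $P > 0$ repulsive;
$C_L > 0$ is outward bending (outer leaflet stretched), so the membrane
bending strain is $\varepsilon(z) = C_L z$.

`apply_bending_to_profile()` superposes
$\Delta\sigma(z) = \dfrac{K_A}{2T}\, C_L z$ (laminate thickness
$T = d_l + 2h$) on each band at its midpoint.  The resulting
leaflet-tension difference $\Delta\gamma = \gamma_{in} - \gamma_{out}$ is
exactly odd in $C_L$ and monotone: inward bending ($C_L < 0$) raises the
inner-leaflet tension, outward bending the outer one.  Above an edge
strain $|C_L|(t+h) = 0.2$ the function warns rather than fails: the
superposition remains well defined but the small-strain premise is
doubtful.

# The finite-element model

## Geometry and mesh

The axisymmetric $r$–$z$ domain runs from the pore wall to a patch radius
$R_{out} = 20$ nm (at least four protein radii, so the far field is
unperturbed).  The protein occupies an annulus between the hourglass pore
wall $r_0(z)$ — outer radius 2.5 nm at the membrane surfaces, tapering
quadratically to a 0.25 nm constriction at $z_c = -0.45$ nm, the
cytoplasmic-side hydrophobic lock — and a cylindrical outer wall at
3.5 nm.  The lipid core has thickness $d_l$ far from the protein and
morphs linearly to the protein's hydrophobic length $d_p$ over a
$\lambda = 2$ nm annulus (hydrophobic matching); the protein–lipid
interface is fully bonded.  The pore shape is a parametric fixture: the
crystal-structure-derived RVE coordinates are not tabulated anywhere we
could reuse, and every qualitative pore-mechanics statement the package
tests survives the parameterisation.

Meshes are structured, conforming bilinear quads: radial columns track
the pore wall through the protein and grade geometrically outward; rows
follow the laminate layers (≥ 3 elements per headgroup band) with a
normalized through-core grid.  Two rows are pinned: the constriction
height $z_c$ (so the gating readout is always a mesh node — letting it
float made every pore readout mesh-noisy) and its mirror image (so the
row layout stays symmetric about the midplane).  Default target size
$h = 0.25$ nm gives roughly 1000 nodes; the full nine-scenario pipeline
solves in a few seconds.

## Elements, materials, loads

The solver is displacement-based small-strain axisymmetric elasticity
with selective reduced integration: the deviatoric part of the
constitutive tensor is integrated $2\times 2$, the volumetric
($\lambda$) part at the element centre.  This keeps the formulation
usable at the protein's $\nu = 0.5$, which is mapped to $0.499$
(a displacement formulation is singular at exactly one half).  The
protein RVE uses $E = 40$ MPa.

For the lipid, no single through-thickness modulus can match both
$K_A$ and $K_B$ of a real bilayer — at matched $K_A$ a homogeneous plate
is several times too stiff in bending (monolayer decoupling is a
transverse-shear effect outside a compatible continuum laminate).  We
therefore give the laminate one effective modulus, $E = 50$ MPa
($\nu = 0.47$), shared by all three bilayers: they are the same
hydrocarbon at different chain lengths, so thickness should be the only
mechanical difference.  This choice reproduces the areal-modulus scale at
the reference thickness ($ET/2(1-\nu) \approx 0.20$ vs 0.24 N/m) and
makes the laminate bending stiffness grow as $T^3$, the accepted scaling
of membrane bending rigidity.  It is the one genuinely free parameter of
the reduction; sensitivity in the 35–60 MPa literature range changes
magnitudes but not the signs discussed below.

Loads enter three ways:

* the intrinsic pressure profile as an initial in-plane stress
  $\sigma_{rr} = \sigma_{\theta\theta} = -P(z')$ in the lipid, evaluated
  in locally scaled coordinates inside the morph annulus so the three
  pressure regimes follow the deformed layers;
* prescribed spherical curvature on the outer 10% clamp band as the full
  Kirchhoff plate field, $u_z = -\tfrac{C_L}{2} r^2$ **plus** the fibre
  rotation $u_r = C_L r z$.  The rotation matters: prescribing the
  deflection alone turns the band into a shear diaphragm that transmits
  no bending moment (we verified the leaflet-area-difference oracle fails
  by three orders of magnitude without it).  With $C_L = 0$ the same
  band is the resting far-field clamp, so resting and bent states share
  one constrained dof set and superpose exactly;
* optional edge tractions (used by the analytic benchmarks).

The mean-field bending stress of the bilayer model is deliberately *not*
added on top of the curvature boundary condition: under the Kirchhoff
band the solver develops the bending stress distribution itself, and
adding the closed-form term would double-count it.

## Verification

The solver is held to analytic oracles in the test suite: exact patch
test (uniform strain reproduced to machine precision), the Lamé
thick-walled cylinder within 1% at $h = 0.1$ nm with monotone
convergence under refinement (and no locking at $\nu = 0.499$),
superposition to $10^{-10}$, and a homogeneous-plate bending check in
which the leaflet area difference matches the shallow-spherical-cap
closed form $\Delta A = 2 C s A$ within a few percent.

## Readouts

The deformed pore profile is the displaced pore-wall node column.  Two
radii are reported: the profile minimum (the narrowest point of the
deformed shape) and the radius at the hydrophobic-lock material point.
The gating readout `delta_r_constriction_nm` uses the lock site: under
load the location of the shape minimum slides along the hourglass, which
makes minimum-based differences saturate and flip sign with mesh size,
whereas the material-point response converges to ~1% by $h = 0.35$ nm.
The leaflet area difference integrates the displaced leaflet midsurfaces
by surface-of-revolution quadrature over the lipid annulus and is
reported relative to the resting state (the z-asymmetric pore gives the
resting state a genuine few-Å² offset; the bending part is odd in $C_L$
to leading order).

# Gating energetics

The energy model is evaluated per bilayer–channel–curvature state:

$$G_H = 2\left(\frac{K_A^3 K_B}{t^6}\right)^{1/4} u_0^2\, 2\pi R_{ave},
\qquad u_0 = \frac{d_p - d_l}{2},$$

$$G_B = \frac{K}{2}(C_L - C_P)^2 +
  K'\left(C_L^{*2} - 2C_L^* C_P^* \cos 2\theta + C_P^{*2}\right).$$

Two readings of the mismatch bracket are possible from its typography;
we use $u_0 = (d_p - d_l)/2$, the monolayer deformation, because the
alternative ($|d_p - d_l/2|$) is dimensionally inconsistent with a
deformation and would not vanish at zero mismatch, contradicting the
zero-mismatch energy minimum.  The trailing factor is the inclusion
circumference $2\pi R_{ave}$, required for units of energy.  Under
spherical bending of an isotropic inclusion ($C_1 = C_2$,
$C_{P1} = C_{P2}$, $\theta = 0$) the bending term reduces to the pure
quadratic, minimised exactly at $C_L = C_P$.

Absolute values of $K$ and $K'$ are not published; we take
$K = K' = K_B \pi R_{ave}^2$ (the Helfrich areal density integrated over
the protein footprint), honouring the stated ratio $K'/K = 1$.  The
channel-state curvatures are fixtures: $C_P = 0$ (cylindrical) closed,
$C_P = -0.08$ nm$^{-1}$ (conical) open.  Whether the published energy
landscape plots $G$ or the open–closed difference is ambiguous; both are
available here (`energy_landscape()` for either channel state), and the
quantitative checks use the minimum location of $G$, which is the same
under either reading.  Energies are reported in J and in $k_BT$ at 298 K
($4.11\times 10^{-21}$ J), since the published landscapes are unitless.

Checked consequences (all asserted in the tests): $G_H \ge 0$ with
equality iff $d_p = d_l$; $G_H$ even in the mismatch sign at fixed $t$,
so the negative-vs-positive asymmetry arises only through $t$ and
$K_B(t)$ — with $K_B \propto t^3$ the prefactor falls exactly as
$t^{-3/4}$; every landscape is minimised at $C_L - C_P = 0$ and ordered
zero < negative < positive mismatch at every grid curvature within
$C_P \pm 0.1$ nm$^{-1}$ (the ordering is guaranteed only on a bounded
grid: far enough from $C_P$ the thick bilayer's larger $K$ must
eventually dominate); and the bending work $W = K_B A_0/(2R^2)$ is
linear in $A_0$ and $K_B$ and quarters when $R$ doubles.

# Amphipath dose

Asymmetric insertion of a conical lysolipid expands one leaflet; for a
shallow spherical cap the area difference is $\Delta A = 2 C s A$ with
leaflet-midsurface separation $s$ and patch area $A$.  The molecule count
is `round(ΔA / a_mol)` (ties to even; 511/101.35 = 5.04 → 5) with the
LPC headgroup projection $a_{mol} = 101.35$ Å², and the molar ratio uses
a fixture host leaflet of 147 POPC lipids (leaflet area 10040 Å² at
68.3 Å² per lipid), reproducing 3.4%.  The patch parameters behind the
511 Å² worked example ($A = 25.15$ nm², $s = 2.54$ nm) are calibration
values chosen to match that reference number — the upstream FE patch
geometry is unpublished, so the FE-integrated area difference is an
order-of-magnitude quantity here, not a bit reproduction.  Radii below
100 nm are classified as local curvature (the scale that modulates MS
channels), above 200 nm as global (negligible effect, flagged with a
warning).

# Scenario generator and robustness

`default_scenarios()` emits the 3 × 3 study design (three bilayers ×
resting/inward/outward at $|C_L| = 0.04$ nm$^{-1}$, i.e. a 25 nm bending
radius).  Scenarios serialise to YAML with units in every field name;
round trips are lossless to 15 significant digits and schema violations
name the offending field.

`perturb_scenario()` multiplies each strictly positive continuous
parameter (thicknesses, moduli, radii) by independent lognormal factors
of unit mean and chosen coefficient of variation, deterministically per
seed; signed quantities (curvatures, the lock position) are untouched.
`ordering_robustness()` re-runs the three headline orderings over many
seeds at cv = 5%, perturbing the three bilayer scenarios with a shared
draw sequence and one shared perturbed channel so each comparison stays
like-for-like.  The generator emulates parametric uncertainty only: it
does not emulate compositional heterogeneity, thermal fluctuations,
protein conformational substates or leaflet-number asymmetry, so passing
robustness checks speak to the model's parameter sensitivity, not to
biological variability.

# What the reduction reproduces, and what it does not

The package reproduces, stably under mesh refinement and asserted in the
suite: the bending-direction asymmetry of leaflet tensions; resting-state
pore narrowing at the hydrophobic lock (strongest for thin bilayers,
weakest for the thickest, flattest-profile bilayer, with widening away
from the core); inward bending opening the lock and outward bending
closing it, exactly oddly, for every mismatch; the energy-landscape
minimum at $C_L = C_P$ and the zero < negative < positive ordering; the
LPC worked example; and the bending-work scalings.

One published ordering is *not* reproduced by the FE layer, and we
report that rather than engineer it: under identical inward curvature
the zero-mismatch bilayer is reported to open the pore most, followed by
negative then positive mismatch.  In a linear elastic solver the bent
minus resting response is independent of the resting pre-stress, and the
bending moment delivered to the inclusion grows with the laminate's
flexural stiffness ($\propto T^3$ at fixed modulus) — the same
work-to-bend argument the energy model makes via $W = K_B A_0/(2R^2)$.
The converged FE ordering is therefore monotone in thickness
(negative > zero > positive), reproducing the negative > positive leg
but not the zero-mismatch maximum.  The zero-mismatch optimum is an
energetic statement — mismatch adds the offset $G_H$ — and emerges here
in the energy model, which is precisely the relationship between the two
routes: the FE layer transmits curvature mechanics, the energy layer
accounts for what the mismatch costs.  Capturing both in one solver
would require geometrically nonlinear analysis about a load-generated
(not geometric) hydrophobic-matching pre-stress, which is outside this
package's scope.  The same monotonicity means the perturbation-robustness
suite reports the pore-ordering leg as failing by construction, and the
energy-ordering leg is itself structurally sensitive at cv = 5%:
independent perturbation of $d_p$ and $d_l$ breaks the equal-mismatch
design, and with $G_H \propto u_0^2$ the positive/negative energy
ordering flips in roughly a sixth of draws.  The test suite asserts the
published expectations faithfully and records these two as failures;
the numbers above are the suite's own measurements.

# Numerical choices and limitations

* Direct sparse Cholesky on the constrained system; residual verified
  below $10^{-10}$ of the load norm on every solve.
* Default problem sizes: $h = 0.25$ nm meshes (~1000 nodes) for the
  scenario pipeline; $h = 0.5$ nm for the 100-seed robustness sweep;
  201-point curvature grids for landscapes.  The full suite runs in
  well under a minute.
* Ties in `round()` follow banker's rounding (relevant only to the
  amphipath count at exact half-integers).
* Degenerate inputs fail early with classed conditions
  (`mscbend_invalid_scenario`, `mscbend_schema_error`,
  `mscbend_singular_system`, `mscbend_mesh_error`); physically dubious
  but computable regimes (large bending strain, global-scale curvature)
  warn instead.
* Out of scope: large-deformation and contact mechanics, full gating to
  the open state, non-axisymmetric bending ($C_1 \ne C_2$ in the FE
  layer; the energy layer does handle it), atomistic detail (charges,
  internal protein degrees of freedom, inter-protein interactions),
  amphipath partitioning thermodynamics and line-tension mechanisms.
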