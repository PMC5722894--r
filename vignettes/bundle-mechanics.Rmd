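---
title: "Continuum mechanics of the MscL C-terminal bundle: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum mechanics of the MscL C-terminal bundle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlegate)
```

# The question and the model

MscL is a pentameric bacterial channel gated by bilayer tension. Its
cytoplasmic C-terminal domain (residues A110–S136 per subunit) is a
five-helix coiled coil held by three inter-subunit interaction rings: a
water-mediated hydrogen-bond ring at E118 (top belt), the E124/R126/D127
salt-bridge ring (middle belt), and a direct R135–S136 hydrogen bond between
adjacent subunits (bottom belt). `bundlegate` asks, at the continuum level,
what happens to this bundle when the channel is pulled open.

The model has four ingredients.

1. **Helices as elastic rods.** Each of the four helical segments per
   subunit is a circular rod (r = 2.5 Å) represented by 3D shear-deformable
   (Timoshenko) beams — the rods are stubby (r/L ≈ 1/15), so shear
   deformability matters; an Euler–Bernoulli flag exists for benchmarks.
   Moduli: N-term 0.35, TM1 2.6, TM2 3.4, C-term 7.7 GPa; ν = 0.48. Those
   values come from steered-MD indentation of the individual helices and are
   used as published.

2. **The bilayer as an elastic plate.** An annular flat shell (membrane +
   Mindlin bending + transverse shear) of thickness 35 Å and E = 4.3 MPa,
   with a central opening matched to the transmembrane rod footprint
   (boundary gap ≤ 3 Å). Tension is applied as an outward in-plane edge
   traction at the outer rim (γ = 9.5 mN/m ⇔ 2.63 MPa edge stress); the rim
   is otherwise restrained only against rigid-body motion (vertical and
   tangential), leaving radial expansion free. At this thickness-to-element
   ratio the plate is "thick", so full shear integration is appropriate and
   shear locking is not a concern; plate bending is in any case dynamically
   irrelevant here (the load is in-plane).

3. **Tie constraints.** The TM2 rods (over their bilayer span), the
   N-terminal rods and the head of TM1 are rigidly coupled, translations
   only, to the nearest plate node — the continuum rendering of "embedded in
   the bilayer". In addition, consecutive segments of each subunit
   (N-term↔TM1 bottom, TM1 top↔TM2 top via the periplasmic loop, TM2
   bottom↔C-term top) are joined by short covalent *linker beams* (radius
   2.5 Å, modulus the mean of the adjoining rods). The spec of the model
   would be mechanically disconnected without them; a polypeptide backbone
   is axially stiff once taut, which is what a beam gives.

4. **Belts as nonlinear connectors.** Each belt is a point-to-point
   connector between adjacent subunits whose force–displacement table is the
   analytic −dU/dr of an explicit interface energy model (tabulated at
   0.05 Å spacing over 0.5–3× the closed-state separation, linear
   interpolation, zero force beyond the grid):

   * *middle*: sum of Debye–Hückel screened Coulomb terms over the charge
     pairs E124⁻↔R126⁺ and D127⁻↔R126⁺ of adjacent subunits;
   * *top*: a Morse well of depth equal to the canonical DSSP hydrogen-bond
     energy (≈ 2.92 kcal/mol) and width parameter α = 0.5 Å⁻¹, active only
     when the environment supports water-mediated bonding (disabled in
     vacuum);
   * *bottom*: a Morse well of the same DSSP-calibrated depth with
     α = 2.0 Å⁻¹ (a direct, short-range bond).

The solver applies the tension in adaptive load increments and equilibrates
each with damped Newton iteration (trust region on the update, backtracking
line search, automatic substepping); softening connectors make the system
genuinely nonlinear. The reference configuration is treated as
self-equilibrated: connector forces present at zero displacement are
subtracted as a constant balancing load, so zero tension reproduces the
crystallographic geometry exactly while the tables remain the raw −dU/dr
(and therefore satisfy the finite-difference oracle in the tests).

# Parameter choices that required judgement

**Side-chain charge offsets (middle belt).** The connectors attach at Cα
sites (the attachment atom is not specified by the source structures'
coarse reading, and Cα keeps the model coarse). But a screened Coulomb
energy evaluated at the Cα–Cα distance (~9.4 Å, ε_r 78.5, 0.3 M) is
~0.08 kcal/mol — far below k_BT, and such a middle belt could not keep the
bundle assembled. Physically the charges sit at the side-chain tips, not at
Cα. The energy model therefore evaluates each pair term at
r_eff = r − (offset_A + offset_B), with offsets E 4.0, D 2.5, R 5.5,
S 2.5 Å (Cα → carboxylate/guanidinium centre distances), smoothly floored
at 2 Å. With the offsets the middle-belt interface energy at the closed
separation is ≈ −2.8 kcal/mol — salt-bridge scale. Setting the offsets to
zero recovers the bare Cα convention.

**The wall springs and their calibration.** A ring of independent beams has
no hoop stiffness, whereas the solid transmembrane wall of the real protein
(and of a solid-meshed FE model) does: under 9.5 mN/m a 4.3 MPa plate
carries ~60 % far-field strain and would drag unconnected rods outward by
30–40 Å. The missing wall continuity is restored by elastic contact springs
between adjacent TM2 rods at membrane mid-height. Their stiffness is *not*
fitted to any reported outcome of the modelled experiment; it is anchored to
an independent, well-established electrophysiological quantity — the
in-plane area expansion of MscL gating, ΔA ≈ 20 nm² from Boltzmann analyses
of tension–activation curves. `calibrate_wall_numeric()` bisects the spring
constant until the radial expansion of the TM2 wall ring at the gating
tension equals ΔR = √(R_p² + ΔA/π) − R_p (≈ 9.6 Å for the default
geometry). Calibration is done once, in the physiological salt-water
environment, and the resulting stiffness — a property of the protein, not
of the solvent — is reused unchanged in vacuum and water.

**Bilayer transverse contraction ratio (`bilayer_poisson` = 0.1).** The
plate recovers its thickness change from the in-plane strains via the
plane-stress coupling ε_z = −ν/(1−ν)(ε_xx+ε_yy). The published model states
no transverse ratio for the bilayer. Volumetric incompressibility (ν = 0.5)
would be wrong here: the apparent 4.3 MPa patch-scale modulus is dominated
by undulational compliance, which carries essentially no thickness change;
only the true area-stretch component (K_A ≈ 0.24 N/m, i.e. K_A/t ≈ 68 MPa)
thins the membrane at constant volume. Scaling 0.5 by the modulus ratio
gives ~0.03; we adopt 0.1 as the one-significant-figure effective value.
This choice was fixed before the pipeline was first run. Sensitivity: under
the default load the open-state thickness is 35·(1 − 2νσ_eff/E)-like, so
ν ∈ [0.03, 0.2] maps to ≈ 34–26 Å.

**Top-belt well width (α = 0.5 Å⁻¹).** The first implementation used
α = 1.0 Å⁻¹; that made the water bridge so stiff near equilibrium
(U''(r₀) = 2D_eα² ≈ 5.8 kcal mol⁻¹ Å⁻²) that it acted as a rigid fulcrum:
the rod tip above E118 bent outward while the E118 ring itself never
separated — contradicting the established picture that the top-belt
water-mediated bonds break during opening. A water bridge is long-range and
soft; α = 0.5 Å⁻¹ (interaction width ~2 Å, peak restoring force
D_eα/2 ≈ 0.73 kcal mol⁻¹ Å⁻¹) lets the belt load and yield. The depth was
left at the canonical DSSP value throughout.

**Belt arc positions.** Residue i maps linearly to arc fraction
(i−110)/26 along the C-terminal rod (110 at the membrane-proximal end), so
E118 sits at 0.31, E124–D127 at 0.54–0.65, R135/S136 at 0.96–1.0.

**Dissociation call.** The per-residue radial displacement is interpolated
along each C-terminal rod and averaged over subunits; the dissociated
segment is the maximal interval starting at 110 that exceeds a threshold.
The default threshold is twice the median displacement of residues 125–136,
floored at 0.5 Å — the floor guards the rule when the distal bundle barely
moves (its median can be ~0 or slightly negative), and 0.5 Å is the scale
of incidental elastic drift of the assembled model. Both knobs are exposed.

# What the synthetic data emulate — and what they do not

`gen_ideal_pentamer()` builds an idealized, exactly five-fold-symmetric
closed state: vertical C-terminal rods at an 8 Å coiled-coil radius, TM1
tilted 25° from the pore axis, TM2 near-vertical with its cytoplasmic end
protruding below the bilayer, N-terminal rods lying radially at the
cytoplasmic surface. It reproduces the published rod dimensions exactly and
the topology of a closed MscL; it does not reproduce per-residue atomic
detail, helix curvature, or inter-subunit packing asymmetry. A green
geometry test therefore establishes correct construction and symmetry, not
structural realism beyond those features.

`gen_belt_fixture()` plants an exact number of geometric hydrogen bonds
(distance ≤ 3.5 Å, deviation from D–H···A linearity ≤ 30°, both inclusive)
on a sparse lattice with decoys violating exactly one criterion each; the
planted count is provable ground truth for the counter, nothing more.

`gen_cw_spectrum()` produces a three-line first-derivative
Lorentzian/Gaussian spectrum with a controllable central peak-to-peak width
— sufficient for the mobility parameter, which only reads that width. It is
*not* a spin-Hamiltonian simulation: no motional regime, no dipolar
broadening, no hyperfine anisotropy. Wide lines overlap the hyperfine
satellites' tails, which biases a width round-trip by up to ~15 % at 8 G;
the definitional recovery tests therefore use the single-line mode
(`outer_amplitude = 0`). `gen_power_sat_curve()` uses the standard
inhomogeneity-exponent saturation model on a 31-point logarithmic power
grid (0.05–51.2 mW); at 5 % amplitude noise the P₁/₂ recovery error is
~4 % median. `gen_mobility_profiles()` encodes the assumed statistical
structure — elevated loops A110–T116 and N134–S136, 3.6-residue (100°/res)
periodicity in T116–E131, and an open-state increase confined to A110–E119
— with adjustable noise; noise level and grid are free parameters of the
synthetic world since the source experiments do not state theirs.

# Numerical choices

* Internal units: Å, kcal/mol; moduli converted once
  (1 kcal mol⁻¹ Å⁻³ = 6.9477 GPa); all conversions centralized and tested.
* Newton tolerance 1e-8 (relative to the applied-load norm), ≤ 50
  iterations per increment, 20 base increments with adaptive halving down to
  1/64 of the base step and a 10 Å trust region per update.
* The helical-periodicity statistic is the variance fraction (R²) explained
  by the best sinusoid with period constrained to 95–105°/residue, after
  linear detrending. A plain DFT-bin power fraction is unusable on a
  16-residue window (the bins fall at 90° and 112.5°); the R² form gives
  ~1 for a pure 100°/residue cosine, 0 for a constant, and a simulated
  white-noise null median of ~0.16.
* Rod axes are fitted by total least squares with a cylinder-fit refinement
  (minimum variance of point-to-axis distance): plain PCA of a helix is
  biased by the azimuth–rise correlation over few turns; the refinement
  recovers an ideal helix axis to ~1e-6 Å.
* The pore diameter scans deformed TM1 axes at 0.5 Å steps over the
  transmembrane region; measured from rod axes minus the rod radius
  (cylinder surface), pore axis at the TM1 centroid.

# Known limitations

* Kinematics are linear (small-strain elements with connector geometry
  updated from current positions). At the gating displacement (~10 Å) this
  over-straightens tilting rods; the ±15 % acceptance bands on the headline
  quantities reflect formulation sensitivity of exactly this kind.
* The wall-spring ring is an effective device: it restores hoop stiffness
  but not the iris-like helix rearrangement of the real protein; its
  calibration imports the experimentally established gating area change
  rather than predicting it.
* Middle-belt connectors join E124 to the adjacent R126 with the summed
  interface table (one connector per interface); D127's term enters the
  energy but not as a separate geometric link.
* The connector energies are pairwise continuum estimates; they approximate
  the force-field interaction energies of an all-atom treatment only in
  scale and ordering (middle/bottom strong, top weak), not in detail.
* Plate bending uses full shear integration (slightly stiff in thin-plate
  bending); irrelevant for in-plane loading but not a general thin-shell
  element.
* The EPR generators are statistical stand-ins; no conclusion about real
  spectra beyond the implemented readout definitions should be drawn from
  green tests.
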