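# bundlegate

Coarse-grained continuum mechanics and spin-label EPR analysis of the
cytoplasmic C-terminal helical bundle of MscL, the bacterial mechanosensitive
channel of large conductance.

## The scientific problem

MscL opens a ~30 Å water-filled pore when bilayer tension approaches the
lytic limit, acting as an osmotic safety valve. Its last 27 residues per
subunit (A110–S136 in *E. coli* MscL) form a five-helix coiled coil on the
cytoplasmic side, held together by three rings ("belts") of inter-subunit
interactions:

* **top belt** — water-mediated hydrogen bonding at E118,
* **middle belt** — the E124/R126/D127 salt-bridge ring,
* **bottom belt** — a direct R135–S136 hydrogen bond between adjacent
  subunits.

Whether this bundle stays assembled during gating (molecular sieve /
oligomer stabilizer) or dissociates has been contested. `bundlegate`
implements a continuum finite-element model of the question, plus the
site-directed spin-labelling (SDSL) EPR readouts used to probe it
experimentally, driven entirely by synthetic geometry and synthetic spectra.

## The model

* α-helices are **elastic rods** (radius r = 2.5 Å; lengths N-term 18.65,
  TM1 47.33, TM2 42.51, C-term 36.06 Å; Young's moduli 0.35, 2.6, 3.4 and
  7.7 GPa; ν = 0.48), discretized as 3D Timoshenko beams.
* the bilayer is an **elastic plate** (E = 4.3 MPa, thickness 35 Å) meshed
  as an annular Mindlin shell with a central opening matched to the
  transmembrane rod footprint (gap ≤ 3 Å); tie constraints couple it to the
  TM2 rods, the N-terminal rods and the head of TM1.
* the belts are **nonlinear connector elements** whose force–displacement
  tables are F(r) = −dU/dr of explicit energy models: screened Coulomb
  (Debye–Hückel) pair terms for the middle belt,

      U(r) = 332.06 q₁q₂ /(ε_r r) · exp(−κr) kcal/mol,
      κ = √(2 N_A e² I / (ε₀ ε_r k_B T)),

  and DSSP-calibrated hydrogen-bond wells for the top and bottom belts,
  with the DSSP electrostatic energy

      E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol.

* a membrane tension γ (default 9.5 mN/m ≙ 2.63 MPa) is applied as an
  outward in-plane edge traction and the nonlinear system is solved by
  incremental Newton iteration with adaptive load substepping.

Environments: `vacuum` (ε_r = 1, no water-mediated bonding), `water`
(ε_r = 78.5) and `salt-water` (0.3 M KCl, Debye κ ≈ 1.80 nm⁻¹).

The EPR side implements the mobility parameter ΔH₀⁻¹ (inverse central-line
peak-to-peak width), power-saturation fitting
A(P) = scale·√P /(1+(2^{1/ε}−1)P/P₁ᐟ₂)^ε, the NiEdda accessibility parameter
Π ∝ ΔP₁ᐟ₂ / ΔH₀, α-helical periodicity (100°/residue) detection, and
closed-vs-open contiguous-segment calling.

## Worked example

```r
library(bundlegate)
report <- run_gating_pipeline(run_config())   # salt-water, 9.5 mN/m
print(report)
```

prints (the run is deterministic):

```
Gating report
  pore diameter     :  14.68 ->  34.23 A
  bilayer thickness :  35.00 ->  30.43 A
  top    belt sep   :   9.40 ->   9.52 A
  middle belt sep   :   9.40 ->   9.02 A
  bottom belt sep   :   9.40 ->   9.40 A
  dissociated segment: [110, 118]
```

Reading: under gating tension the pore dilates to ~34 Å and the bilayer
thins from 35 to ~30 Å, while of the C-terminal bundle only the segment
A110–E118 moves away from the five-fold axis — the middle and bottom belts
keep the lower bundle assembled. Repeating the run in vacuum
(`run_environment_sweep`) makes the top-belt separation jump to 12.4 Å
instead of 9.5 Å: without water-mediated top-belt bonding the bundle splays
much further, which is the model's statement that those hydrogen bonds
stabilize the bundle.

EPR example:

```r
pr  <- gen_mobility_profiles(epr_profile_spec(noise_sd = 0))
delta_mobility_segments(pr$closed, pr$open)   # list(c(110L, 119L))
fit_power_saturation(gen_power_sat_curve(p_half = 5, noise_sd = 0))$p_half  # 5.0
```

A command-line front end is installed at `inst/cli/bundlegate`
(subcommands `run`/`simulate`, `sweep`, `synth`, `epr mobility`,
`epr p-half`, `epr compare`).

## Documentation

The methods vignette (`vignettes/bundle-mechanics.Rmd`) describes the model
assumptions, the parameter choices and their provenance, what the synthetic
generators do and do not emulate, and known limitations.
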