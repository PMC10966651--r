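---
title: "The microwave replacement model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microwave replacement model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Microwave irradiation couples to the permanent dipole of water and pumps
energy into molecular rotation much faster than collisions can redistribute
it, so the rotational degrees of freedom of the solvent run hot relative to
its translational degrees of freedom. `mwmd` represents this *replacement
model* directly, without an explicit oscillating field: rigid three-site
(SPC) water has exactly six kinetic degrees of freedom, three translational
(centre-of-mass motion) and three rotational (motion of the sites about the
centre of mass), and each set is coupled to its own weak-coupling
(Berendsen) heat bath. A third bath thermostats the solute. The microwave
condition sets the rotational bath to 700 K while the translational and
solute baths stay at 300 K; the equilibrium condition sets all three to
300 K. Ions, which have no rotational degrees of freedom, follow the
translational bath.

The kinetic partition is computed exactly: for each water,
`ke_trans = M |v_com|^2 / 2` and `ke_rot = ke_total - ke_trans`. For a
rigid molecule the residual is purely rotational, so no inertia tensor is
needed on the propagation path; the inertia-tensor route
(`w = I^-1 L`, `ke = w' I w / 2`) is retained in the test suite as an
independent oracle. Temperatures follow from equipartition with
`kB = 0.00831446 kJ/(mol K)`.

Each bath rescales its velocities every step by
`lambda = sqrt(1 + (dt/tau) (T_target/T_inst - 1))`, capped at 1.25 per
step. Water velocities are decomposed into the centre-of-mass part and the
internal remainder, scaled separately, and recombined, so the two solvent
baths act on disjoint degrees of freedom; the rotational bath provably
leaves every molecular centre-of-mass velocity unchanged.

## What the thermostats can and cannot hold

With the default relaxation time `tau = 0.01 ps` the controller is strong,
but it is proportional control: in a nonequilibrium steady state each bath
sits offset from its setpoint by exactly the amount needed for the
per-step rescaling to balance the physical heat flux through its degrees
of freedom. In the microwave condition the rotation-to-translation
conduction in liquid water is fast (the implied librational energy
relaxation time in these simulations is roughly 0.2 ps, consistent with
the sub-picosecond values reported for water), which at a 400 K rotational
excess amounts to a conduction of tens of kJ/mol per water per
picosecond. The resulting steady state on a 216-water box is
approximately 679 K rotational and 321 K translational: about 20 K below
and above the 700/300 K setpoints. We verified that these offsets are a
property of the continuous dynamics, not of the implementation: they are
unchanged under timestep halving and quartering, under system size and
cutoff (216 waters at 0.8 nm vs 512 at 1.1 nm), and under the cutoff
smoothing scheme (plain truncation vs switching of any width). Shortening
`tau` would shrink them linearly, but 0.01 ps is the protocol value, so
the package reports the honest steady-state temperatures instead.

## Interactions

Nonbonded interactions are Lennard-Jones (`C12/r^12 - C6/r^6`, geometric
combination) plus reaction-field Coulomb:

`E = f q_i q_j (1/r + crf r^2 / (2 Rc^3) - (1 + crf/2)/Rc)`,
`crf = 2 (eps_rf - 1) / (2 eps_rf + 1)`,

with `f = 138.935458 kJ nm mol^-1 e^-2` and external permittivity
`eps_rf = 61` by default. The shift makes each pair energy vanish at the
cutoff. Excluded (1-2 and 1-3) pairs still receive the distance-dependent
reaction-field correction `f q_i q_j crf r^2 / (2 Rc^3)`; the constant
shift term is omitted for them because it exists only to cancel a direct
`1/r` that excluded pairs do not have, and it carries no force. 1-4
interactions act at full strength.

The cutoff is applied between molecule (charge-group) centres of
geometry — each water or ion is one group, each solute atom its own group —
which avoids the severe artifacts of cutting a water dipole into
monopoles. A plain group cutoff still leaves the Hamiltonian discontinuous
whenever a group pair crosses the cutoff, which on a desk-scale box
produces an energy drift of several percent per 10 ps. The whole
site-site interaction of a group pair is therefore modulated by a C1
switching function of the centre distance over the window
`[Rc - 0.1 nm, Rc]` (the envelope gradient acts on the group centres and
is included in the virial). With switching, a 216-water NVE run at
dt = 2 fs drifts by under 0.2% over 10 ps. `switch_width = 0` recovers
plain truncation.

Bonded terms are harmonic bonds and angles and periodic dihedrals
(`k (1 + cos(m phi - phi0))`), used during minimization; during dynamics
all solute bonds are SHAKE-constrained (relative tolerance 1e-4) and
waters are reset analytically by SETTLE, with an iterative fallback for
degenerate trial geometries. After constraint projection the half-step
velocities are recomputed from the constrained displacement.

Pressure, when needed, is the atomic-virial form
`P = (2 KE + W)/(3V)` including the constraint virial
(`f_c . (x - x_com,mol)`), and the Berendsen barostat scales the box and
molecular centres of mass isotropically with `mu` clamped to
[0.95, 1.05] per step. The barostat is active only in the final
equilibration cycle; production runs are NVT.

## Protocol

Equilibration runs in 20 ps cycles (10,000 steps at 2 fs): a 50 to 300 K
heating ladder in 50 K increments (six cycles, all baths equal), for the
microwave condition one added cycle that raises the rotational bath to
700 K, then a cycle that initializes roto-translational constraints on
the solute (per-step removal of its net linear and angular momentum) and
a final cycle with pressure coupling to 1 atm — 160 ps total for the
equilibrium condition and 180 ps for the microwave condition. The solute
position-restraint force constant starts at 25 MJ/(mol nm^2) and is
multiplied by 0.1 each cycle, with the first cycle at the initial value.
The net centre-of-mass motion of all atoms is removed every 1000 steps
throughout. `steps_per_cycle` scales the whole schedule down for
desk-scale work; tests and the acceptance script use 500-step (1 ps)
cycles, which this small-system protocol tolerates because the heating
ladder converges within a fraction of each cycle at `tau = 0.01 ps`.

Default production length in tests is 50 ps with frames every 0.2 ps.
Propagation is deterministic, so a checkpoint (positions, velocities, box,
global step) restarts bit-identically as long as segment boundaries are
multiples of the neighbour-list interval, which the driver enforces.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| timestep | 0.002 | ps | leapfrog |
| tau (all baths) | 0.01 | ps | weak coupling; offsets scale with tau |
| rotational setpoint (MW) | 700 | K | the replacement-model temperature |
| cutoff | 1.4 | nm | reduced automatically when the box is small |
| switch width | 0.1 | nm | 0 = plain truncation |
| eps_rf | 61 | - | reaction-field external permittivity |
| restraint start | 25 | MJ/(mol nm^2) | x0.1 per cycle |
| salt concentration | 0.15 | mol/L | per species, from the water count via 55.345 mol/L |
| ion exclusion | 0.4 | nm | minimum ion-solute distance |
| solvation wall | 1.2 | nm | solute to box wall |
| water exclusion | 0.23 | nm | atom to added-water centre of geometry |
| SHAKE tolerance | 1e-4 | relative | per constraint, every step |
| H-bond criteria | 0.25 nm, 135 deg | | H-acceptor distance, donor angle |
| SASA | probe 0.14 nm, 960 points | | Shrake-Rupley, golden-spiral points |

The paper-scale cutoff of 1.4 nm requires box edges above 3.0 nm
(minimum image plus neighbour-list skin). The desk-scale boxes used in
the tests (1.9-2.5 nm) therefore run at 0.7-1.1 nm cutoffs; this changes
absolute energies slightly but none of the qualitative behaviour the
package is built to demonstrate.

## The synthetic systems

`build_water_box()` places rigid SPC waters (O charge -0.82 e, H +0.41 e,
O-H 0.1 nm, H-O-H 109.47 degrees, LJ on oxygen only) on a jittered cubic
lattice at a target density of 970 kg/m^3 with random orientations.
`make_toy_solute()` builds united-atom peptide stand-ins — five sites per
residue (N, CA, C, O and a sidechain bead CB), standard backbone geometry
assembled by internal coordinates at ideal helix (-57, -47), extended
(-139, 135) or hairpin backbone dihedrals — with roughly a quarter of the
sidechain beads carrying a +-1 e charge under seed control, and bonded
equilibrium values taken from the constructed geometry so every fixture
starts at its own bonded-energy minimum. The amide hydrogen is implicit;
hydrogen-bond and secondary-structure analyses place it geometrically
from the preceding carbonyl (the DSSP convention).

These fixtures emulate the size, charge pattern and hydrogen-bonding
topology of small proteins, not their chemistry: there is no real
force-field parameterization, no explicit polar hydrogens, no sidechain
rotamers, and 6-12 residues instead of 50-250. Passing tests therefore
demonstrate that the machinery (thermostat separation, constraint
dynamics, energy decomposition, analyses) behaves correctly and that the
*direction* of the solvation effects under rotational heating — fewer
solute-water hydrogen bonds, less-negative solute-water electrostatics —
reproduces at desk scale; they say nothing quantitative about real
proteins over 100 ns.

## Measuring the solvation response at desk scale

The headline comparison — fewer solute-water hydrogen bonds and
less-negative solute-water electrostatics under rotational heating — is a
*solvation* effect. A single 6-12-residue toy peptide free in solution
explores different conformations over any 50 ps pair of runs, and that
conformational drift moves the solute-water observables by more than the
solvation effect itself. The package therefore measures the effect in a
paired design with the solute position-restrained
(1000 kJ mol^-1 nm^-2) to its settled conformation in *both* conditions:
the two runs then differ only in the solvent's rotational temperature, so
the difference is the solvation response at fixed solute structure. The
restraint is common to both arms of each pair; it reduces variance and
cannot bias the sign of the effect. With this design an 8-residue helix
in ~420 waters shows 20-22% fewer solute-water hydrogen bonds and 2-6%
less-negative solute-water electrostatic energy under the microwave
condition, the same direction (and, for the hydrogen bonds, a similar
magnitude) as full-scale protein simulations report. Unrestrained
comparisons remain available — they simply need far more sampling than a
desk-scale budget provides.

## Analyses

RMSD uses Kabsch superposition (SVD with reflection exclusion) on
backbone atoms; RMSD100 applies the Carugo-Pongor size normalization
`RMSD / (1 + ln sqrt(N/100))`, which is undefined below N = 15 and
unvalidated below 40 residues (the function warns). RMSF superposes
frames first by default (`fit = FALSE` for pre-aligned frames). The
hydrogen-bond criterion is geometric (H-acceptor <= 0.25 nm, donor angle
>= 135 degrees). SASA is Shrake-Rupley with deterministic golden-spiral
points; the polar/nonpolar split classifies residues by name (Gly and
Pro are kept in the polar list as configured in `residue_polarity()`;
the classification is a user-replaceable argument). Secondary structure
is a simplified Kabsch-Sander assignment: DSSP electrostatic H-bond
energy with the -0.5 kcal/mol threshold, helix from two consecutive
i to i+4 turns, sheet from bridge patterns, coil otherwise.

Uncertainties use Flyvbjerg-Petersen blocking: pairwise halving with the
SEM taken from the first plateau (relative change below 5% across two
levels) or the deepest level with at least four blocks. Condition
comparisons report `(mean_MW / mean_eq) - 1` per paired system — chosen so
that quantities that shrink under microwave heating come out negative —
with the SEM of the per-system changes; the literal ratio orientation is
available via `literal_order = TRUE`.

## Numerical choices and degenerate inputs

- Thermostat order per step: integrate, constrain, scheduled global-motion
  removal, kinetic partition, per-bath scaling — so constrained degrees of
  freedom never enter a temperature.
- `lambda` capped at 1.25 per step (and used directly when the
  instantaneous temperature is zero) to prevent blow-up on tiny systems.
- SETTLE falls back to SHAKE for near-collinear trial geometries; the
  fallback count is reported.
- Collinear angle triplets and degenerate dihedrals raise errors rather
  than returning garbage forces; overlapping atoms (r < 1e-6 nm) abort
  the nonbonded evaluation.
- The minimizer stops on `|dE|` below threshold from the first step (a
  rejected move with a sub-threshold rise counts as converged), grows the
  step by 1.2 on acceptance and halves it on rejection, and projects
  waters back to rigidity after every accepted move.
- Velocity initialization projects Maxwell-Boltzmann draws onto the
  constraint manifold exactly: rigid-body velocities per water, iterative
  bond-direction removal for the solute, then global COM removal.

## Known limitations

- Berendsen baths do not sample a canonical ensemble, and in the
  nonequilibrium condition they hold offset steady states (above); the
  package reports measured temperatures rather than pretending the
  setpoints are met.
- The toy force field is not GROMOS 54A8; absolute energies and SASA
  values are not comparable to protein simulations.
- Desk-scale cutoffs (0.7-1.1 nm) and 50 ps trajectories; no
  twin-range cutoff, no PME, no Nose-Hoover, no anisotropic pressure
  coupling.
- `n_hb_pp` equals its backbone subset for the built-in solutes because
  toy sidechain beads carry no donors or acceptors.
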