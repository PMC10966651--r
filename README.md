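# mwmd

Nonequilibrium molecular dynamics of aqueous systems with **separate
rotational and translational solvent heat baths** — a desk-scale engine and
analysis suite for studying microwave-like heating of solvated molecules.

## The problem

Microwave radiation couples to the permanent dipole of water and pumps
energy into molecular *rotation* faster than collisions can thermalize it,
so irradiated water is rotationally hot while its translational motion and
any dissolved solute stay near the bath temperature. Simulating the
oscillating field directly is expensive and frequency-specific. The
*replacement model* implemented here represents the irradiated steady state
instead: rigid three-site (SPC) water has exactly six kinetic degrees of
freedom — three translational (centre-of-mass) and three rotational — and
each set is coupled to its own weak-coupling (Berendsen) thermostat,

    lambda_b = sqrt(1 + (dt / tau) * (T_b / T_inst,b - 1)),

with a third bath on the solute. The **microwave condition** sets the
rotational bath to 700 K with the other two at 300 K; the **equilibrium
condition** sets all three to 300 K. Comparing paired trajectories isolates
the effect of rotational excitation on solute structure and energetics:
hydrogen bonding, compactness (RMSD, RMSD100, RMSF, radius of gyration,
head-to-tail distance), solvent-accessible surface area with a
polar/nonpolar split, and the intra-solute vs solute–water decomposition of
van der Waals and electrostatic energies.

The package is for computational chemists and methods students who want a
complete, inspectable implementation at desk scale: the full pipeline —
system building, steepest-descent minimization, a staged heating/
equilibration protocol, NVT production with checkpointing, and the analysis
suite — runs on a laptop in minutes using toy peptides in a few hundred
waters.

What is under the hood: leapfrog integration (2 fs), SETTLE for water and
SHAKE for solute bonds, reaction-field electrostatics (`eps_rf = 61`) with
charge-group cutoffs smoothed by a C1 switching envelope, group-wise energy
decomposition, Maxwell–Boltzmann velocity initialization projected onto the
constraint manifold, Kabsch superposition, Shrake–Rupley SASA,
a Kabsch–Sander-style secondary-structure assignment, Flyvbjerg–Petersen
block averaging, and the paired condition-ratio statistic
`(mean_MW / mean_eq) - 1`. Compiled (Rcpp) kernels drive the hot loops.

## Worked example

Drive a small water box into the microwave steady state:

```r
library(mwmd)

sys <- build_water_box(64, seed = 1)
rf  <- reaction_field_params(cutoff = 0.5)          # box is only 1.25 nm
mn  <- steepest_descent_minimize(sys, rf, energy_threshold = 0.01)
sys <- initialize_velocities(mn$system, 300, seed = 2)

mw  <- list(bath_spec("solvent_translational", 300, 0.01),
            bath_spec("solvent_rotational",    700, 0.01))
run <- run_md(sys, 10000, mw, rf, sample_every = 10)  # 20 ps

sprintf("mean T_trans = %.1f K, mean T_rot = %.1f K",
        mean(run$temperatures$T_trans), mean(run$temperatures$T_rot))
#> mean T_trans = 322.2 K, mean T_rot = 678.7 K
```

The rotational bath holds the solvent near 700 K while centre-of-mass
motion stays near 300 K — the two solvent temperature baths act on disjoint
degrees of freedom. The ~20 K offsets from the setpoints are the honest
steady state of a proportional (Berendsen) controller balancing the fast
physical rotation-to-translation heat flux at `tau = 0.01 ps`; see the
methods vignette (`vignettes/microwave-replacement-model.Rmd`) for the
analysis.

For solutes, `make_toy_solute()` builds helix-like, hairpin-like or
extended united-atom peptides, `solvate()` and `add_ions()` prepare the
box, `build_equilibration_schedule()` / `run_schedule()` execute the
staged protocol (50→300 K ladder, restraint decay from 25 MJ/(mol nm²),
the extra 700 K rotational cycle under the microwave condition — 160 ps
vs 180 ps at full scale), `run_production()` runs NVT with bit-identical
checkpoint restarts, and `analysis_summary()` computes every structural
and energetic observable with block-averaged uncertainties. A thin CLI
(`inst/scripts/mwmd`, or `mwmd_cli()`) chains
`build → minimize → equilibrate → run → analyze → compare`.

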