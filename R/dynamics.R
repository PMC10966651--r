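# Time propagation, constraints, the three-bath weak-coupling thermostat,
# global-motion removal, pressure coupling, velocity initialization and
# steepest-descent minimization.

#' Integrator parameters
#'
#' @param timestep ps (default 0.002 = 2 fs).
#' @param shake_tolerance relative geometric tolerance on constrained
#'   distances (default 1e-4).
#' @param com_removal_interval remove the net centre-of-mass motion of all
#'   atoms every this many steps (default 1000; 0 disables).
#' @param rototranslational_constraints remove the solute's net linear and
#'   angular momentum every step.
#' @return an `integrator_params` list.
#' @export
integrator_params <- function(timestep = 0.002, shake_tolerance = 1e-4,
                              com_removal_interval = 1000,
                              rototranslational_constraints = FALSE) {
  stopifnot_scalar_pos(timestep, "timestep")
  stopifnot_scalar_pos(shake_tolerance, "shake_tolerance")
  structure(list(timestep = timestep, shake_tolerance = shake_tolerance,
                 com_removal_interval = com_removal_interval,
                 rototranslational_constraints = rototranslational_constraints),
            class = "integrator_params")
}

#' Barostat parameters (isotropic Berendsen pressure coupling)
#'
#' @param target_pressure atm.
#' @param coupling_time ps.
#' @param isothermal_compressibility 1/atm; default 4.56e-5 (water-like).
#' @return a `barostat_params` list.
#' @export
barostat_params <- function(target_pressure = 1, coupling_time = 0.5,
                            isothermal_compressibility = 4.56e-5) {
  stopifnot_scalar_pos(target_pressure, "target_pressure")
  stopifnot_scalar_pos(coupling_time, "coupling_time")
  stopifnot_scalar_pos(isothermal_compressibility, "isothermal_compressibility")
  structure(list(target_pressure = target_pressure,
                 coupling_time = coupling_time,
                 isothermal_compressibility = isothermal_compressibility),
            class = "barostat_params")
}

# constraint data shared by the R-level step and the compiled driver
constraint_data <- function(topology) {
  wt <- water_triplets(topology)
  w <- spc_water()
  b <- topology$bonds
  sol <- topology$atoms$molkind == "solute"
  sb <- b[sol[b$i] & sol[b$j], , drop = FALSE]
  list(waters = wt, d_oh = w$d_oh, d_hh = w$d_hh, m_o = w$m_o, m_h = w$m_h,
       solute_cons = sb)
}

#' Apply SHAKE to a set of distance constraints
#'
#' Iterative correction of `positions_new` so that every constrained
#' distance matches its reference length within a relative tolerance,
#' using correction directions taken from the (constraint-satisfying)
#' reference positions.
#'
#' @param positions_ref reference positions (n x 3, nm) satisfying the
#'   constraints.
#' @param positions_new trial positions to correct.
#' @param bonds data.frame `i, j, r0`.
#' @param masses per-atom masses, u.
#' @param tolerance relative tolerance (default 1e-4).
#' @param max_iterations iteration budget (default 500).
#' @return corrected positions matrix.
#' @export
shake_constrain <- function(positions_ref, positions_new, bonds, masses,
                            tolerance = 1e-4, max_iterations = 500) {
  if (nrow(bonds) == 0) return(positions_new)
  res <- cpp_shake(as.matrix(positions_ref), as.matrix(positions_new),
                   matrix(as.integer(c(bonds$i, bonds$j)), ncol = 2),
                   bonds$r0, masses, tolerance, max_iterations)
  res$positions
}

#' Apply SETTLE to rigid three-site waters
#'
#' Analytic (non-iterative) reset of each water's O-H and H-H distances to
#' the rigid geometry, preserving the molecule's linear and angular
#' momentum change implied by the constraint forces. Degenerate (near
#' collinear) trial geometries fall back to an iterative SHAKE solve.
#'
#' @param positions_ref reference positions satisfying the constraints.
#' @param positions_new trial positions.
#' @param topology the system topology (waters located by molecule kind).
#' @return list with `positions` and `n_fallback` (count of degenerate
#'   molecules routed through SHAKE).
#' @export
settle_water <- function(positions_ref, positions_new, topology) {
  cd <- constraint_data(topology)
  if (nrow(cd$waters) == 0)
    return(list(positions = positions_new, n_fallback = 0L))
  res <- cpp_settle(as.matrix(positions_ref), as.matrix(positions_new),
                    cd$waters, cd$m_o, cd$m_h, cd$d_oh, cd$d_hh,
                    topology$atoms$mass)
  list(positions = res$positions, n_fallback = res$n_fallback)
}

#' One leapfrog integration step
#'
#' `v(t+dt/2) = v(t-dt/2) + F/m dt`, `x(t+dt) = x(t) + v(t+dt/2) dt`,
#' followed by constraint projection (SETTLE for waters, SHAKE for solute
#' bonds) and recomputation of the half-step velocities from the
#' constrained displacement.
#'
#' @param system an [simulation_system()].
#' @param forces n x 3 matrix, kJ mol^-1 nm^-1, current for `positions`.
#' @param params an [integrator_params()].
#' @param constrain_solute_bonds apply SHAKE to solute bonds (default TRUE,
#'   the production behaviour; set FALSE to integrate flexible bonds, e.g.
#'   when bond forces are computed explicitly).
#' @return the propagated system.
#' @export
leapfrog_step <- function(system, forces, params = integrator_params(),
                          constrain_solute_bonds = TRUE) {
  if (any(!is.finite(forces)))
    stop("propagation error: non-finite force")
  dt <- params$timestep
  m <- system$topology$atoms$mass
  v <- system$velocities + forces / m * dt
  xnew <- system$positions + v * dt
  xold <- system$positions
  cd <- constraint_data(system$topology)
  if (nrow(cd$waters) > 0)
    xnew <- settle_water(xold, xnew, system$topology)$positions
  if (constrain_solute_bonds && nrow(cd$solute_cons) > 0)
    xnew <- shake_constrain(xold, xnew, cd$solute_cons, m,
                            params$shake_tolerance)
  system$velocities <- (xnew - xold) / dt
  system$positions <- xnew
  system
}

#' Three-bath weak-coupling thermostat
#'
#' Per bath, velocities are rescaled by
#' `lambda = sqrt(1 + (dt/tau) (T_target/T_inst - 1))`. Solute atom
#' velocities scale by the solute bath's lambda. Each water velocity is
#' decomposed into its molecular centre-of-mass part and the internal
#' (rotational) remainder; the parts are scaled by the translational and
#' rotational bath lambdas respectively and recombined, so the two solvent
#' baths act on disjoint degrees of freedom. Ions follow the translational
#' bath. With a vanishing instantaneous temperature lambda is capped at
#' `lambda_max` to prevent blow-up.
#'
#' @param system an [simulation_system()].
#' @param baths list of three [bath_spec()] objects (selectors `solute`,
#'   `solvent_translational`, `solvent_rotational`).
#' @param dof a [count_dof()] result.
#' @param timestep ps.
#' @param lambda_max per-step cap on the scaling factor (default 1.25).
#' @return list with the scaled `system`, the per-bath `lambda` values and
#'   the instantaneous `temperatures` used.
#' @export
three_bath_thermostat <- function(system, baths, dof, timestep,
                                  lambda_max = 1.25) {
  sel <- vapply(baths, function(b) b$selector, "")
  get_bath <- function(s) baths[[match(s, sel)]]
  top <- system$topology
  m <- top$atoms$mass
  v <- system$velocities
  sol <- atom_indices(top, "solute")
  ion <- atom_indices(top, "ion")
  wt <- water_triplets(top)

  ke_solute <- if (length(sol)) 0.5 * sum(m[sol] * rowSums(v[sol, , drop = FALSE]^2)) else 0
  ke_ion <- if (length(ion)) 0.5 * sum(m[ion] * rowSums(v[ion, , drop = FALSE]^2)) else 0
  part <- if (nrow(wt) > 0) partition_water_kinetic(system) else list(ke_trans = 0, ke_rot = 0)

  lam <- c(solute = 1, trans = 1, rot = 1)
  temps <- c(solute = NA_real_, trans = NA_real_, rot = NA_real_)
  lam_for <- function(Tinst, bath) {
    if (Tinst <= 1e-12) return(lambda_max)
    min(sqrt(max(1 + (timestep / bath$coupling_time) *
                   (bath$target_temperature / Tinst - 1), 0)), lambda_max)
  }
  if (length(sol) && "solute" %in% sel && dof$n_dof_solute > 0) {
    temps["solute"] <- instantaneous_temperature(ke_solute, dof$n_dof_solute)
    lam["solute"] <- lam_for(temps["solute"], get_bath("solute"))
  }
  if (nrow(wt) > 0 && "solvent_translational" %in% sel) {
    nd <- dof$n_dof_solvent_trans + dof$n_dof_ion
    temps["trans"] <- instantaneous_temperature(part$ke_trans + ke_ion, nd)
    lam["trans"] <- lam_for(temps["trans"], get_bath("solvent_translational"))
  }
  if (nrow(wt) > 0 && "solvent_rotational" %in% sel) {
    temps["rot"] <- instantaneous_temperature(part$ke_rot, dof$n_dof_solvent_rot)
    lam["rot"] <- lam_for(temps["rot"], get_bath("solvent_rotational"))
  }
  if (length(sol)) v[sol, ] <- v[sol, , drop = FALSE] * lam["solute"]
  if (length(ion)) v[ion, ] <- v[ion, , drop = FALSE] * lam["trans"]
  if (nrow(wt) > 0) {
    w <- spc_water()
    M <- w$m_o + 2 * w$m_h
    for (k in seq_len(nrow(wt))) {
      io <- wt[k, 1]; i1 <- wt[k, 2]; i2 <- wt[k, 3]
      vcom <- (w$m_o * v[io, ] + w$m_h * v[i1, ] + w$m_h * v[i2, ]) / M
      for (a in c(io, i1, i2))
        v[a, ] <- lam["trans"] * vcom + lam["rot"] * (v[a, ] - vcom)
    }
  }
  system$velocities <- v
  list(system = system, lambda = lam, temperatures = temps)
}

#' Remove global motion
#'
#' `com_only` zeroes the net linear momentum of the scope;
#' `roto_translational` additionally zeroes the net angular momentum about
#' the scope's centre of mass. Both are projections, so the scope's kinetic
#' energy never increases.
#'
#' @param system an [simulation_system()].
#' @param mode `"com_only"` or `"roto_translational"`.
#' @param scope `"all"` or `"solute"`.
#' @return the corrected system.
#' @export
remove_global_motion <- function(system, mode = c("com_only", "roto_translational"),
                                 scope = c("all", "solute")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  idx <- if (scope == "all") seq_len(n_atoms(system))
         else atom_indices(system$topology, "solute")
  if (length(idx) == 0) return(system)
  m <- system$topology$atoms$mass[idx]
  v <- system$velocities[idx, , drop = FALSE]
  x <- system$positions[idx, , drop = FALSE]
  vcom <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, vcom, "-")
  if (mode == "roto_translational") {
    com <- colSums(x * m) / sum(m)
    r <- sweep(x, 2, com, "-")
    L <- colSums(m * t(apply(cbind(r, v), 1, function(z)
      pracma_cross(z[1:3], z[4:6]))))
    I <- matrix(0, 3, 3)
    for (k in seq_along(m)) {
      rk <- r[k, ]
      I <- I + m[k] * (sum(rk^2) * diag(3) - outer(rk, rk))
    }
    w <- tryCatch(solve(I, L), error = function(e) rep(0, 3))
    v <- v - t(apply(r, 1, function(rk) pracma_cross(w, rk)))
  }
  system$velocities[idx, ] <- v
  system
}

#' Isotropic Berendsen pressure coupling
#'
#' Box and molecule centres of mass are scaled by
#' `mu = (1 - (dt/tau_p) kappa_T (P_target - P_inst))^(1/3)`, clamped to
#' `[0.95, 1.05]` per step. Molecules move rigidly (their internal geometry
#' is untouched), so constraints stay satisfied.
#'
#' @param system an [simulation_system()].
#' @param pressure instantaneous pressure, atm (virial-based; see
#'   [instantaneous_pressure()]).
#' @param params a [barostat_params()].
#' @param timestep ps.
#' @return list with the scaled `system` and `mu`.
#' @export
berendsen_barostat <- function(system, pressure, params, timestep) {
  mu3 <- 1 - (timestep / params$coupling_time) *
    params$isothermal_compressibility * (params$target_pressure - pressure)
  mu <- max(0.95, min(1.05, mu3^(1 / 3)))
  top <- system$topology
  x <- system$positions
  m <- top$atoms$mass
  for (mol in split(seq_len(n_atoms(system)), top$atoms$molid)) {
    com <- colSums(x[mol, , drop = FALSE] * m[mol]) / sum(m[mol])
    x[mol, ] <- sweep(x[mol, , drop = FALSE], 2, (mu - 1) * com, "+")
  }
  system$positions <- x
  system$box <- system$box * mu
  list(system = system, mu = mu)
}

#' Virial-based instantaneous pressure
#'
#' Atomic-virial pressure `P = (2 KE + W) / (3 V)` converted to atm, where
#' `W` is the pair virial `sum r_ij . F_ij` (including constraint forces
#' when supplied by the MD driver).
#'
#' @param kinetic_energy kJ/mol (all kinetic degrees of freedom).
#' @param virial kJ/mol.
#' @param volume nm^3.
#' @return pressure, atm.
#' @export
instantaneous_pressure <- function(kinetic_energy, virial, volume) {
  (2 * kinetic_energy + virial) / (3 * volume) * .p_unit
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component Gaussian velocities at the given temperature, followed by
#' centre-of-mass motion removal and projection onto the constraint
#' manifold: each rigid water's velocities are replaced by the equivalent
#' rigid-body motion (COM velocity plus angular velocity about the COM),
#' and solute bond-direction relative velocities are iteratively removed,
#' so every constrained distance has zero time derivative.
#'
#' @param system an [simulation_system()].
#' @param temperature K.
#' @param seed integer seed (mandatory).
#' @return system with velocities set.
#' @export
initialize_velocities <- function(system, temperature, seed) {
  if (missing(seed)) stop("seed is mandatory")
  top <- system$topology
  m <- top$atoms$mass
  if (any(m <= 0)) stop("masses must be positive")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  n <- n_atoms(system)
  sigma <- sqrt(.kB * temperature / m)
  v <- matrix(rnorm(3 * n), n, 3) * sigma
  # rigid-body projection for waters: v -> vcom + omega x r
  wt <- water_triplets(top)
  x <- system$positions
  for (k in seq_len(nrow(wt))) {
    idx <- wt[k, ]
    mm <- m[idx]
    com <- colSums(x[idx, ] * mm) / sum(mm)
    vcom <- colSums(v[idx, ] * mm) / sum(mm)
    r <- sweep(x[idx, ], 2, com, "-")
    L <- colSums(mm * t(vapply(1:3, function(s)
      pracma_cross(r[s, ], v[idx[s], ] - vcom), numeric(3))))
    I <- matrix(0, 3, 3)
    for (s in 1:3)
      I <- I + mm[s] * (sum(r[s, ]^2) * diag(3) - outer(r[s, ], r[s, ]))
    # water inertia tensor is singular along no axis (planar molecule is
    # fine); still guard numerically
    w <- tryCatch(solve(I + diag(1e-12, 3), L), error = function(e) rep(0, 3))
    for (s in 1:3)
      v[idx[s], ] <- vcom + pracma_cross(w, r[s, ])
  }
  # solute constrained bonds: remove relative velocity along each bond
  cd <- constraint_data(top)
  sb <- cd$solute_cons
  if (nrow(sb) > 0) {
    for (iter in 1:50) {
      maxdev <- 0
      for (b in seq_len(nrow(sb))) {
        i <- sb$i[b]; j <- sb$j[b]
        d <- unit_vec(x[i, ] - x[j, ])
        rel <- sum((v[i, ] - v[j, ]) * d)
        maxdev <- max(maxdev, abs(rel))
        mu <- 1 / (1 / m[i] + 1 / m[j])
        v[i, ] <- v[i, ] - (mu / m[i]) * rel * d
        v[j, ] <- v[j, ] + (mu / m[j]) * rel * d
      }
      if (maxdev < 1e-12) break
    }
  }
  system$velocities <- v
  remove_global_motion(system, "com_only", "all")
}

#' Steepest-descent energy minimization
#'
#' Moves along the normalized force direction with an adaptive step: the
#' step grows by 1.2 on energy decrease and shrinks by 0.5 on increase
#' (capped at `max_step`). Stops when `|dE|` falls below the threshold or
#' the step budget is exhausted. Waters are projected back onto their
#' rigid geometry after every accepted move. Supports harmonic position
#' restraints, frozen atoms, and disabling Lennard-Jones interactions for
#' a subset of atoms (their charges are kept), the protocol used to relax
#' initially ill-placed sites.
#'
#' @param system an [simulation_system()].
#' @param rf a [reaction_field_params()].
#' @param initial_step nm (default 0.01).
#' @param max_step nm (default 0.05).
#' @param energy_threshold kJ/mol; 0.001 in vacuo, 0.01 in solvent are the
#'   conventional choices.
#' @param min_steps,max_steps step budget (defaults 100 and 1000).
#' @param restraints optional list(`atoms`, `ref`, `k` in kJ mol^-1 nm^-2).
#' @param frozen_atoms indices never moved.
#' @param lj_off_atoms indices whose LJ interactions are disabled.
#' @return list with the minimized `system`, `energy` trace, `converged`
#'   flag and `n_steps`.
#' @export
steepest_descent_minimize <- function(system, rf = reaction_field_params(),
                                      initial_step = 0.01, max_step = 0.05,
                                      energy_threshold = 0.01,
                                      min_steps = 100, max_steps = 1000,
                                      restraints = NULL, frozen_atoms = NULL,
                                      lj_off_atoms = NULL) {
  top <- system$topology
  if (!is.null(lj_off_atoms) && length(lj_off_atoms)) {
    # zero-LJ variant of the topology: point the atoms at a ghost type
    lt <- top$lj_types
    if (!"LJ0" %in% lt$type)
      lt <- rbind(lt, data.frame(type = "LJ0", c6 = 0, c12 = 0))
    top$lj_types <- lt
    top$atoms$type[lj_off_atoms] <- "LJ0"
    system$topology <- top
  }
  eval_ef <- function(sys) system_energy_forces(sys, rf, use_bond_forces = TRUE,
                                                restraints = restraints)
  ef <- eval_ef(system)
  if (!is.finite(ef$total)) stop("initial energy not finite")
  step <- initial_step
  energies <- ef$total
  converged <- FALSE
  n_done <- 0   # accepted moves
  for (it in seq_len(max_steps)) {
    f <- ef$forces
    if (!is.null(frozen_atoms)) f[frozen_atoms, ] <- 0
    fmax <- max(abs(f))
    if (fmax < 1e-12) { converged <- TRUE; break }
    dir <- f / sqrt(sum(f^2))
    trial <- system
    trial$positions <- system$positions + step * dir
    # keep waters rigid
    if (nrow(water_triplets(top)) > 0)
      trial$positions <- settle_water(system$positions, trial$positions, top)$positions
    ef_trial <- eval_ef(trial)
    if (ef_trial$total <= ef$total) {
      dE <- ef$total - ef_trial$total
      n_done <- n_done + 1
      system <- trial
      ef <- ef_trial
      energies <- c(energies, ef$total)
      step <- min(step * 1.2, max_step)
      if (dE < energy_threshold) { converged <- TRUE; break }
    } else {
      # a rejected move that would barely raise the energy means the
      # configuration is already at a minimum at this resolution
      if (ef_trial$total - ef$total < energy_threshold) { converged <- TRUE; break }
      step <- step * 0.5
      if (step < 1e-7) { converged <- FALSE; break }
    }
  }
  list(system = system, energy = energies, converged = converged,
       n_steps = n_done)
}

#' Run molecular dynamics with the three-bath thermostat
#'
#' The main propagation driver (compiled): leapfrog integration, SETTLE
#' for waters and SHAKE for solute bonds, per-step three-bath
#' weak-coupling thermostatting on the kinetic-energy partition, periodic
#' centre-of-mass motion removal, optional solute roto-translational
#' constraints, optional isotropic pressure coupling, and optional
#' harmonic position restraints.
#'
#' @param system an [simulation_system()] with initialized velocities.
#' @param n_steps number of 'timestep' steps.
#' @param baths list of up to three [bath_spec()]; omitted selectors are
#'   left uncoupled.
#' @param rf a [reaction_field_params()]; the cutoff must satisfy
#'   `box > 2 (cutoff + skin)`.
#' @param params an [integrator_params()].
#' @param restraints optional list(`atoms`, `ref`, `k` in kJ mol^-1 nm^-2).
#' @param barostat optional [barostat_params()]; NULL disables coupling.
#' @param sample_every sample temperatures/energies every this many steps.
#' @param frame_every store coordinate frames every this many steps
#'   (0 = none).
#' @param skin neighbour-list skin, nm.
#' @param nstlist neighbour-list rebuild interval, steps.
#' @param t0 time origin for reported samples, ps.
#' @param lambda_max per-step thermostat scaling cap.
#' @return list of class `mw_run`: final `system`, `temperatures`
#'   (data.frame time/T_solute/T_trans/T_rot), `energies` (data.frame with
#'   the group-wise breakdown, kinetic energy, pressure and volume),
#'   `trajectory` (an `mw_trajectory`), and thermostat/constraint event
#'   counters.
#' @export
run_md <- function(system, n_steps, baths, rf = reaction_field_params(),
                   params = integrator_params(), restraints = NULL,
                   barostat = NULL, sample_every = 10, frame_every = 0,
                   skin = 0.1, nstlist = 5, t0 = 0, lambda_max = 1.25) {
  top <- system$topology
  if (any(system$box <= 2 * (rf$cutoff + skin)))
    stop("configuration error: box edges must exceed 2 * (cutoff + skin)")
  lj <- lj_tables(top)
  cd <- constraint_data(top)
  sol <- atom_indices(top, "solute")
  ion <- atom_indices(top, "ion")
  dof <- count_dof(system,
                   com_removal = params$com_removal_interval > 0,
                   rototranslational = params$rototranslational_constraints)
  sel <- vapply(baths, function(b) b$selector, "")
  bt <- function(s) {
    k <- match(s, sel)
    if (is.na(k)) -1 else baths[[k]]$target_temperature
  }
  btau <- function(s) {
    k <- match(s, sel)
    if (is.na(k)) 1 else baths[[k]]$coupling_time
  }
  ridx <- integer(0); rref <- matrix(0, 0, 3); rk <- 0
  if (!is.null(restraints) && restraints$k > 0) {
    ridx <- as.integer(restraints$atoms); rref <- as.matrix(restraints$ref)
    rk <- restraints$k
  }
  p <- list(
    nsteps = as.integer(n_steps), dt = params$timestep,
    cutoff = rf$cutoff, rswitch = rf$rswitch %||% rf$cutoff,
    crf = rf$crf, skin = skin,
    nstlist = as.integer(nstlist),
    shake_tol = params$shake_tolerance, shake_maxit = 500L,
    bath_T = c(bt("solute"), bt("solvent_translational"), bt("solvent_rotational")),
    bath_tau = c(btau("solute"), btau("solvent_translational"), btau("solvent_rotational")),
    dof_solute = dof$n_dof_solute,
    dof_trans = dof$n_dof_solvent_trans + dof$n_dof_ion,
    dof_rot = dof$n_dof_solvent_rot,
    com_interval = as.integer(params$com_removal_interval),
    rototrans = isTRUE(params$rototranslational_constraints),
    barostat = !is.null(barostat),
    p_target = if (is.null(barostat)) 1 else barostat$target_pressure,
    p_tau = if (is.null(barostat)) 1 else barostat$coupling_time,
    p_kappa = if (is.null(barostat)) 0 else barostat$isothermal_compressibility,
    sample_every = as.integer(sample_every),
    frame_every = as.integer(frame_every),
    step_offset = as.integer(round(t0 / params$timestep)),
    t0 = t0, lambda_max = lambda_max)
  sb <- cd$solute_cons
  res <- cpp_run_md(system$positions, system$velocities, system$box,
                    top$atoms$mass, top$atoms$charge, lj$type_index,
                    lj$c6, lj$c12,
                    interaction_groups(top), energy_group_labels(top),
                    excl_matrix(top),
                    cd$waters, c(cd$d_oh, cd$d_hh, cd$m_o, cd$m_h),
                    matrix(as.integer(c(sb$i, sb$j)), ncol = 2), sb$r0,
                    angle_ijk(top), top$angles$theta0 * pi / 180, top$angles$ktheta,
                    dih_ijkl(top), as.integer(top$dihedrals$mult),
                    top$dihedrals$phi0 * pi / 180, top$dihedrals$kphi,
                    ridx, rref, rk,
                    as.integer(sol), as.integer(ion), p)
  system$positions <- res$positions
  system$velocities <- res$velocities
  system$box <- res$box
  temps <- as.data.frame(res$temp_series)
  names(temps) <- c("time", "T_solute", "T_trans", "T_rot")
  en <- as.data.frame(res$energy_series)
  names(en) <- c("time", "e_vdw_pp", "e_es_pp", "e_vdw_pw", "e_es_pw",
                 "e_vdw_ss", "e_es_ss", "e_bonded", "e_restraint",
                 "e_kinetic", "pressure", "volume", "e_potential")
  traj <- mw_trajectory(frames = res$frames, times = res$frame_times,
                        box = system$box, topology = top, energies = en)
  structure(list(system = system, temperatures = temps, energies = en,
                 trajectory = traj,
                 n_lambda_cap = res$n_lambda_cap,
                 n_settle_fallback = res$n_settle_fallback),
            class = "mw_run")
}
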