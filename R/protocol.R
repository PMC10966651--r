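# The staged equilibration schedule (heating ladder, restraint decay,
# rotational-heating cycle, roto-translational and pressure cycles) and
# the production-run driver with checkpoint/restart.

#' Simulation condition
#'
#' `equilibrium` couples all three baths to 300 K. `microwave` is the
#' replacement model for microwave irradiation: the solvent rotational
#' bath is raised to 700 K while the solute and solvent translational
#' baths stay at 300 K.
#'
#' @param name `"equilibrium"` or `"microwave"`.
#' @param tau weak-coupling relaxation time for all baths, ps
#'   (default 0.01).
#' @return a `condition_spec` list with `production_bath_targets`
#'   (solute, solvent translational, solvent rotational; K).
#' @export
condition_spec <- function(name = c("equilibrium", "microwave"), tau = 0.01) {
  name <- match.arg(name)
  targets <- if (name == "equilibrium") c(300, 300, 300) else c(300, 300, 700)
  structure(list(name = name,
                 production_bath_targets = setNames(
                   targets, c("solute", "solvent_translational", "solvent_rotational")),
                 tau = tau), class = "condition_spec")
}

baths_from_targets <- function(targets, tau) {
  list(bath_spec("solute", targets[1], tau),
       bath_spec("solvent_translational", targets[2], tau),
       bath_spec("solvent_rotational", targets[3], tau))
}

#' Build the staged equilibration schedule
#'
#' Each cycle is 20 ps (10,000 steps at 2 fs by default). The system heats
#' from 50 to 300 K in 50 K increments (six cycles, all baths equal), the
#' microwave condition adds one cycle that raises the rotational bath to
#' 700 K, then one cycle initializes solute roto-translational constraints
#' and a final cycle switches on pressure coupling to 1 atm. Totals:
#' 160 ps (equilibrium, 8 cycles) and 180 ps (microwave, 9 cycles). The
#' solute position-restraint force constant starts at 25 MJ mol^-1 nm^-2
#' and is multiplied by 0.1 each cycle; the centre of mass of all atoms is
#' removed every 1000 steps throughout.
#'
#' @param condition a [condition_spec()].
#' @param timestep ps (default 0.002).
#' @param steps_per_cycle default 10000; reduce for scaled-down runs (the
#'   reported durations scale accordingly).
#' @param restraint_start initial restraint force constant,
#'   MJ mol^-1 nm^-2.
#' @param restraint_decay per-cycle multiplier (default 0.1).
#' @return list of `schedule_cycle` lists with fields `index`, `duration`
#'   (ps), `n_steps`, `bath_targets` (K, x3), `restraint_force_constant`
#'   (MJ mol^-1 nm^-2), `rototranslational_on`, `pressure_coupling_on`.
#' @export
build_equilibration_schedule <- function(condition, timestep = 0.002,
                                         steps_per_cycle = 10000,
                                         restraint_start = 25,
                                         restraint_decay = 0.1) {
  heat <- seq(50, 300, by = 50)
  targets <- lapply(heat, function(T) c(T, T, T))
  if (condition$name == "microwave")
    targets <- c(targets, list(c(300, 300, 700)))
  prod <- unname(condition$production_bath_targets)
  targets <- c(targets, list(prod), list(prod))  # roto-trans, then pressure
  ncyc <- length(targets)
  lapply(seq_len(ncyc), function(i) {
    structure(list(
      index = i,
      duration = steps_per_cycle * timestep,
      n_steps = steps_per_cycle,
      bath_targets = targets[[i]],
      restraint_force_constant = restraint_start * restraint_decay^(i - 1),
      rototranslational_on = i == ncyc - 1,
      pressure_coupling_on = i == ncyc), class = "schedule_cycle")
  })
}

#' Total simulated time of a schedule
#' @param schedule result of [build_equilibration_schedule()].
#' @return ps.
#' @export
schedule_total_time <- function(schedule) {
  sum(vapply(schedule, function(cy) cy$duration, numeric(1)))
}

#' Execute an equilibration schedule
#'
#' Runs each cycle with its bath targets, decaying position restraints on
#' the solute, and the roto-translational / pressure-coupling flags of the
#' final cycles. Velocities are drawn at the first cycle's target
#' temperature.
#'
#' @param system a minimized, solvated system.
#' @param schedule from [build_equilibration_schedule()].
#' @param rf a [reaction_field_params()].
#' @param condition a [condition_spec()] (for tau).
#' @param seed velocity-initialization seed (mandatory).
#' @param timestep ps.
#' @param sample_every steps between samples.
#' @return list with the equilibrated `system` and `report`: one row per
#'   cycle with mean bath temperatures, restraint constant/energy, and
#'   mean pressure.
#' @export
run_schedule <- function(system, schedule, rf = reaction_field_params(),
                         condition = condition_spec("equilibrium"),
                         seed, timestep = 0.002, sample_every = 10) {
  if (missing(seed)) stop("seed is mandatory")
  system <- initialize_velocities(system, schedule[[1]]$bath_targets[1], seed)
  sol <- atom_indices(system$topology, "solute")
  ref0 <- system$positions[sol, , drop = FALSE]
  report <- list()
  t_now <- 0
  for (cy in schedule) {
    restr <- NULL
    if (length(sol) > 0 && cy$restraint_force_constant > 0)
      restr <- list(atoms = sol, ref = ref0,
                    k = cy$restraint_force_constant * 1000)
    par <- integrator_params(timestep = timestep,
                             com_removal_interval = 1000,
                             rototranslational_constraints = cy$rototranslational_on)
    bar <- if (cy$pressure_coupling_on) barostat_params() else NULL
    run <- run_md(system, cy$n_steps,
                  baths_from_targets(cy$bath_targets, condition$tau),
                  rf = rf, params = par, restraints = restr, barostat = bar,
                  sample_every = sample_every, t0 = t_now)
    if (any(!is.finite(run$system$positions)))
      stop("non-finite coordinates in equilibration cycle ", cy$index)
    system <- run$system
    t_now <- t_now + cy$duration
    report[[cy$index]] <- data.frame(
      cycle = cy$index,
      target_solute = cy$bath_targets[1],
      target_trans = cy$bath_targets[2],
      target_rot = cy$bath_targets[3],
      mean_T_solute = mean(run$temperatures$T_solute),
      mean_T_trans = mean(run$temperatures$T_trans),
      mean_T_rot = mean(run$temperatures$T_rot),
      restraint_mj = cy$restraint_force_constant,
      mean_e_restraint = mean(run$energies$e_restraint),
      mean_pressure = mean(run$energies$pressure))
  }
  list(system = system, report = do.call(rbind, report))
}

#' NVT production run with checkpointing
#'
#' Constant-volume propagation under the condition's bath targets.
#' Coordinates and the energy breakdown are recorded every
#' `report_interval` ps. When `checkpoint` is a path, the full state
#' (positions, velocities, box, segment counter) is written after every
#' segment; restarting from it continues the trajectory bit-identically,
#' because propagation is deterministic and segment boundaries align with
#' the neighbour-list rebuild schedule.
#'
#' @param system an equilibrated [simulation_system()].
#' @param condition a [condition_spec()].
#' @param duration ps (0 gives an empty trajectory).
#' @param report_interval ps between recorded frames.
#' @param rf a [reaction_field_params()].
#' @param timestep ps.
#' @param checkpoint optional checkpoint file path.
#' @param segment_ps checkpoint segment length, ps.
#' @return list with final `system`, `trajectory` ([mw_trajectory()]),
#'   `temperatures` and `energies` data frames.
#' @export
run_production <- function(system, condition, duration, report_interval = 0.2,
                           rf = reaction_field_params(), timestep = 0.002,
                           checkpoint = NULL, segment_ps = NULL) {
  frame_every <- max(1L, as.integer(round(report_interval / timestep)))
  n_total <- as.integer(round(duration / timestep))
  if (n_total == 0) {
    return(list(system = system,
                trajectory = mw_trajectory(list(), numeric(0), system$box,
                                           system$topology,
                                           empty_energy_frame()),
                temperatures = NULL, energies = empty_energy_frame()))
  }
  if (is.null(segment_ps)) segment_ps <- duration
  seg_steps <- as.integer(round(segment_ps / timestep))
  seg_steps <- max(frame_every, (seg_steps %/% frame_every) * frame_every)
  baths <- baths_from_targets(unname(condition$production_bath_targets),
                              condition$tau)
  start_step <- 0L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- readRDS(checkpoint)
    system$positions <- st$positions
    system$velocities <- st$velocities
    system$box <- st$box
    start_step <- st$step
  }
  temps <- list(); ens <- list(); frames <- list(); ftimes <- numeric(0)
  step_now <- start_step
  while (step_now < n_total) {
    nseg <- min(seg_steps, n_total - step_now)
    run <- run_md(system, nseg, baths, rf = rf,
                  params = integrator_params(timestep = timestep,
                                             com_removal_interval = 1000),
                  sample_every = 10, frame_every = frame_every,
                  t0 = step_now * timestep)
    system <- run$system
    step_now <- step_now + nseg
    temps[[length(temps) + 1]] <- run$temperatures
    ens[[length(ens) + 1]] <- run$energies
    frames <- c(frames, run$trajectory$frames)
    ftimes <- c(ftimes, run$trajectory$times)
    if (!is.null(checkpoint))
      saveRDS(list(positions = system$positions, velocities = system$velocities,
                   box = system$box, step = step_now), checkpoint)
  }
  energies <- do.call(rbind, ens)
  list(system = system,
       trajectory = mw_trajectory(frames, ftimes, system$box,
                                  system$topology, energies),
       temperatures = do.call(rbind, temps),
       energies = energies)
}

empty_energy_frame <- function() {
  data.frame(time = numeric(0), e_vdw_pp = numeric(0), e_es_pp = numeric(0),
             e_vdw_pw = numeric(0), e_es_pw = numeric(0),
             e_vdw_ss = numeric(0), e_es_ss = numeric(0),
             e_bonded = numeric(0), e_restraint = numeric(0),
             e_kinetic = numeric(0), pressure = numeric(0),
             volume = numeric(0), e_potential = numeric(0))
}
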