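# integration, constraints, thermostat, global-motion removal, barostat,
# velocity initialization, minimization

test_that("leapfrog with zero force displaces by v dt exactly", {
  atoms <- data.frame(name = "A1", type = "CT", charge = 0, mass = 12,
                      resid = 1, resname = "ALA", molid = 1, molkind = "solute")
  sys <- simulation_system(matrix(c(1, 1, 1), 1, 3), c(4, 4, 4),
                           mw_topology(atoms),
                           velocities = matrix(c(0.3, -0.1, 0.2), 1, 3))
  out <- leapfrog_step(sys, matrix(0, 1, 3))
  expect_equal(out$positions[1, ], c(1, 1, 1) + c(0.3, -0.1, 0.2) * 0.002)
})

test_that("leapfrog conserves energy for a harmonic oscillator over 1e4 steps", {
  # 1D oscillator via a single harmonic bond to a heavy anchor
  k <- 1000; m <- 1
  period <- 2 * pi * sqrt(m / k)
  dt <- period / 100
  atoms <- data.frame(name = c("A1", "A2"), type = "CT", charge = 0,
                      mass = c(1e12, m), resid = 1:2, resname = "ALA",
                      molid = 1, molkind = "solute")
  top <- mw_topology(atoms, bonds = data.frame(i = 1, j = 2, r0 = 0.2, kb = k))
  x <- rbind(c(1, 1, 1), c(1.25, 1, 1))    # stretched by 0.05
  sys <- simulation_system(x, c(4, 4, 4), top)
  par <- integrator_params(timestep = dt)
  e0 <- 0.5 * k * 0.05^2
  eh <- numeric(10000)
  for (s in 1:10000) {
    bf <- bonded_energy_forces(sys)
    sys <- leapfrog_step(sys, bf$forces, par, constrain_solute_bonds = FALSE)
    ke <- 0.5 * m * sum(sys$velocities[2, ]^2)
    eh[s] <- bonded_energy_forces(sys)$energy + ke
  }
  # the half-step energy oscillates at O((w dt)^2) but must not drift:
  # linear trend over the whole run below 0.1% of the initial energy
  trend <- coef(lm(eh ~ seq_along(eh)))[2] * length(eh)
  expect_lt(abs(trend) / e0, 0.001)
  # half-step KE oscillates with relative amplitude ~ w dt / 2
  wdt <- 2 * pi / 100
  expect_lt((max(eh) - min(eh)) / e0, 1.5 * wdt)
})

test_that("SHAKE restores a stretched diatomic to tolerance and leaves satisfied constraints alone", {
  atoms <- data.frame(name = c("A1", "A2"), type = "CT", charge = 0, mass = 12,
                      resid = 1:2, resname = "ALA", molid = 1, molkind = "solute")
  bonds <- data.frame(i = 1, j = 2, r0 = 0.15)
  ref <- rbind(c(1, 1, 1), c(1.15, 1, 1))
  out0 <- shake_constrain(ref, ref, bonds, c(12, 12))
  expect_equal(out0, ref)
  stretched <- rbind(c(1, 1, 1), c(1.1515, 1, 1))  # +1%
  out <- shake_constrain(ref, stretched, bonds, c(12, 12), tolerance = 1e-4)
  d <- sqrt(sum((out[1, ] - out[2, ])^2))
  expect_lt(abs(d - 0.15) / 0.15, 1e-4)
})

test_that("SHAKE on a perturbed chain matches a direct Lagrange-multiplier solve", {
  set.seed(55)
  n <- 11
  ref <- cbind(cumsum(c(0, rep(0.15, n - 1))), 0, 0) +
    matrix(rnorm(3 * n, 0, 0.01), n, 3)
  bonds <- data.frame(i = 1:(n - 1), j = 2:n,
                      r0 = sqrt(rowSums((ref[-n, ] - ref[-1, ])^2)))
  m <- runif(n, 5, 20)
  trial <- ref + matrix(rnorm(3 * n, 0, 0.004), n, 3)
  got <- shake_constrain(ref, trial, bonds, m, tolerance = 1e-10,
                         max_iterations = 10000)
  # oracle: Newton iteration on the multiplier equations
  # x = trial + sum_k g_k (1/m) (d r_k / d x) with directions from ref
  nb <- nrow(bonds)
  g <- rep(0, nb)
  dref <- ref[bonds$i, ] - ref[bonds$j, ]
  for (iter in 1:200) {
    x <- trial
    for (k in 1:nb) {
      x[bonds$i[k], ] <- x[bonds$i[k], ] - g[k] * dref[k, ] / m[bonds$i[k]]
      x[bonds$j[k], ] <- x[bonds$j[k], ] + g[k] * dref[k, ] / m[bonds$j[k]]
    }
    cons <- rowSums((x[bonds$i, ] - x[bonds$j, ])^2) - bonds$r0^2
    if (max(abs(cons)) < 1e-14) break
    J <- matrix(0, nb, nb)
    for (k in 1:nb) for (l in 1:nb) {
      dxk <- x[bonds$i[k], ] - x[bonds$j[k], ]
      dd <- rep(0, 3)
      if (bonds$i[l] == bonds$i[k]) dd <- dd - dref[l, ] / m[bonds$i[k]]
      if (bonds$j[l] == bonds$i[k]) dd <- dd + dref[l, ] / m[bonds$i[k]]
      di <- dd
      dd <- rep(0, 3)
      if (bonds$i[l] == bonds$j[k]) dd <- dd - dref[l, ] / m[bonds$j[k]]
      if (bonds$j[l] == bonds$j[k]) dd <- dd + dref[l, ] / m[bonds$j[k]]
      J[k, l] <- 2 * sum(dxk * (di - dd))
    }
    g <- g - solve(J, cons)
  }
  oracle <- trial
  for (k in 1:nb) {
    oracle[bonds$i[k], ] <- oracle[bonds$i[k], ] - g[k] * dref[k, ] / m[bonds$i[k]]
    oracle[bonds$j[k], ] <- oracle[bonds$j[k], ] + g[k] * dref[k, ] / m[bonds$j[k]]
  }
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("SETTLE is exact, agrees with converged SHAKE, and conserves molecular momentum", {
  w <- spc_water()
  sys <- build_water_box(64, seed = 61)
  set.seed(62)
  pert <- sys$positions + matrix(rnorm(length(sys$positions), 0, 0.004), ncol = 3)
  st <- settle_water(sys$positions, pert, sys$topology)
  expect_equal(st$n_fallback, 0)
  wt <- mwmd:::water_triplets(sys$topology)
  doh1 <- sqrt(rowSums((st$positions[wt[, 1], ] - st$positions[wt[, 2], ])^2))
  doh2 <- sqrt(rowSums((st$positions[wt[, 1], ] - st$positions[wt[, 3], ])^2))
  dhh <- sqrt(rowSums((st$positions[wt[, 2], ] - st$positions[wt[, 3], ])^2))
  expect_lt(max(abs(doh1 - w$d_oh), abs(doh2 - w$d_oh)), 1e-8)
  expect_lt(max(abs(dhh - w$d_hh)), 1e-8)
  # SHAKE oracle on the same three constraints
  cd <- mwmd:::constraint_data(sys$topology)
  bonds <- data.frame(i = c(wt[, 1], wt[, 1], wt[, 2]),
                      j = c(wt[, 2], wt[, 3], wt[, 3]),
                      r0 = rep(c(w$d_oh, w$d_oh, w$d_hh), each = nrow(wt)))
  sh <- shake_constrain(sys$positions, pert, bonds, sys$topology$atoms$mass,
                        tolerance = 1e-12, max_iterations = 50000)
  expect_lt(max(abs(st$positions - sh)), 1e-6)
  # constraint forces are internal: molecular COM of the trial is preserved
  m <- sys$topology$atoms$mass
  for (k in sample(nrow(wt), 10)) {
    idx <- wt[k, ]
    com_trial <- colSums(pert[idx, ] * m[idx]) / sum(m[idx])
    com_set <- colSums(st$positions[idx, ] * m[idx]) / sum(m[idx])
    expect_lt(max(abs(com_trial - com_set)), 1e-8)
  }
  # rigid-body translation is a fixed point
  shift <- sweep(sys$positions, 2, c(0.3, -0.2, 0.1), "+")
  st2 <- settle_water(sys$positions, shift, sys$topology)
  expect_lt(max(abs(st2$positions - shift)), 1e-10)
})

test_that("thermostat leaves velocities alone at target and scales by sqrt(2) when T = T0/2", {
  sys <- build_water_box(27, seed = 71)
  sys <- initialize_velocities(sys, 300, seed = 72)
  d <- count_dof(sys)
  pk <- partition_water_kinetic(sys)
  t_tr <- instantaneous_temperature(pk$ke_trans, d$n_dof_solvent_trans)
  t_rot <- instantaneous_temperature(pk$ke_rot, d$n_dof_solvent_rot)
  baths <- list(bath_spec("solvent_translational", t_tr, 0.01),
                bath_spec("solvent_rotational", t_rot, 0.01))
  out <- three_bath_thermostat(sys, baths, d, 0.002)
  expect_equal(unname(out$lambda["trans"]), 1, tolerance = 1e-12)
  expect_equal(unname(out$lambda["rot"]), 1, tolerance = 1e-12)
  expect_equal(out$system$velocities, sys$velocities, tolerance = 1e-12)
  # dt = tau, T_inst = T_target/2 -> lambda = sqrt(2) (capped at lambda_max)
  baths2 <- list(bath_spec("solvent_translational", 2 * t_tr, 0.002),
                 bath_spec("solvent_rotational", t_rot, 0.01))
  out2 <- three_bath_thermostat(sys, baths2, d, 0.002, lambda_max = 2)
  expect_equal(unname(out2$lambda["trans"]), sqrt(2), tolerance = 1e-10)
})

test_that("thermostat scaling moves both solvent temperatures toward their targets
           and leaves water COM velocities untouched by the rotational bath", {
  sys <- build_water_box(27, seed = 73)
  sys <- initialize_velocities(sys, 300, seed = 74)
  d <- count_dof(sys)
  baths <- list(bath_spec("solvent_translational", 300, 0.01),
                bath_spec("solvent_rotational", 700, 0.01))
  pk0 <- partition_water_kinetic(sys)
  t0 <- c(instantaneous_temperature(pk0$ke_trans, d$n_dof_solvent_trans),
          instantaneous_temperature(pk0$ke_rot, d$n_dof_solvent_rot))
  out <- three_bath_thermostat(sys, baths, d, 0.002)
  pk1 <- partition_water_kinetic(out$system)
  t1 <- c(instantaneous_temperature(pk1$ke_trans, d$n_dof_solvent_trans),
          instantaneous_temperature(pk1$ke_rot, d$n_dof_solvent_rot))
  expect_lte(abs(t1[1] - 300), abs(t0[1] - 300))
  expect_lt(abs(t1[2] - 700), abs(t0[2] - 700))
  # rotational-only scaling preserves each COM velocity exactly
  baths_rot <- list(bath_spec("solvent_rotational", 700, 0.01))
  out2 <- three_bath_thermostat(sys, baths_rot, d, 0.002)
  wt <- mwmd:::water_triplets(sys$topology)
  m <- sys$topology$atoms$mass
  for (k in 1:5) {
    idx <- wt[k, ]
    v0 <- colSums(sys$velocities[idx, ] * m[idx]) / sum(m[idx])
    v1 <- colSums(out2$system$velocities[idx, ] * m[idx]) / sum(m[idx])
    expect_equal(v1, v0, tolerance = 1e-12)
  }
})

test_that("global motion removal zeroes momenta and never increases kinetic energy", {
  sys <- build_water_box(27, seed = 81)
  set.seed(82)
  sys$velocities <- matrix(rnorm(243, 0, 0.4), ncol = 3)
  drift <- c(0.5, -0.3, 0.1)
  sys$velocities <- sweep(sys$velocities, 2, drift, "+")
  m <- sys$topology$atoms$mass
  out <- remove_global_motion(sys, "com_only", "all")
  expect_lt(max(abs(colSums(out$velocities * m))), 1e-9)
  ke0 <- 0.5 * sum(m * rowSums(sys$velocities^2))
  ke1 <- 0.5 * sum(m * rowSums(out$velocities^2))
  expect_lte(ke1, ke0)
  # rigidly rotating solute: roto-translational removal kills all motion
  pep <- make_toy_solute("extended", 4, seed = 83)
  mm <- pep$topology$atoms$mass
  com <- colSums(pep$positions * mm) / sum(mm)
  w <- c(1, 2, -1)
  pep$velocities <- t(apply(pep$positions, 1, function(x)
    mwmd:::pracma_cross(w, x - com)))
  out2 <- remove_global_motion(pep, "roto_translational", "solute")
  L <- colSums(mm * t(apply(cbind(sweep(out2$positions, 2, com), out2$velocities),
                            1, function(z) mwmd:::pracma_cross(z[1:3], z[4:6]))))
  expect_lt(max(abs(L)), 1e-10)
  expect_lt(max(abs(out2$velocities)), 1e-10)
})

test_that("Berendsen barostat scales in the right direction and respects the clamp", {
  sys <- build_water_box(8, seed = 91)
  par <- barostat_params(target_pressure = 1, coupling_time = 0.5)
  out_eq <- berendsen_barostat(sys, 1, par, 0.002)
  expect_equal(out_eq$mu, 1)
  expect_equal(out_eq$system$box, sys$box)
  out_hi <- berendsen_barostat(sys, 5000, par, 0.002)
  expect_gt(out_hi$mu, 1)
  out_lo <- berendsen_barostat(sys, -5000, par, 0.002)
  expect_lt(out_lo$mu, 1)
  out_clamp <- berendsen_barostat(sys, 1e12, par, 0.002)
  expect_equal(out_clamp$mu, 1.05)
  # molecule geometry untouched by scaling
  wt <- mwmd:::water_triplets(sys$topology)
  d0 <- sqrt(sum((sys$positions[wt[1, 1], ] - sys$positions[wt[1, 2], ])^2))
  d1 <- sqrt(sum((out_hi$system$positions[wt[1, 1], ] -
                    out_hi$system$positions[wt[1, 2], ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("velocity initialization is seed-deterministic, hits the temperature,
           and leaves constrained distances stationary", {
  sys <- build_water_box(216, seed = 95)
  a <- initialize_velocities(sys, 300, seed = 96)
  b <- initialize_velocities(sys, 300, seed = 96)
  expect_identical(a$velocities, b$velocities)
  pk <- partition_water_kinetic(a)
  d <- count_dof(a)
  t_all <- instantaneous_temperature(pk$ke_trans + pk$ke_rot,
                                     d$n_dof_solvent_trans + d$n_dof_solvent_rot)
  # instantaneous T of one draw: sd(T)/T = sqrt(2/1296) ~ 3.9%; allow 4 sd
  expect_lt(abs(t_all - 300) / 300, 0.16)
  # d/dt of every constrained distance is zero
  wt <- mwmd:::water_triplets(a$topology)
  pairs <- rbind(cbind(wt[, 1], wt[, 2]), cbind(wt[, 1], wt[, 3]),
                 cbind(wt[, 2], wt[, 3]))
  dx <- a$positions[pairs[, 1], ] - a$positions[pairs[, 2], ]
  dv <- a$velocities[pairs[, 1], ] - a$velocities[pairs[, 2], ]
  expect_lt(max(abs(rowSums(dx * dv))), 1e-10)
})

test_that("velocity initialization reaches the target within sampling error at 1000 waters", {
  sys <- build_water_box(1000, seed = 97)
  sys <- initialize_velocities(sys, 300, seed = 98)
  pk <- partition_water_kinetic(sys)
  d <- count_dof(sys)
  t_all <- instantaneous_temperature(pk$ke_trans + pk$ke_rot,
                                     d$n_dof_solvent_trans + d$n_dof_solvent_rot)
  expect_lt(abs(t_all - 300) / 300, 0.03)
})

test_that("steepest descent: converges on an LJ dimer and descends monotonically", {
  lt <- default_lj_types()
  c6 <- lt$c6[lt$type == "CT"]; c12 <- lt$c12[lt$type == "CT"]
  rmin <- (2 * c12 / c6)^(1 / 6)
  atoms <- data.frame(name = c("A1", "A2"), type = "CT", charge = 0, mass = 12,
                      resid = 1:2, resname = "ALA", molid = 1:2,
                      molkind = "solute")
  sys <- simulation_system(rbind(c(1, 1, 1), c(1 + 1.5 * rmin, 1, 1)),
                           c(6, 6, 6), mw_topology(atoms))
  rf <- reaction_field_params(cutoff = 1.4, switch_width = 0)
  res <- steepest_descent_minimize(sys, rf, energy_threshold = 1e-8)
  r_final <- sqrt(sum((res$system$positions[1, ] - res$system$positions[2, ])^2))
  expect_lt(abs(r_final - rmin), 1e-3)
  expect_true(all(diff(res$energy) <= 0))
  # already at the minimum: no accepted moves, coordinates unchanged
  res2 <- steepest_descent_minimize(res$system, rf, energy_threshold = 1e-6)
  expect_lte(res2$n_steps, 1)
  expect_lt(max(abs(res2$system$positions - res$system$positions)), 0.02)
  expect_true(res2$converged)
})
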