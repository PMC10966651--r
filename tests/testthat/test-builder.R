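# water boxes, solvation, ion placement, toy solutes, position restraints

test_that("water box: lattice arithmetic, determinism and O-O spacing", {
  sys <- build_water_box(8, target_density = 970, seed = 1)
  vol_w <- 18.0154 * 1.66054 / 970
  expect_equal(sys$box, rep((8 * vol_w)^(1 / 3), 3), tolerance = 1e-10)
  sys2 <- build_water_box(8, target_density = 970, seed = 1)
  expect_identical(sys$positions, sys2$positions)
  wt <- mwmd:::water_triplets(sys$topology)
  oo <- as.matrix(dist(sys$positions[wt[, 1], ]))
  diag(oo) <- Inf
  expect_gt(min(oo), 0.24)
  expect_error(build_water_box(8, target_density = 3000, seed = 1),
               "infeasible")
})

test_that("solvation respects wall and exclusion distances and is deterministic", {
  pep <- make_toy_solute("extended", 4, seed = 7)
  spec <- solvation_spec(wall_distance = 1.2, min_solvent_distance = 0.23)
  sys <- solvate(pep, spec, seed = 8)
  expect_true(all(sys$box >= apply(pep$positions, 2, function(z) diff(range(z))) + 2.4 - 1e-9))
  # exhaustive check of the 0.23 nm exclusion
  sol <- atom_indices(sys$topology, "solute")
  wt <- mwmd:::water_triplets(sys$topology)
  centres <- t(vapply(seq_len(nrow(wt)), function(k)
    colMeans(sys$positions[wt[k, ], ]), numeric(3)))
  for (k in seq_len(nrow(wt))) {
    d <- mwmd:::min_image(sweep(sys$positions[sol, , drop = FALSE], 2,
                                centres[k, ], "-"), sys$box)
    expect_gte(min(sqrt(rowSums(d^2))), 0.23)
  }
  sys2 <- solvate(pep, spec, seed = 8)
  expect_equal(sum(sys2$topology$atoms$molkind == "water"),
               sum(sys$topology$atoms$molkind == "water"))
  expect_identical(sys$positions, sys2$positions)
})

test_that("ion counts follow the water-molarity convention and the system ends neutral", {
  pep <- make_toy_solute("helix_like", 6, seed = 11)
  sys <- solvate(pep, solvation_spec(wall_distance = 0.8), seed = 12)
  nw <- sum(sys$topology$atoms$molkind == "water") / 3
  q_sol <- round(sum(pep$topology$atoms$charge))
  spec <- ion_spec(concentration = 0.15, seed = 13)
  out <- add_ions(sys, spec)
  a <- out$topology$atoms
  n_pairs <- round(0.15 * nw / 55.345)
  n_na <- sum(a$type == "NAI"); n_cl <- sum(a$type == "CLI")
  expect_equal(n_na - n_cl, -q_sol)
  expect_true(n_na == n_pairs || n_cl == n_pairs)
  expect_equal(sum(a$charge), 0, tolerance = 1e-9)
  # every ion is beyond the exclusion distance from all solute atoms
  sol <- atom_indices(out$topology, "solute")
  for (ion in atom_indices(out$topology, "ion")) {
    d <- mwmd:::min_image(sweep(out$positions[sol, , drop = FALSE], 2,
                                out$positions[ion, ], "-"), out$box)
    expect_gt(min(sqrt(rowSums(d^2))), 0.4)
  }
})

test_that("a neutral 1000-water box at 0.15 mol/L receives 3 Na+ and 3 Cl-", {
  # round(0.15 * 1000 / 55.345) = 3 pairs under the water-molarity convention
  wb <- build_water_box(1000, seed = 61)
  out <- add_ions(wb, ion_spec(concentration = 0.15, seed = 62))
  a <- out$topology$atoms
  expect_equal(sum(a$type == "NAI"), 3)
  expect_equal(sum(a$type == "CLI"), 3)
  expect_equal(sum(a$charge), 0, tolerance = 1e-9)
  expect_equal(sum(a$molkind == "water") / 3, 994)
})

test_that("neutralization without salt adds exactly the counter charge", {
  # build a small charged solute by hand: net charge -2
  atoms <- data.frame(name = paste0("A", 1:2), type = "SBP",
                      charge = c(-1, -1), mass = 26, resid = 1:2,
                      resname = "ASP", molid = 1, molkind = "solute")
  top <- mw_topology(atoms, bonds = data.frame(i = 1, j = 2, r0 = 0.3, kb = 1e4))
  sol <- simulation_system(rbind(c(0, 0, 0), c(0.3, 0, 0)), c(2, 2, 2), top)
  sys <- solvate(sol, solvation_spec(wall_distance = 0.7), seed = 21)
  out <- add_ions(sys, ion_spec(concentration = 0, seed = 22))
  a <- out$topology$atoms
  expect_equal(sum(a$type == "NAI"), 2)
  expect_equal(sum(a$type == "CLI"), 0)
  expect_equal(sum(a$charge), 0, tolerance = 1e-9)
})

test_that("toy solutes have the expected atom/bond counts and are seed-stable", {
  pep <- make_toy_solute("extended", 5, seed = 31)
  expect_equal(nrow(pep$positions), 25)
  expect_equal(nrow(pep$topology$bonds), 24)
  pep2 <- make_toy_solute("extended", 5, seed = 31)
  expect_identical(pep$topology$atoms, pep2$topology$atoms)
  expect_identical(pep$positions, pep2$positions)
  expect_false(identical(
    make_toy_solute("extended", 5, seed = 32)$topology$atoms$charge,
    pep$topology$atoms$charge) &&
    isTRUE(all.equal(make_toy_solute("extended", 5, seed = 32)$topology$atoms,
                     pep$topology$atoms)))
  expect_false(is.na(pep$topology$head_atom))
  expect_false(is.na(pep$topology$tail_atom))
})

test_that("a helix-like chain starts with at least 4 intra-solute hydrogen bonds", {
  pep <- make_toy_solute("helix_like", 12, seed = 33)
  hb <- hbond_statistics(list(pep$positions), pep$topology)
  expect_gte(hb$n_hb_pp[1], 4)
})

test_that("helix is more compact than the extended chain of equal length", {
  h <- make_toy_solute("helix_like", 10, seed = 35)
  e <- make_toy_solute("extended", 10, seed = 35)
  expect_lt(head_to_tail(h$positions, topology = h$topology),
            head_to_tail(e$positions, topology = e$topology))
})

test_that("position restraints: energy values and finite-difference gradients", {
  pep <- make_toy_solute("extended", 3, seed = 41)
  ref <- pep$positions
  spec <- restraint_spec(25, ref[atom_indices(pep$topology, "solute"), ])
  at_ref <- position_restraint_energy_forces(pep, spec)
  expect_equal(at_ref$energy, 0)
  # single atom displaced 0.1 nm at 25 MJ/(mol nm^2): E = 0.5*25000*0.01 = 125
  disp <- pep
  disp$positions[4, ] <- disp$positions[4, ] + c(0.1, 0, 0)
  out <- position_restraint_energy_forces(disp, spec)
  expect_equal(out$energy, 125, tolerance = 1e-10)
  fd <- fd_forces(disp, function(s)
    position_restraint_energy_forces(s, spec)$energy, c(2, 4))
  expect_equal(fd, out$forces[c(2, 4), ], tolerance = 1e-6)
})
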