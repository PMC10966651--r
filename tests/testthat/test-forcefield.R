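# pair lists, reaction-field electrostatics, Lennard-Jones, bonded terms

make_point_system <- function(pos, box, charge = 0, type = "CT") {
  n <- nrow(pos)
  atoms <- data.frame(name = paste0("A", 1:n), type = type,
                      charge = charge, mass = 12, resid = 1:n,
                      resname = "ALA", molid = 1:n, molkind = "solute")
  simulation_system(pos, box, mw_topology(atoms))
}

test_that("pair list matches direct expectations in simple geometries", {
  sys <- make_point_system(rbind(c(1, 1, 1), c(2, 1, 1)), c(5, 5, 5))
  expect_equal(nrow(build_pair_list(sys, 1.4)), 1)
  expect_equal(nrow(build_pair_list(sys, 0.9)), 0)
  # periodic image: fractional positions 0.05 and 0.95 of a 3 nm edge
  sys2 <- make_point_system(rbind(c(0.15, 1, 1), c(2.85, 1, 1)), c(3, 3, 3))
  p <- build_pair_list(sys2, 1.4)
  expect_equal(nrow(p), 1)
})

test_that("pair list is rejected when the box cannot support the cutoff", {
  sys <- make_point_system(rbind(c(1, 1, 1), c(2, 1, 1)), c(2.5, 2.5, 2.5))
  expect_error(build_pair_list(sys, 1.4), "configuration error")
})

test_that("pair list equals the O(N^2) brute-force oracle on random configurations", {
  for (seed in 1:3) {
    set.seed(seed)
    pos <- matrix(runif(50 * 3, 0, 4), 50, 3)
    sys <- make_point_system(pos, c(4, 4, 4))
    got <- build_pair_list(sys, 1.4)
    want <- brute_pair_list(pos, c(4, 4, 4), 1.4, sys$topology$exclusions)
    expect_equal(unname(got), unname(want))
  }
})

test_that("reaction-field pair energy vanishes at the cutoff by construction", {
  rc <- 1.4
  sys <- make_point_system(rbind(c(1, 1, 1), c(1 + rc, 1, 1)), c(5, 5, 5),
                           charge = 1)
  rf <- reaction_field_params(cutoff = rc, epsilon_rf = 61, switch_width = 0)
  expect_equal(rf$crf, 120 / 123)
  e1 <- system_energy_forces(sys, rf)$energies$e_es_pp
  sys$positions[2, 1] <- 1 + rc - 1e-7
  e2 <- system_energy_forces(sys, rf)$energies$e_es_pp
  expect_lt(abs(e2), 1e-4)
  expect_equal(e1, 0)
})

test_that("LJ pair at its minimum has the analytic energy and zero force", {
  lt <- default_lj_types()
  c6 <- lt$c6[lt$type == "CT"]; c12 <- lt$c12[lt$type == "CT"]
  rmin <- (2 * c12 / c6)^(1 / 6)
  sys <- make_point_system(rbind(c(1, 1, 1), c(1 + rmin, 1, 1)), c(6, 6, 6))
  rf <- reaction_field_params(cutoff = 1.4, switch_width = 0)
  ef <- system_energy_forces(sys, rf)
  expect_equal(ef$energies$e_vdw_pp, -c6^2 / (4 * c12), tolerance = 1e-10)
  expect_lt(max(abs(ef$forces)), 1e-8)
})

test_that("atom overlap raises an error", {
  sys <- make_point_system(rbind(c(1, 1, 1), c(1, 1, 1 + 1e-8)), c(5, 5, 5))
  expect_error(system_energy_forces(sys, reaction_field_params(cutoff = 1)),
               "overlap")
})

test_that("nonbonded forces match central finite differences of the energy", {
  sys <- cached("ff_box", {
    s <- build_water_box(27, seed = 21)
    set.seed(22)
    s$positions <- s$positions + matrix(rnorm(243, 0, 0.002), ncol = 3)
    s
  })
  rf <- reaction_field_params(cutoff = 0.45)
  ef <- system_energy_forces(sys, rf, use_bond_forces = FALSE)
  set.seed(23)
  atoms <- sample(nrow(sys$positions), 6)
  fd <- fd_forces(sys, function(s)
    system_energy_forces(s, rf, use_bond_forces = FALSE)$total, atoms)
  for (ai in seq_along(atoms)) for (c in 1:3) {
    an <- ef$forces[atoms[ai], c]
    expect_lt(abs(fd[ai, c] - an), 1e-5 * max(abs(an), 1))
  }
})

test_that("bonded terms reproduce hand-computed energies and vanish at equilibrium", {
  pep <- make_toy_solute("extended", 4, seed = 3)
  bf <- bonded_energy_forces(pep)
  expect_lt(abs(bf$energy), 1e-9)
  expect_lt(max(abs(bf$forces)), 1e-6)
  # single bond stretched by 0.01 nm at kb = 1e5: E = 0.5*1e5*1e-4 = 5
  atoms <- data.frame(name = c("A1", "A2"), type = "CT", charge = 0, mass = 12,
                      resid = 1:2, resname = "ALA", molid = 1, molkind = "solute")
  top <- mw_topology(atoms, bonds = data.frame(i = 1, j = 2, r0 = 0.15, kb = 1e5))
  sys <- simulation_system(rbind(c(1, 1, 1), c(1.16, 1, 1)), c(4, 4, 4), top)
  expect_equal(bonded_energy_forces(sys)$energy, 5, tolerance = 1e-10)
})

test_that("bonded forces on a peptide conformation match finite differences", {
  pep <- make_toy_solute("helix_like", 5, seed = 9)
  set.seed(10)
  pep$positions <- pep$positions + matrix(rnorm(length(pep$positions), 0, 0.004),
                                          ncol = 3)
  bf <- bonded_energy_forces(pep)
  atoms <- sample(nrow(pep$positions), 6)
  fd <- fd_forces(pep, function(s) bonded_energy_forces(s)$energy, atoms)
  expect_equal(fd, bf$forces[atoms, , drop = FALSE], tolerance = 1e-5)
})

test_that("collinear angles raise a degenerate-geometry error", {
  atoms <- data.frame(name = paste0("A", 1:3), type = "CT", charge = 0,
                      mass = 12, resid = 1:3, resname = "ALA", molid = 1,
                      molkind = "solute")
  top <- mw_topology(atoms, bonds = data.frame(i = 1:2, j = 2:3, r0 = 0.15, kb = 0),
                     angles = data.frame(i = 1, j = 2, k = 3, theta0 = 109,
                                         ktheta = 400))
  sys <- simulation_system(rbind(c(1, 1, 1), c(1.15, 1, 1), c(1.3, 1, 1)),
                           c(4, 4, 4), top)
  expect_error(bonded_energy_forces(sys), "collinear")
})

test_that("net force is zero and the group decomposition sums to the total", {
  pep <- make_toy_solute("hairpin_like", 6, seed = 13)
  sys <- solvate(pep, solvation_spec(wall_distance = 0.5), seed = 14)
  rf <- reaction_field_params(cutoff = 0.7)
  ef <- system_energy_forces(sys, rf, use_bond_forces = TRUE)
  fscale <- max(abs(ef$forces))
  expect_lt(max(abs(colSums(ef$forces))) / fscale, 1e-8)
  en <- ef$energies
  expect_equal(en$e_tot_pp, en$e_vdw_pp + en$e_es_pp)
  expect_equal(en$e_tot_pw, en$e_vdw_pw + en$e_es_pw)
  expect_equal(ef$total,
               en$e_tot_pp + en$e_tot_pw + en$e_solvent_solvent + en$e_bonded_solute,
               tolerance = 1e-10)
})

test_that("topology text format round-trips", {
  pep <- make_toy_solute("helix_like", 4, seed = 17)
  path <- tempfile(fileext = ".top")
  write_topology(pep$topology, path)
  top2 <- read_topology(path)
  expect_equal(top2$atoms$charge, pep$topology$atoms$charge)
  expect_equal(top2$bonds$r0, pep$topology$bonds$r0)
  expect_equal(top2$dihedrals$phi0, pep$topology$dihedrals$phi0)
  expect_equal(unname(as.matrix(top2$exclusions)),
               unname(as.matrix(pep$topology$exclusions)))
  expect_equal(top2$head_atom, pep$topology$head_atom)
})
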