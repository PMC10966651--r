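# superposition, RMSD100, RMSF, compactness measures, hydrogen bonds,
# SASA, secondary structure, block averaging, condition comparison

rot_mat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

test_that("superposition RMSD: identity, rotated copies, and collinear rejection", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(x, x)$rmsd, 0, tolerance = 1e-12)
  R <- rot_mat(c(1, 2, 3), 1.1)
  y <- x %*% t(R) + matrix(rep(c(1, -2, 0.5), each = 10), 10, 3)
  expect_lt(superpose_rmsd(y, x)$rmsd, 1e-10)
  line <- cbind(seq_len(5), 2 * seq_len(5), -seq_len(5))
  expect_error(superpose_rmsd(line, line + 0.01), "collinear")
})

test_that("Kabsch RMSD matches a brute-force search over rotations", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  y <- x %*% t(rot_mat(c(0, 1, 1), 0.7)) + matrix(rnorm(30, 0, 0.05), 10, 3)
  got <- superpose_rmsd(y, x)$rmsd
  # oracle: minimize RMSD over Euler angles, grid start + Nelder-Mead refine
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  obj <- function(ang) {
    R <- rot_mat(c(1, 0, 0), ang[1]) %*% rot_mat(c(0, 1, 0), ang[2]) %*%
      rot_mat(c(0, 0, 1), ang[3])
    sqrt(mean(rowSums((yc %*% t(R) - xc)^2)))
  }
  best <- Inf
  for (a in seq(0, 2 * pi, length.out = 7)[-7])
    for (b in seq(0, pi, length.out = 4))
      for (g in seq(0, 2 * pi, length.out = 7)[-7]) {
        o <- optim(c(a, b, g), obj, control = list(reltol = 1e-14, maxit = 5000))
        best <- min(best, o$value)
      }
  expect_lt(abs(got - best), 1e-6)
})

test_that("RMSD after superposition never exceeds RMSD before", {
  set.seed(3)
  for (k in 1:5) {
    x <- matrix(rnorm(24), 8, 3)
    y <- x %*% t(rot_mat(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(24, 0, 0.2), 8, 3)
    before <- sqrt(mean(rowSums((y - x)^2)))
    expect_lte(superpose_rmsd(y, x)$rmsd, before + 1e-12)
  }
})

test_that("RMSD100 normalization: identity at N = 100, known value at N = 400, domain error", {
  expect_equal(rmsd100(0.27, 100), 0.27)
  expect_equal(rmsd100(0.3, 400), 0.3 / (1 + log(2)), tolerance = 1e-12)
  expect_equal(rmsd100(0, 150), 0)
  expect_warning(rmsd100(0.2, 30), "40 residues")
  expect_error(suppressWarnings(rmsd100(0.2, 5)), "denominator")
})

test_that("RMSF: zero for a static trajectory, d for two-point oscillation, sqrt(3) sigma for jitter", {
  set.seed(4)
  x <- matrix(rnorm(18), 6, 3)
  expect_error(rmsf(list(x)), "at least 2")
  expect_equal(max(rmsf(list(x, x, x))), 0, tolerance = 1e-12)
  # one atom oscillating +-d along an axis, frames pre-aligned (no fit)
  d <- 0.05
  up <- x; up[1, 1] <- x[1, 1] + d
  dn <- x; dn[1, 1] <- x[1, 1] - d
  r <- rmsf(list(up, dn, up, dn), fit_reference = x, fit = FALSE)
  expect_equal(r[1], d, tolerance = 1e-10)
  expect_equal(max(r[-1]), 0, tolerance = 1e-12)
  # isotropic Gaussian jitter: RMSF -> sigma sqrt(3)
  sigma <- 0.02
  base <- matrix(rnorm(60, 0, 3), 20, 3)
  frames <- lapply(1:2000, function(i) base + matrix(rnorm(60, 0, sigma), 20, 3))
  r2 <- rmsf(frames, fit_reference = base, fit = FALSE)
  expect_lt(abs(mean(r2) - sigma * sqrt(3)), 0.05 * sigma * sqrt(3))
})

test_that("radius of gyration: point, dumbbell and ring limits", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ring <- cbind(1.7 * cos(th), 1.7 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 1.7, tolerance = 1e-6)
})

test_that("head-to-tail distance is plain Euclidean and demands tags", {
  fr <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(head_to_tail(fr, 1, 2), 5)
  expect_equal(head_to_tail(rbind(c(1, 1, 1), c(1, 1, 1)), 1, 2), 0)
  expect_error(head_to_tail(fr), "tagged")
})

test_that("hydrogen-bond counting follows the geometric criteria", {
  # ideal linear N-H...O at 0.20 nm: counted; at 0.30 nm: not
  crit <- hbond_criteria()
  dpos <- matrix(c(0, 0, 0), 1, 3)
  hpos <- matrix(c(0.1, 0, 0), 1, 3)
  expect_equal(mwmd:::count_hb(dpos, hpos, matrix(c(0.3, 0, 0), 1, 3), crit), 1)
  expect_equal(mwmd:::count_hb(dpos, hpos, matrix(c(0.4, 0, 0), 1, 3), crit), 0)
  # 120-degree donor angle: rejected under the 135-degree default
  a120 <- hpos + 0.2 * c(cos(pi / 3), sin(pi / 3), 0)
  expect_equal(mwmd:::count_hb(dpos, hpos, matrix(a120, 1, 3), crit), 0)
})

test_that("hydrogen-bond counts match exhaustive evaluation on random frames", {
  set.seed(5)
  crit <- hbond_criteria()
  for (k in 1:3) {
    dpos <- matrix(runif(60, 0, 1.2), 20, 3)
    hpos <- dpos + matrix(rnorm(60, 0, 0.03), 20, 3)
    apos <- matrix(runif(60, 0, 1.2), 20, 3)
    got <- mwmd:::count_hb(dpos, hpos, apos, crit)
    want <- brute_hb_count(dpos, hpos, apos,
                           crit$max_h_acceptor_distance, crit$min_donor_angle)
    expect_equal(got, want)
  }
})

test_that("hydrogen-bond counts are invariant under rigid rotation and translation", {
  pep <- make_toy_solute("helix_like", 10, seed = 6)
  n0 <- hbond_statistics(list(pep$positions), pep$topology)$n_hb_pp
  R <- rot_mat(c(1, 1, 0), 0.8)
  moved <- pep$positions %*% t(R) + matrix(rep(c(1, 2, -1), each = nrow(pep$positions)),
                                           ncol = 3)
  n1 <- hbond_statistics(list(moved), pep$topology)$n_hb_pp
  expect_equal(n1, n0)
})

test_that("SASA: analytic sphere, additivity, and a two-sphere cap oracle", {
  # single sphere r = 0.15, probe 0.14: 4 pi 0.29^2
  s1 <- sasa(matrix(0, 1, 3), radii = 0.15, probe_radius = 0.14)
  expect_lt(abs(s1$total - 4 * pi * 0.29^2), 0.01 * 4 * pi * 0.29^2)
  # far-separated spheres: areas add
  s2 <- sasa(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(0.15, 0.2),
             probe_radius = 0.14)
  expect_lt(abs(s2$total - 4 * pi * (0.29^2 + 0.34^2)),
            0.01 * 4 * pi * (0.29^2 + 0.34^2))
  # overlapping spheres: spherical-cap closed form as the oracle
  r1 <- 0.15 + 0.14; r2 <- 0.18 + 0.14; d <- 0.25
  s3 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(0.15, 0.18),
             probe_radius = 0.14)
  cap_h <- function(ra, rb, dd) ra - (dd^2 + ra^2 - rb^2) / (2 * dd)
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * cap_h(r1, r2, d)
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * cap_h(r2, r1, d)
  expect_lt(abs(s3$total - (a1 + a2)), 0.01 * (a1 + a2))
  expect_error(sasa(matrix(0, 1, 3), radii = 0.15, n_points = 50), "n_points")
})

test_that("SASA polar/nonpolar classes partition the total for solute residues", {
  pep <- make_toy_solute("hairpin_like", 8, seed = 7)
  a <- pep$topology$atoms
  s <- sasa(pep$positions, atoms = a)
  expect_lt(abs(s$polar + s$nonpolar - s$total), 1e-6 * s$total)
  expect_gt(s$total, 0)
})

test_that("secondary structure: helix fixture scores helix, extended chain scores none", {
  hel <- make_toy_solute("helix_like", 14, seed = 8)
  fr <- secondary_structure_frequencies(list(hel$positions), hel$topology)
  expect_gte(fr$helix, 0.6)
  ext <- make_toy_solute("extended", 14, seed = 8)
  fe <- secondary_structure_frequencies(list(ext$positions), ext$topology)
  expect_equal(fe$helix, 0)
  expect_equal(fr$helix + fr$sheet + fr$coil, 1, tolerance = 1e-12)
  expect_equal(fe$helix + fe$sheet + fe$coil, 1, tolerance = 1e-12)
})

test_that("block averaging: constant series, iid noise, and AR(1) inflation", {
  expect_error(block_average(rep(1, 8)), "too short")
  cb <- block_average(rep(2.5, 64))
  expect_equal(cb$mean, 2.5)
  expect_equal(cb$sem, 0)
  set.seed(9)
  n <- 2^14
  iid <- rnorm(n)
  ba <- block_average(iid)
  expect_lt(abs(ba$sem - 1 / sqrt(n)) / (1 / sqrt(n)), 0.15)
  # AR(1), rho = 0.9: blocked SEM at least doubles the naive estimate
  rho <- 0.9
  ar <- numeric(n)
  eps <- rnorm(n)
  for (i in 2:n) ar[i] <- rho * ar[i - 1] + eps[i]
  bar <- block_average(ar)
  naive <- sd(ar) / sqrt(n)
  expect_gte(bar$sem, 2 * naive)
})

test_that("analysis summary assembles every observable with coherent invariants", {
  pep <- make_toy_solute("helix_like", 8, seed = 71)
  set.seed(72)
  frames <- lapply(1:20, function(i)
    pep$positions + matrix(rnorm(length(pep$positions), 0, 0.01), ncol = 3))
  en <- do.call(rbind, lapply(1:20, function(i)
    data.frame(time = i * 0.2, e_vdw_pp = rnorm(1, -50, 2),
               e_es_pp = rnorm(1, -300, 5), e_vdw_pw = rnorm(1, -80, 3),
               e_es_pw = rnorm(1, -500, 10), e_vdw_ss = 0, e_es_ss = 0,
               e_bonded = 10, e_restraint = 0, e_kinetic = 500,
               pressure = 0, volume = 8, e_potential = -900)))
  traj <- mw_trajectory(frames, en$time, c(4, 4, 4), pep$topology, en)
  s <- analysis_summary(traj, pep$topology, pep$positions)
  expect_s3_class(s, "analysis_summary")
  expect_gt(s$rmsd$mean, 0)
  expect_true(is.na(s$rmsd100$mean))   # normalization undefined at N = 8
  expect_lt(abs(s$sasa_polar$mean + s$sasa_nonpolar$mean - s$sasa_total$mean),
            1e-6 * s$sasa_total$mean)
  expect_equal(s$helix_frequency + s$sheet_frequency + s$coil_frequency, 1,
               tolerance = 1e-12)
  expect_equal(s$energy$e_tot_pw$mean,
               mean(en$e_vdw_pw) + mean(en$e_es_pw), tolerance = 1e-10)
  expect_gte(s$n_hb_pp$mean, s$n_hb_pp_backbone$mean)
  expect_equal(s$n_frames, 20)
  expect_equal(s$n_residues, 8)
})

test_that("condition comparison implements (MW/eq - 1) with per-system SEM", {
  same <- condition_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_change, 0)
  expect_equal(same$sem_change, 0)
  one <- condition_comparison(0.270, 0.240)
  expect_equal(one$mean_change, 0.240 / 0.270 - 1, tolerance = 1e-12)
  # n systems with identical change c: mean = c, SEM = 0
  eq <- c(1, 2, 4)
  mw <- eq * 0.9
  multi <- condition_comparison(eq, mw)
  expect_equal(multi$mean_change, -0.1, tolerance = 1e-12)
  expect_equal(multi$sem_change, 0, tolerance = 1e-12)
  lit <- condition_comparison(0.270, 0.240, literal_order = TRUE)
  expect_equal(lit$mean_change, 0.270 / 0.240 - 1, tolerance = 1e-12)
  expect_warning(condition_comparison(c(1, 0), c(1, 1)), "zero denominator")
})
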