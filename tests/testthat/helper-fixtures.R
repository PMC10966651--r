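# shared fixtures and independent oracles used across test files

# a single water system with prescribed velocities
one_water_system <- function(velocities = matrix(0, 3, 3)) {
  top <- mw_topology(mwmd:::water_atoms(1), mwmd:::water_bonds(1))
  pos <- mwmd:::water_template() + 1.5
  simulation_system(pos, c(3, 3, 3), top, velocities)
}

# water box cached per session (building is cheap; minimization is not)
fixture_env <- new.env()

cached <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, force(expr), fixture_env)
  get(key, fixture_env)
}

# rotational KE via the inertia-tensor route: 1/2 w' I w per molecule,
# an oracle independent of the residual-KE implementation
ke_rot_inertia_oracle <- function(system) {
  top <- system$topology
  wt <- mwmd:::water_triplets(top)
  m <- top$atoms$mass
  total <- 0
  for (k in seq_len(nrow(wt))) {
    idx <- wt[k, ]
    mm <- m[idx]
    x <- system$positions[idx, ]
    v <- system$velocities[idx, ]
    com <- colSums(x * mm) / sum(mm)
    vcom <- colSums(v * mm) / sum(mm)
    r <- sweep(x, 2, com)
    L <- c(0, 0, 0)
    I <- matrix(0, 3, 3)
    for (s in 1:3) {
      L <- L + mm[s] * mwmd:::pracma_cross(r[s, ], v[s, ] - vcom)
      I <- I + mm[s] * (sum(r[s, ]^2) * diag(3) - outer(r[s, ], r[s, ]))
    }
    w <- solve(I, L)
    total <- total + 0.5 * sum(w * (I %*% w))
  }
  total
}

# brute-force O(N^2) pair list over atoms (minimum image), excluding pairs
brute_pair_list <- function(positions, box, cutoff, exclusions) {
  n <- nrow(positions)
  ex <- paste(exclusions[, 1], exclusions[, 2])
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% ex) next
    d <- positions[i, ] - positions[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# central finite-difference forces for any scalar energy function
fd_forces <- function(system, energy_fn, atoms, h = 1e-6) {
  f <- matrix(NA_real_, length(atoms), 3)
  for (ai in seq_along(atoms)) {
    a <- atoms[ai]
    for (c in 1:3) {
      sp <- system; sp$positions[a, c] <- sp$positions[a, c] + h
      sm <- system; sm$positions[a, c] <- sm$positions[a, c] - h
      f[ai, c] <- -(energy_fn(sp) - energy_fn(sm)) / (2 * h)
    }
  }
  f
}

# exhaustive hydrogen-bond count from explicit donor/H/acceptor coordinates
brute_hb_count <- function(dpos, hpos, apos, dmax, amin) {
  n <- 0
  for (k in seq_len(nrow(hpos))) for (a in seq_len(nrow(apos))) {
    r <- sqrt(sum((apos[a, ] - hpos[k, ])^2))
    if (r > dmax || r < 1e-6) next
    v1 <- dpos[k, ] - hpos[k, ]
    v2 <- apos[a, ] - hpos[k, ]
    ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang >= amin) n <- n + 1
  }
  n
}

# a small equilibrated water box shared by dynamics tests
equilibrated_water_box <- function(n = 64, seed = 101, ps = 4) {
  cached(sprintf("wb_%d_%d_%g", n, seed, ps), {
    sys <- build_water_box(n, seed = seed)
    rf <- reaction_field_params(cutoff = min(0.8, min(sys$box) / 2 - 0.11))
    mn <- steepest_descent_minimize(sys, rf, energy_threshold = 0.01)
    sys <- initialize_velocities(mn$system, 300, seed = seed + 1)
    baths <- list(bath_spec("solvent_translational", 300, 0.01),
                  bath_spec("solvent_rotational", 300, 0.01))
    run <- run_md(sys, round(ps / 0.002), baths, rf, sample_every = 10)
    list(system = run$system, rf = rf)
  })
}
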