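# System construction: water boxes, solvation, ion placement and the
# deterministic toy peptide fixtures used in place of real proteins.

water_volume_nm3 <- function(density_kg_m3) {
  m_w <- 2 * 1.008 + 15.9994          # u
  m_w * 1.66054 / density_kg_m3       # nm^3 per molecule
}

# topology for n rigid SPC waters (optionally appended after existing atoms)
water_atoms <- function(n_waters, molid_offset = 0, resid_offset = 0) {
  w <- spc_water()
  data.frame(
    name = rep(c("OW", "HW1", "HW2"), n_waters),
    type = rep(c("OW", "HW", "HW"), n_waters),
    charge = rep(c(w$q_o, w$q_h, w$q_h), n_waters),
    mass = rep(c(w$m_o, w$m_h, w$m_h), n_waters),
    resid = rep(seq_len(n_waters) + resid_offset, each = 3),
    resname = "SOL",
    molid = rep(seq_len(n_waters) + molid_offset, each = 3),
    molkind = "water")
}

water_bonds <- function(n_waters, atom_offset = 0) {
  w <- spc_water()
  if (n_waters == 0)
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0), kb = numeric(0)))
  base <- (seq_len(n_waters) - 1) * 3 + atom_offset
  data.frame(
    i = c(base + 1, base + 1, base + 2),
    j = c(base + 2, base + 3, base + 3),
    r0 = rep(c(w$d_oh, w$d_oh, w$d_hh), each = n_waters),
    kb = 0)  # waters are rigid: bonds exist only to define constraints/exclusions
}

# coordinates of one SPC water: O at origin, molecular plane xy
water_template <- function() {
  w <- spc_water()
  ang <- 109.47 * pi / 180
  rbind(c(0, 0, 0),
        c(w$d_oh * sin(ang / 2), -w$d_oh * cos(ang / 2), 0),
        c(-w$d_oh * sin(ang / 2), -w$d_oh * cos(ang / 2), 0))
}

#' Build a box of rigid SPC water
#'
#' Waters are placed on a jittered cubic lattice with random orientations;
#' the box edge follows from the target mass density. Deterministic for a
#' given seed.
#'
#' @param n_waters number of molecules (>= 1).
#' @param target_density kg/m^3 (default 970, a typical pre-equilibration
#'   density that leaves room for lattice relaxation).
#' @param seed integer RNG seed (mandatory: every stochastic builder in the
#'   package takes one).
#' @return an [simulation_system()].
#' @export
build_water_box <- function(n_waters, target_density = 970, seed) {
  if (n_waters < 1) stop("n_waters must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  edge <- (n_waters * water_volume_nm3(target_density))^(1 / 3)
  nside <- ceiling(n_waters^(1 / 3))
  spacing <- edge / nside
  if (spacing < 0.27)
    stop("density infeasible: lattice spacing ", round(spacing, 3),
         " nm would put O-O closer than 0.24 nm")
  jitter_max <- min(0.025, (spacing - 0.25) / 2)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  tpl <- water_template()
  cells <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                 z = seq_len(nside)))[seq_len(n_waters), , drop = FALSE]
  pos <- matrix(0, 3 * n_waters, 3)
  for (w in seq_len(n_waters)) {
    centre <- (cells[w, ] - 0.5) * spacing +
      runif(3, -jitter_max, jitter_max)
    rot <- random_rotation()
    pos[(3 * w - 2):(3 * w), ] <- sweep(tpl %*% t(rot), 2, centre, "+")
  }
  top <- mw_topology(water_atoms(n_waters), water_bonds(n_waters))
  simulation_system(pos, rep(edge, 3), top)
}

# reproducible local RNG scope
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Solvation parameters
#'
#' @param wall_distance minimum solute-to-box-wall distance, nm.
#' @param min_solvent_distance minimum distance between any existing atom
#'   and the centre of geometry of an added water, nm.
#' @param target_density water density used for the fill lattice, kg/m^3.
#' @return a `solvation_spec` list.
#' @export
solvation_spec <- function(wall_distance = 1.2, min_solvent_distance = 0.23,
                           target_density = 970) {
  stopifnot_scalar_pos(wall_distance, "wall_distance")
  stopifnot_scalar_pos(min_solvent_distance, "min_solvent_distance")
  structure(list(wall_distance = wall_distance,
                 min_solvent_distance = min_solvent_distance,
                 target_density = target_density), class = "solvation_spec")
}

#' Solvate a solute in a rectangular box of SPC water
#'
#' The box extends `wall_distance` beyond the solute extent in each
#' dimension; lattice waters whose centre of geometry comes within
#' `min_solvent_distance` of any solute atom are discarded. Deterministic
#' given `(solute, spec, seed)`.
#'
#' @param solute an [simulation_system()] (typically from
#'   [make_toy_solute()]) or a list with `topology` and `positions`.
#' @param spec a [solvation_spec()].
#' @param seed integer RNG seed for lattice jitter and orientations.
#' @return a solvated [simulation_system()]; solute first, waters after.
#' @export
solvate <- function(solute, spec = solvation_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  xs <- as.matrix(solute$positions)
  stop_top <- solute$topology
  ext_lo <- apply(xs, 2, min)
  ext_hi <- apply(xs, 2, max)
  box <- (ext_hi - ext_lo) + 2 * spec$wall_distance
  # centre the solute
  shift <- box / 2 - (ext_lo + ext_hi) / 2
  xs <- sweep(xs, 2, shift, "+")
  vol_w <- water_volume_nm3(spec$target_density)
  nside <- pmax(1, floor(box / vol_w^(1 / 3)))
  spacing <- box / nside
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  # template centred on its centre of geometry, so the placed molecule's
  # geometric centre coincides with the (distance-checked) lattice point
  tpl <- water_template()
  tpl <- sweep(tpl, 2, colMeans(tpl))
  jit <- pmin(0.025, pmax((min(spacing) - 0.25) / 2, 0))
  cells <- as.matrix(expand.grid(x = seq_len(nside[1]), y = seq_len(nside[2]),
                                 z = seq_len(nside[3])))
  keep_pos <- list()
  for (w in seq_len(nrow(cells))) {
    centre <- (cells[w, ] - 0.5) * spacing + runif(3, -jit, jit)
    # minimum-image distance from water centre to all existing atoms
    d <- min_image(sweep(xs, 2, centre, "-"), box)
    if (min(sqrt(rowSums(d^2))) < spec$min_solvent_distance) next
    rot <- random_rotation()
    keep_pos[[length(keep_pos) + 1]] <- sweep(tpl %*% t(rot), 2, centre, "+")
  }
  nw <- length(keep_pos)
  if (nw == 0) stop("zero waters retained during solvation")
  ns <- nrow(xs)
  a_sol <- stop_top$atoms
  a_wat <- water_atoms(nw, molid_offset = max(a_sol$molid),
                       resid_offset = max(a_sol$resid))
  bw <- water_bonds(nw, atom_offset = ns)
  top <- mw_topology(rbind(a_sol, a_wat),
                     rbind(stop_top$bonds, bw),
                     stop_top$angles, stop_top$dihedrals,
                     head_atom = stop_top$head_atom,
                     tail_atom = stop_top$tail_atom)
  simulation_system(rbind(xs, do.call(rbind, keep_pos)), box, top)
}

#' Ion placement parameters
#'
#' @param concentration mol/L of each species (Na+ and Cl-), converted to a
#'   pair count via the pure-water molarity 55.345 mol/L:
#'   `n_pairs = round(c * N_water / 55.345)`.
#' @param exclusion_distance minimum ion-solute distance, nm.
#' @param neutralize add/remove single ions until the total system charge
#'   is exactly zero.
#' @param seed integer seed for the replacement draw.
#' @return an `ion_spec` list.
#' @export
ion_spec <- function(concentration = 0.15, exclusion_distance = 0.4,
                     neutralize = TRUE, seed = 1) {
  if (concentration < 0) stop("concentration must be >= 0")
  structure(list(concentration = concentration,
                 exclusion_distance = exclusion_distance,
                 neutralize = neutralize, seed = seed), class = "ion_spec")
}

#' Replace waters by Na+/Cl- ions at a given concentration
#'
#' Ions replace randomly chosen waters whose oxygen lies farther than
#' `exclusion_distance` from every solute atom. After placing the salt
#' pairs, single counter-ions are removed (or, if none are removable,
#' added) until the total system charge is exactly zero.
#'
#' @param system a solvated [simulation_system()].
#' @param spec an [ion_spec()].
#' @param solute_net_charge solute formal charge, e; defaults to the sum of
#'   solute partial charges rounded to the nearest integer.
#' @return an [simulation_system()] with waters replaced by ions.
#' @export
add_ions <- function(system, spec = ion_spec(), solute_net_charge = NULL) {
  top <- system$topology
  a <- top$atoms
  sol <- atom_indices(top, "solute")
  if (is.null(solute_net_charge))
    solute_net_charge <- round(sum(a$charge[sol]))
  wt <- water_triplets(top)
  nw <- nrow(wt)
  n_pairs <- round(spec$concentration * nw / 55.345)
  # eligibility: water O farther than the exclusion distance from the solute
  eligible <- seq_len(nw)
  if (length(sol) > 0) {
    xs <- system$positions[sol, , drop = FALSE]
    keep <- vapply(seq_len(nw), function(w) {
      d <- min_image(sweep(xs, 2, system$positions[wt[w, 1], ], "-"), system$box)
      min(sqrt(rowSums(d^2))) > spec$exclusion_distance
    }, logical(1))
    eligible <- which(keep)
  }
  n_na <- n_pairs
  n_cl <- n_pairs
  q <- solute_net_charge
  if (spec$neutralize && q != 0) {
    if (q > 0) {
      rem <- min(q, n_na)
      n_na <- n_na - rem
      n_cl <- n_cl + (q - rem)   # add anions if removal alone cannot balance
    } else {
      rem <- min(-q, n_cl)
      n_cl <- n_cl - rem
      n_na <- n_na + (-q - rem)
    }
  }
  n_ions <- n_na + n_cl
  if (n_ions == 0) return(system)
  if (length(eligible) < n_ions)
    stop("insufficient eligible waters for ion placement: need ", n_ions,
         ", have ", length(eligible), " (deficit ", n_ions - length(eligible), ")")
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))
  chosen <- sample(eligible, n_ions)
  kinds <- c(rep("NAI", n_na), rep("CLI", n_cl))
  # new system: drop chosen waters' H sites, convert O site to the ion
  drop_atoms <- c(wt[chosen, 2], wt[chosen, 3])
  ion_at <- wt[chosen, 1]
  a$name[ion_at] <- ifelse(kinds == "NAI", "NA", "CL")
  a$type[ion_at] <- kinds
  a$charge[ion_at] <- ifelse(kinds == "NAI", 1, -1)
  a$mass[ion_at] <- ifelse(kinds == "NAI", 22.9898, 35.453)
  a$molkind[ion_at] <- "ion"
  a$resname[ion_at] <- ifelse(kinds == "NAI", "NA", "CL")
  keep <- setdiff(seq_len(nrow(a)), drop_atoms)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  b <- top$bonds
  bkeep <- b$i %in% keep & b$j %in% keep & !(b$i %in% ion_at) & !(b$j %in% ion_at)
  b <- b[bkeep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  ang <- top$angles
  if (nrow(ang)) { ang$i <- remap[ang$i]; ang$j <- remap[ang$j]; ang$k <- remap[ang$k] }
  dih <- top$dihedrals
  if (nrow(dih)) { dih$i <- remap[dih$i]; dih$j <- remap[dih$j]
                   dih$k <- remap[dih$k]; dih$l <- remap[dih$l] }
  newtop <- mw_topology(a[keep, , drop = FALSE], b, ang, dih,
                        head_atom = if (is.na(top$head_atom)) NA_integer_ else remap[top$head_atom],
                        tail_atom = if (is.na(top$tail_atom)) NA_integer_ else remap[top$tail_atom])
  total_q <- sum(newtop$atoms$charge)
  if (spec$neutralize && abs(total_q) > 1e-9)
    stop("internal error: system not neutral after ion placement")
  simulation_system(system$positions[keep, , drop = FALSE], system$box, newtop,
                    system$velocities[keep, , drop = FALSE])
}

#' Generate a toy peptide solute
#'
#' Deterministic united-atom chains standing in for real proteins at desk
#' scale. Each residue carries backbone sites N, CA, C, O plus one
#' sidechain bead CB; a seed-controlled fraction of beads is charged
#' (+-1 e, Lys/Asp-like) and the rest neutral. The first and last backbone
#' atoms are tagged for head-to-tail analysis. `helix_like` chains are
#' built at ideal alpha-helical backbone dihedrals so that i -> i+4
#' carbonyl-amide contacts are in hydrogen-bonding range; `hairpin_like`
#' makes two antiparallel strands with a turn; `extended` is a straight
#' beta-like strand.
#'
#' @param kind `"helix_like"`, `"hairpin_like"` or `"extended"`.
#' @param n_residues 3 to 60.
#' @param seed integer seed controlling the charged/neutral bead mix.
#' @return an [simulation_system()] in a loose bounding box (solvate before
#'   running dynamics).
#' @export
make_toy_solute <- function(kind = c("helix_like", "hairpin_like", "extended"),
                            n_residues, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is mandatory")
  if (n_residues < 3 || n_residues > 60) stop("n_residues must be in [3, 60]")
  phi_psi <- switch(kind,
    helix_like = c(-57, -47),
    extended = c(-139, 135),
    hairpin_like = c(-139, 135))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  # seed-controlled bead charges: ~25% charged, alternating sign
  charged <- runif(n_residues) < 0.25
  sgn <- rep(c(1, -1), length.out = sum(charged))
  cb_charge <- numeric(n_residues)
  cb_charge[charged] <- sgn
  resnames <- ifelse(cb_charge > 0, "LYS", ifelse(cb_charge < 0, "ASP",
    rep(c("ALA", "SER"), length.out = n_residues)))

  b_nca <- 0.147; b_cac <- 0.153; b_cn <- 0.133; b_co <- 0.123; b_cacb <- 0.153
  a_ncac <- 110; a_cacn <- 114; a_cnca <- 121
  nres <- n_residues
  pos <- list()
  # first residue placed by hand
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(b_nca, 0, 0)
  pos[["C1"]] <- pos[["CA1"]] + b_cac * c(cos((180 - a_ncac) * pi / 180),
                                          sin((180 - a_ncac) * pi / 180), 0)
  phi <- phi_psi[1]; psi <- phi_psi[2]
  for (r in 2:nres) {
    # hairpin: invert sense in second half via a turn
    if (kind == "hairpin_like") {
      half <- ceiling(nres / 2)
      if (r == half + 1) { phi <- -60; psi <- -30 }        # turn residue
      else if (r == half + 2) { phi <- -90; psi <- 0 }
      else { phi <- phi_psi[1]; psi <- phi_psi[2] }
    }
    pN <- place_atom(pos[[paste0("N", r - 1)]], pos[[paste0("CA", r - 1)]],
                     pos[[paste0("C", r - 1)]], b_cn, a_cacn, psi)
    pCA <- place_atom(pos[[paste0("CA", r - 1)]], pos[[paste0("C", r - 1)]],
                      pN, b_nca, a_cnca, 180)               # omega trans
    pC <- place_atom(pos[[paste0("C", r - 1)]], pN, pCA, b_cac, a_ncac, phi)
    pos[[paste0("N", r)]] <- pN
    pos[[paste0("CA", r)]] <- pCA
    pos[[paste0("C", r)]] <- pC
  }
  # carbonyl O: sp2 C, in the CA-C-N(next) plane opposite the bisector;
  # last residue O placed by psi dihedral
  for (r in seq_len(nres)) {
    pC <- pos[[paste0("C", r)]]
    pCA <- pos[[paste0("CA", r)]]
    if (r < nres) {
      pN1 <- pos[[paste0("N", r + 1)]]
      d <- -(unit_vec(pCA - pC) + unit_vec(pN1 - pC))
      pos[[paste0("O", r)]] <- pC + b_co * unit_vec(d)
    } else {
      pos[[paste0("O", r)]] <- place_atom(pos[[paste0("N", r)]], pCA, pC,
                                          b_co, 121, psi + 180)
    }
    # CB bead bonded to CA: angle C-CA-CB ~110, dihedral N-C-CA-CB
    pN <- pos[[paste0("N", r)]]
    pos[[paste0("CB", r)]] <- place_atom(pN, pC, pCA, b_cacb, 110, 122)
  }
  roles <- c("N", "CA", "C", "O", "CB")
  atom_names <- as.vector(t(outer(seq_len(nres), roles,
                                  function(r, a) paste0(a, r))))
  coords <- do.call(rbind, pos[atom_names])
  nm <- rep(roles, nres)
  types <- rep(c("NT", "CT", "CT", "OT", "SB"), nres)
  types[seq(5, 5 * nres, by = 5)] <- ifelse(cb_charge != 0, "SBP", "SB")
  charges <- as.vector(vapply(seq_len(nres), function(r)
    c(0.31, -0.31, 0.45, -0.45, cb_charge[r]), numeric(5)))
  masses <- rep(c(15.0147, 13.019, 12.011, 15.9994, 26), nres)
  atoms <- data.frame(
    name = nm, type = types, charge = charges, mass = masses,
    resid = rep(seq_len(nres), each = 5),
    resname = rep(resnames, each = 5),
    molid = 1L, molkind = "solute")
  idx <- function(role, r) (r - 1) * 5 + match(role, roles)
  bonds <- list()
  addb <- function(i, j, r0) bonds[[length(bonds) + 1]] <<- c(i, j, r0)
  for (r in seq_len(nres)) {
    addb(idx("N", r), idx("CA", r), b_nca)
    addb(idx("CA", r), idx("C", r), b_cac)
    addb(idx("C", r), idx("O", r), b_co)
    addb(idx("CA", r), idx("CB", r), b_cacb)
    if (r < nres) addb(idx("C", r), idx("N", r + 1), b_cn)
  }
  bonds <- do.call(rbind, bonds)
  bonds <- data.frame(i = bonds[, 1], j = bonds[, 2], r0 = bonds[, 3],
                      kb = 3e5)
  # angles/dihedrals take their equilibrium values from the constructed
  # geometry, so each fixture starts at a bonded-energy minimum
  angles <- make_angles_from_bonds(bonds, coords, ktheta = 450)
  dihedrals <- backbone_dihedrals(nres, idx, coords, kphi = 5)
  top <- mw_topology(atoms, bonds, angles, dihedrals,
                     head_atom = idx("N", 1), tail_atom = idx("C", nres))
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  box <- pmax(hi - lo, 1) + 3
  simulation_system(sweep(coords, 2, -lo + 1.5, "+"), box, top)
}

# all bonded triplets, theta0 from current geometry
make_angles_from_bonds <- function(bonds, coords, ktheta) {
  n <- nrow(coords)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  out <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; l <- cmb[2, k]
      v1 <- coords[i, ] - coords[j, ]; v2 <- coords[l, ] - coords[j, ]
      th <- acos(max(-1, min(1, sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2)))))
      out[[length(out) + 1]] <- data.frame(i = i, j = j, k = l,
                                           theta0 = th * 180 / pi,
                                           ktheta = ktheta)
    }
  }
  do.call(rbind, out)
}

# phi/psi/omega dihedrals, phase set so the built geometry is a minimum
backbone_dihedrals <- function(nres, idx, coords, kphi) {
  quad <- list()
  for (r in seq_len(nres)) {
    if (r > 1) quad[[length(quad) + 1]] <- c(idx("C", r - 1), idx("N", r),
                                             idx("CA", r), idx("C", r))  # phi
    if (r < nres) {
      quad[[length(quad) + 1]] <- c(idx("N", r), idx("CA", r), idx("C", r),
                                    idx("N", r + 1))                      # psi
      quad[[length(quad) + 1]] <- c(idx("CA", r), idx("C", r), idx("N", r + 1),
                                    idx("CA", r + 1))                     # omega
    }
  }
  if (length(quad) == 0)
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      l = integer(0), mult = integer(0), phi0 = numeric(0),
                      kphi = numeric(0)))
  q <- do.call(rbind, quad)
  phi0 <- vapply(seq_len(nrow(q)), function(k) {
    d <- dihedral_angle(coords[q[k, 1], ], coords[q[k, 2], ],
                        coords[q[k, 3], ], coords[q[k, 4], ])
    (d * 180 / pi + 180) %% 360   # minimum of k(1+cos(phi - phi0)) at phi0-180
  }, numeric(1))
  data.frame(i = q[, 1], j = q[, 2], k = q[, 3], l = q[, 4],
             mult = 1L, phi0 = phi0, kphi = kphi)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  atan2(vec_norm(b2) * sum(b1 * pracma_cross(b2, b3)),
        sum(pracma_cross(b1, b2) * pracma_cross(b2, b3)))
}

#' Harmonic position restraint parameters
#'
#' @param force_constant MJ mol^-1 nm^-2 (the conventional unit for strong
#'   solute restraints during solvent relaxation; multiplied by 1000
#'   internally to kJ).
#' @param attachment reference positions (n x 3, nm).
#' @return a `restraint_spec` list.
#' @export
restraint_spec <- function(force_constant, attachment) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  structure(list(force_constant = force_constant,
                 attachment = as.matrix(attachment)), class = "restraint_spec")
}

#' Position-restraint energy and forces
#'
#' `E = sum 0.5 k |x - x_ref|^2` over restrained atoms, with `k` given in
#' MJ mol^-1 nm^-2.
#'
#' @param system an [simulation_system()].
#' @param spec a [restraint_spec()]; `attachment` must have one row per
#'   restrained atom.
#' @param atoms indices of restrained atoms; defaults to all solute atoms.
#' @return list with `energy` (kJ/mol) and `forces` (n x 3).
#' @export
position_restraint_energy_forces <- function(system, spec,
                                             atoms = atom_indices(system$topology, "solute")) {
  k <- spec$force_constant * 1000   # MJ -> kJ
  ref <- spec$attachment
  if (nrow(ref) != length(atoms))
    stop("reference positions must match restrained atom count")
  d <- system$positions[atoms, , drop = FALSE] - ref
  e <- 0.5 * k * sum(d^2)
  f <- matrix(0, n_atoms(system), 3)
  f[atoms, ] <- -k * d
  list(energy = e, forces = f)
}
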