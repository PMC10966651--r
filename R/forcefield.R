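# Topology container, Lennard-Jones tables, reaction-field electrostatics
# and the wrappers around the compiled nonbonded/bonded kernels.

#' Default Lennard-Jones type table
#'
#' C6/C12 parameters (kJ mol^-1 nm^6 and kJ mol^-1 nm^12) for the site
#' types used by the builders. Water uses canonical SPC values (LJ on
#' oxygen only); solute bead and ion parameters are a fixed toy
#' parameterization versioned here.
#'
#' @return data.frame with columns `type`, `c6`, `c12`.
#' @export
default_lj_types <- function() {
  se <- rbind(
    OW  = c(0.3166, 0.650),   # SPC oxygen
    HW  = c(0.0,    0.0),     # SPC hydrogen: no LJ
    NT  = c(0.325,  0.450),   # backbone united N(H)
    CT  = c(0.336,  0.400),   # backbone CA / carbonyl C
    OT  = c(0.300,  0.600),   # carbonyl O
    SB  = c(0.400,  0.500),   # neutral sidechain bead
    SBP = c(0.400,  0.500),   # charged sidechain bead (+-1 e)
    NAI = c(0.260,  0.062),   # Na+ (toy)
    CLI = c(0.440,  0.450)    # Cl- (toy)
  )
  data.frame(type = rownames(se),
             c6 = ifelse(se[, 1] > 0, 4 * se[, 2] * se[, 1]^6, 0),
             c12 = ifelse(se[, 1] > 0, 4 * se[, 2] * se[, 1]^12, 0),
             row.names = NULL)
}

#' Rigid SPC water parameters
#'
#' Canonical published SPC values: O charge -0.82 e, H charge +0.41 e,
#' O-H 0.1 nm, H-O-H 109.47 degrees, LJ on oxygen only.
#'
#' @return list with geometry, charges and masses.
#' @export
spc_water <- function() {
  d_oh <- 0.1
  ang <- 109.47 * pi / 180
  list(d_oh = d_oh,
       d_hh = 2 * d_oh * sin(ang / 2),
       q_o = -0.82, q_h = 0.41,
       m_o = 15.9994, m_h = 1.008)
}

#' Construct a topology
#'
#' @param atoms data.frame with columns `name`, `type` (LJ type), `charge`
#'   (e), `mass` (u), `resid`, `resname`, `molid` (molecule index) and
#'   `molkind` (`"solute"`, `"water"` or `"ion"`).
#' @param bonds data.frame `i, j, r0, kb` (nm, kJ mol^-1 nm^-2); may be empty.
#' @param angles data.frame `i, j, k, theta0, ktheta` (degrees,
#'   kJ mol^-1 rad^-2).
#' @param dihedrals data.frame `i, j, k, l, mult, phi0, kphi` (degrees,
#'   kJ/mol).
#' @param lj_types data.frame `type, c6, c12`; defaults to
#'   [default_lj_types()].
#' @param exclusions optional two-column integer matrix of excluded pairs;
#'   if `NULL`, 1-2 and 1-3 pairs are generated from the bond graph
#'   (1-4 interactions are kept at full strength).
#' @param head_atom,tail_atom optional atom indices tagged for head-to-tail
#'   analysis.
#' @return object of class `mw_topology`.
#' @export
mw_topology <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                        lj_types = default_lj_types(), exclusions = NULL,
                        head_atom = NA_integer_, tail_atom = NA_integer_) {
  atoms <- as.data.frame(atoms)
  need <- c("name", "type", "charge", "mass", "resid", "resname", "molid", "molkind")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  n <- nrow(atoms)
  empty_bonds <- data.frame(i = integer(0), j = integer(0),
                            r0 = numeric(0), kb = numeric(0))
  empty_ang <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                          theta0 = numeric(0), ktheta = numeric(0))
  empty_dih <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                          l = integer(0), mult = integer(0),
                          phi0 = numeric(0), kphi = numeric(0))
  bonds <- if (is.null(bonds) || nrow(bonds) == 0) empty_bonds else as.data.frame(bonds)
  angles <- if (is.null(angles) || nrow(angles) == 0) empty_ang else as.data.frame(angles)
  dihedrals <- if (is.null(dihedrals) || nrow(dihedrals) == 0) empty_dih else as.data.frame(dihedrals)
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop("bonded term indices out of range")
  if (!all(atoms$type %in% lj_types$type))
    stop("unknown LJ type(s): ",
         paste(setdiff(atoms$type, lj_types$type), collapse = ", "))
  if (any(lj_types$c12 < 0)) stop("C12 must be non-negative")
  if (is.null(exclusions))
    exclusions <- make_exclusions(bonds, n)
  exclusions <- normalize_pairs(exclusions)
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, lj_types = lj_types,
                 exclusions = exclusions,
                 head_atom = head_atom, tail_atom = tail_atom),
            class = "mw_topology")
}

#' @export
print.mw_topology <- function(x, ...) {
  cat(sprintf("<mw_topology> %d atoms, %d bonds, %d angles, %d dihedrals, %d exclusions\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$exclusions)))
  invisible(x)
}

# 1-2 and 1-3 exclusions from the bond graph
make_exclusions <- function(bonds, n) {
  if (nrow(bonds) == 0) return(matrix(integer(0), 0, 2))
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (b in seq_len(nrow(bonds)))
    out[[length(out) + 1]] <- c(bonds$i[b], bonds$j[b])
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (k in seq_len(ncol(cmb)))
        out[[length(out) + 1]] <- cmb[, k]
    }
  }
  normalize_pairs(do.call(rbind, out))
}

normalize_pairs <- function(p) {
  if (is.null(p) || length(p) == 0) return(matrix(integer(0), 0, 2))
  p <- matrix(as.integer(p), ncol = 2)
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(p[order(p[, 1], p[, 2]), , drop = FALSE])
}

#' Reaction-field electrostatics parameters
#'
#' The reaction-field Coulomb interaction used beyond-cutoff mean-field
#' screening with external relative permittivity `epsilon_rf`:
#' `E = f q_i q_j (1/r + crf r^2/(2 Rc^3) - (1 + crf/2)/Rc)` with
#' `crf = 2 (eps_rf - 1) / (2 eps_rf + 1)` (zero ionic strength, internal
#' permittivity 1). The shift makes the pair energy vanish at the cutoff.
#'
#' @param cutoff cutoff radius Rc, nm.
#' @param epsilon_rf external relative permittivity (>= 1).
#' @param switch_width width of the group-pair switching region below the
#'   cutoff, nm. The whole interaction of a molecule (charge-group) pair is
#'   modulated by a C1 switching function of the centre-of-geometry
#'   distance over `[cutoff - switch_width, cutoff]`, which keeps the
#'   Hamiltonian continuous as pairs cross the cutoff (essential for
#'   energy conservation); 0 recovers plain truncation.
#' @return list with `cutoff`, `epsilon_rf`, `crf`, `rswitch`.
#' @export
reaction_field_params <- function(cutoff = 1.4, epsilon_rf = 61,
                                  switch_width = 0.1) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  if (epsilon_rf < 1) stop("epsilon_rf must be >= 1")
  if (switch_width < 0 || switch_width >= cutoff)
    stop("switch_width must be in [0, cutoff)")
  list(cutoff = cutoff, epsilon_rf = epsilon_rf,
       crf = 2 * (epsilon_rf - 1) / (2 * epsilon_rf + 1),
       rswitch = cutoff - switch_width)
}

# per-atom LJ type indices plus symmetric C6/C12 type-pair tables
# (geometric-mean combination)
lj_tables <- function(topology) {
  lt <- topology$lj_types
  ti <- match(topology$atoms$type, lt$type)
  s6 <- sqrt(lt$c6)
  s12 <- sqrt(lt$c12)
  list(type_index = ti, c6 = outer(s6, s6), c12 = outer(s12, s12))
}

# interaction-group ids: waters and ions are one group per molecule
# (charge-group style cutoff, which keeps truncation noise small for the
# strongly dipolar waters); solute atoms are individual groups.
interaction_groups <- function(topology) {
  a <- topology$atoms
  key <- ifelse(a$molkind == "solute", paste0("s", seq_len(nrow(a))),
                paste0("m", a$molid))
  as.integer(factor(key, levels = unique(key)))
}

energy_group_labels <- function(topology) {
  ifelse(topology$atoms$molkind == "solute", 0L, 1L)
}

#' Build a pair list under rectangular periodic boundaries
#'
#' Returns every non-excluded atom pair whose minimum-image distance is at
#' most `cutoff`. With `groups = "molecule"` the cutoff is instead applied
#' between molecule (charge-group) centres of geometry, and all site pairs
#' of a group pair within the cutoff are returned; this is the criterion
#' the dynamics engine uses.
#'
#' @param system an [simulation_system()].
#' @param cutoff nm; box edges must exceed `2 * cutoff`.
#' @param groups `"atom"` (default) or `"molecule"`.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
build_pair_list <- function(system, cutoff, groups = c("atom", "molecule")) {
  groups <- match.arg(groups)
  if (any(system$box <= 2 * cutoff))
    stop("configuration error: box edges must exceed 2 * cutoff for minimum-image validity")
  top <- system$topology
  lj <- lj_tables(top)
  g <- if (groups == "atom") seq_len(n_atoms(system)) else interaction_groups(top)
  res <- cpp_pair_list(system$positions, system$box, cutoff,
                       as.integer(g), energy_group_labels(top),
                       top$atoms$charge, lj$type_index, lj$c6, lj$c12,
                       excl_matrix(top))
  p <- res$pairs
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  colnames(p) <- c("i", "j")
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

excl_matrix <- function(topology) {
  e <- topology$exclusions
  if (nrow(e) == 0) matrix(integer(0), 0, 2) else matrix(as.integer(e), ncol = 2)
}

#' Nonbonded energies and forces with group decomposition
#'
#' Lennard-Jones plus reaction-field Coulomb interactions over the
#' molecule-group pair list, decomposed into solute-solute (`pp`),
#' solute-solvent (`pw`) and solvent-solvent (`ss`) contributions.
#' Excluded pairs still receive the reaction-field correction term beyond
#' `1/r` (GROMOS convention), so the shift stays consistent.
#'
#' @param system an [simulation_system()].
#' @param rf a [reaction_field_params()].
#' @param groups cutoff criterion, see [build_pair_list()].
#' @return list with an `energies` breakdown (see [energy_breakdown()]),
#'   `forces` (n x 3, kJ mol^-1 nm^-1) and the scalar `virial`.
#' @export
nonbonded_energy_forces <- function(system, rf, groups = "molecule") {
  ef <- system_energy_forces(system, rf, groups = groups,
                             use_bond_forces = FALSE, bonded = FALSE)
  list(energies = ef$energies, forces = ef$forces, virial = ef$virial)
}

#' Bonded energies and forces
#'
#' Harmonic bonds `0.5 kb (r - r0)^2`, harmonic angles
#' `0.5 ktheta (theta - theta0)^2` and periodic dihedrals
#' `kphi (1 + cos(mult phi - phi0))`, with analytic gradients.
#'
#' @param system an [simulation_system()].
#' @return list with `energy` (total bonded, kJ/mol), per-term energies and
#'   `forces`.
#' @export
bonded_energy_forces <- function(system) {
  top <- system$topology
  lj <- lj_tables(top)
  n <- n_atoms(system)
  res <- cpp_energy_forces(system$positions,
                           # huge box: no periodic wrapping for bonded-only
                           rep(1e6, 3),
                           rep(0, n), lj$type_index,
                           matrix(0, nrow(top$lj_types), nrow(top$lj_types)),
                           matrix(0, nrow(top$lj_types), nrow(top$lj_types)),
                           seq_len(n), rep(0L, n),
                           matrix(integer(0), 0, 2),
                           1e-3, 1e-3, 0,
                           bond_ij(top), top$bonds$r0, top$bonds$kb,
                           angle_ijk(top), top$angles$theta0 * pi / 180,
                           top$angles$ktheta,
                           dih_ijkl(top), as.integer(top$dihedrals$mult),
                           top$dihedrals$phi0 * pi / 180, top$dihedrals$kphi,
                           integer(0), matrix(0, 0, 3), 0, TRUE)
  list(energy = res$e_bond + res$e_angle + res$e_dihedral,
       e_bond = res$e_bond, e_angle = res$e_angle, e_dihedral = res$e_dihedral,
       forces = res$forces)
}

bond_ij <- function(top) matrix(as.integer(c(top$bonds$i, top$bonds$j)), ncol = 2)
angle_ijk <- function(top) matrix(as.integer(c(top$angles$i, top$angles$j, top$angles$k)), ncol = 3)
dih_ijkl <- function(top) matrix(as.integer(c(top$dihedrals$i, top$dihedrals$j,
                                              top$dihedrals$k, top$dihedrals$l)), ncol = 4)

#' Total potential energy and forces
#'
#' Single-point evaluation combining nonbonded, bonded and (optionally)
#' position-restraint terms. Used by the minimizer and by tests; the MD
#' driver evaluates the same kernels internally.
#'
#' @param system an [simulation_system()].
#' @param rf a [reaction_field_params()].
#' @param use_bond_forces logical; include harmonic bond terms (TRUE during
#'   minimization where bonds are unconstrained; during dynamics bonds are
#'   handled by SHAKE/SETTLE instead).
#' @param restraints optional list(`atoms`, `ref`, `k`): harmonic position
#'   restraints with force constant `k` in kJ mol^-1 nm^-2.
#' @param groups cutoff criterion, see [build_pair_list()].
#' @param bonded include angle/dihedral terms (default TRUE).
#' @return list with `energies` ([energy_breakdown()]), `total` (kJ/mol),
#'   `forces`, `virial`.
#' @export
system_energy_forces <- function(system, rf, use_bond_forces = TRUE,
                                 restraints = NULL, groups = "molecule",
                                 bonded = TRUE) {
  top <- system$topology
  lj <- lj_tables(top)
  n <- n_atoms(system)
  g <- if (groups == "atom") seq_len(n) else interaction_groups(top)
  ridx <- integer(0); rref <- matrix(0, 0, 3); rk <- 0
  if (!is.null(restraints) && restraints$k > 0) {
    ridx <- as.integer(restraints$atoms)
    rref <- as.matrix(restraints$ref)
    rk <- restraints$k
  }
  if (bonded) {
    ang <- angle_ijk(top); th0 <- top$angles$theta0 * pi / 180; kth <- top$angles$ktheta
    dih <- dih_ijkl(top); dmu <- as.integer(top$dihedrals$mult)
    dph <- top$dihedrals$phi0 * pi / 180; dkp <- top$dihedrals$kphi
  } else {
    ang <- matrix(integer(0), 0, 3); th0 <- numeric(0); kth <- numeric(0)
    dih <- matrix(integer(0), 0, 4); dmu <- integer(0)
    dph <- numeric(0); dkp <- numeric(0)
  }
  res <- cpp_energy_forces(system$positions, system$box,
                           top$atoms$charge, lj$type_index, lj$c6, lj$c12,
                           as.integer(g), energy_group_labels(top),
                           excl_matrix(top), rf$cutoff,
                           rf$rswitch %||% rf$cutoff, rf$crf,
                           bond_ij(top), top$bonds$r0, top$bonds$kb,
                           ang, th0, kth, dih, dmu, dph, dkp,
                           ridx, rref, rk, use_bond_forces)
  en <- energy_breakdown(
    e_vdw_pp = res$e_vdw_pp, e_es_pp = res$e_es_pp,
    e_vdw_pw = res$e_vdw_pw, e_es_pw = res$e_es_pw,
    e_solvent_solvent = res$e_vdw_ss + res$e_es_ss,
    e_bonded_solute = res$e_bond + res$e_angle + res$e_dihedral)
  total <- en$e_tot_pp + en$e_tot_pw + en$e_solvent_solvent +
    en$e_bonded_solute + res$e_restraint
  list(energies = en, total = total, e_restraint = res$e_restraint,
       forces = res$forces, virial = res$virial)
}

#' Energy decomposition container
#'
#' Group-wise decomposition of the potential energy: intra-solute (`pp`)
#' and solute-solvent (`pw`) van der Waals and electrostatic terms, plus
#' solvent-solvent and bonded totals. Totals satisfy
#' `e_tot_pp = e_vdw_pp + e_es_pp` and `e_tot_pw = e_vdw_pw + e_es_pw`.
#'
#' @param e_vdw_pp,e_es_pp,e_vdw_pw,e_es_pw,e_bonded_solute,e_solvent_solvent
#'   energies in kJ/mol.
#' @return list of class `energy_breakdown`.
#' @export
energy_breakdown <- function(e_vdw_pp = 0, e_es_pp = 0, e_vdw_pw = 0,
                             e_es_pw = 0, e_bonded_solute = 0,
                             e_solvent_solvent = 0) {
  structure(list(
    e_vdw_pp = e_vdw_pp, e_es_pp = e_es_pp, e_tot_pp = e_vdw_pp + e_es_pp,
    e_vdw_pw = e_vdw_pw, e_es_pw = e_es_pw, e_tot_pw = e_vdw_pw + e_es_pw,
    e_bonded_solute = e_bonded_solute,
    e_solvent_solvent = e_solvent_solvent), class = "energy_breakdown")
}
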