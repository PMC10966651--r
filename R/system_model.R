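# Simulation state, degree-of-freedom accounting and the kinetic-energy
# partition that makes separate rotational/translational thermostatting of
# rigid water possible.

#' Construct a simulation system
#'
#' Bundles coordinates, velocities, a rectangular periodic box and a
#' topology into the container used by every builder, dynamics and analysis
#' function in the package.
#'
#' @param positions numeric matrix (n_atoms x 3), nm.
#' @param box numeric length-3 vector of box edge lengths, nm (all > 0).
#' @param topology an object created by [mw_topology()].
#' @param velocities optional numeric matrix (n_atoms x 3), nm/ps; defaults
#'   to zero.
#' @return An object of class `mw_system`: a list with elements
#'   `positions`, `velocities`, `box`, `topology`.
#' @export
simulation_system <- function(positions, box, topology, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!inherits(topology, "mw_topology")) stop("topology must be an mw_topology")
  n <- nrow(positions)
  if (n != nrow(topology$atoms))
    stop("positions and topology disagree on atom count")
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three strictly positive edge lengths")
  if (is.null(velocities)) {
    velocities <- matrix(0, n, 3)
  } else {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == c(n, 3)))
      stop("velocities must match positions in shape")
  }
  wt <- water_triplets(topology)
  if (nrow(wt) * 3 + sum(topology$atoms$molkind != "water") != n)
    stop("every water molecule must have exactly 3 sites")
  structure(list(positions = positions, velocities = velocities,
                 box = as.numeric(box), topology = topology),
            class = "mw_system")
}

#' @export
print.mw_system <- function(x, ...) {
  a <- x$topology$atoms
  cat(sprintf("<mw_system> %d atoms (%d solute, %d waters, %d ions), box %.3f x %.3f x %.3f nm\n",
              nrow(a), sum(a$molkind == "solute"),
              sum(a$molkind == "water") / 3, sum(a$molkind == "ion"),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

n_atoms <- function(system) nrow(system$positions)

#' Atom indices by molecule kind
#'
#' @param topology an [mw_topology()].
#' @param kind one of `"solute"`, `"water"`, `"ion"`.
#' @return integer vector of atom indices.
#' @export
atom_indices <- function(topology, kind) {
  which(topology$atoms$molkind == kind)
}

# matrix (n_waters x 3) of O, H1, H2 atom indices, in molecule order
water_triplets <- function(topology) {
  a <- topology$atoms
  wat <- which(a$molkind == "water")
  if (length(wat) == 0) return(matrix(integer(0), 0, 3))
  mols <- split(wat, a$molid[wat])
  bad <- vapply(mols, length, 1L) != 3L
  if (any(bad)) stop("every water molecule must have exactly 3 sites")
  out <- do.call(rbind, lapply(mols, function(ix) {
    o <- ix[a$name[ix] == "OW"]
    h <- ix[a$name[ix] != "OW"]
    if (length(o) != 1 || length(h) != 2) stop("water must be one OW and two HW sites")
    c(o, h)
  }))
  rownames(out) <- NULL
  out
}

#' Specify a heat bath
#'
#' One weak-coupling (Berendsen) bath. Three baths drive a nonequilibrium
#' run: the solute bath, the solvent translational bath (centre-of-mass
#' motion of each rigid water, plus any ions) and the solvent rotational
#' bath (motion of water sites about their molecular centre of mass).
#'
#' @param selector one of `"solute"`, `"solvent_translational"`,
#'   `"solvent_rotational"`.
#' @param target_temperature target temperature, K (> 0).
#' @param coupling_time relaxation time tau, ps (> 0). The short default
#'   0.01 ps counteracts the strong energy flux from rotationally hot to
#'   translationally cold degrees of freedom.
#' @return A `bath_spec` list.
#' @export
bath_spec <- function(selector = c("solute", "solvent_translational",
                                   "solvent_rotational"),
                      target_temperature, coupling_time = 0.01) {
  selector <- match.arg(selector)
  stopifnot_scalar_pos(target_temperature, "target_temperature")
  stopifnot_scalar_pos(coupling_time, "coupling_time")
  structure(list(selector = selector,
                 target_temperature = target_temperature,
                 coupling_time = coupling_time),
            class = "bath_spec")
}

#' Partition solvent kinetic energy into translational and rotational parts
#'
#' For each rigid three-site water the translational part is the kinetic
#' energy of the molecular centre of mass, and the rotational part is the
#' exact residual (total molecular kinetic energy minus centre-of-mass
#' kinetic energy). For a rigid molecule the residual is purely rotational,
#' so no inertia tensor is needed and the identity
#' `ke_trans + ke_rot == total solvent KE` holds to machine precision.
#'
#' @param system an [simulation_system()] containing at least one water.
#' @return list with `ke_trans` and `ke_rot` (kJ/mol).
#' @export
partition_water_kinetic <- function(system) {
  top <- system$topology
  wt <- water_triplets(top)
  if (nrow(wt) == 0) stop("system contains no water molecules")
  m <- top$atoms$mass
  if (any(m[wt] <= 0) || sum(m[wt]) <= 0) stop("water masses must be positive")
  v <- system$velocities
  ke_trans <- 0
  ke_rot <- 0
  mO <- m[wt[1, 1]]
  mH <- m[wt[1, 2]]
  M <- mO + 2 * mH
  for (w in seq_len(nrow(wt))) {
    io <- wt[w, 1]; i1 <- wt[w, 2]; i2 <- wt[w, 3]
    p <- mO * v[io, ] + mH * v[i1, ] + mH * v[i2, ]
    vcom <- p / M
    kec <- 0.5 * M * sum(vcom^2)
    ket <- 0.5 * (mO * sum(v[io, ]^2) + mH * sum(v[i1, ]^2) + mH * sum(v[i2, ]^2))
    ke_trans <- ke_trans + kec
    ke_rot <- ke_rot + (ket - kec)
  }
  list(ke_trans = ke_trans, ke_rot = ke_rot)
}

#' Instantaneous temperature from kinetic energy
#'
#' Equipartition: `T = 2 KE / (n_dof * kB)` with
#' `kB = 0.00831446 kJ/(mol K)`.
#'
#' @param kinetic_energy kJ/mol (>= 0).
#' @param n_dof number of kinetic degrees of freedom (>= 1).
#' @return temperature, K.
#' @export
instantaneous_temperature <- function(kinetic_energy, n_dof) {
  if (length(n_dof) != 1 || !is.finite(n_dof) || n_dof < 1)
    stop("undefined temperature: n_dof must be >= 1")
  2 * kinetic_energy / (n_dof * .kB)
}

#' Count kinetic degrees of freedom
#'
#' A rigid three-site water contributes exactly six kinetic degrees of
#' freedom: three translational and three rotational (its three internal
#' distances are constrained and carry no kinetic energy). Solute degrees
#' of freedom are `3 N_atoms` minus one per constrained bond, minus global
#' constraints: 6 when roto-translational constraints are active, 3 when
#' only centre-of-mass removal is active, 0 otherwise.
#'
#' @param system an [simulation_system()].
#' @param com_removal logical; is periodic centre-of-mass removal active?
#' @param rototranslational logical; are solute roto-translational
#'   constraints active? (Overrides `com_removal` for the solute count.)
#' @return list with `n_dof_solute`, `n_dof_solvent_trans`,
#'   `n_dof_solvent_rot`, `n_dof_ion`.
#' @export
count_dof <- function(system, com_removal = FALSE, rototranslational = FALSE) {
  top <- system$topology
  a <- top$atoms
  n_wat <- sum(a$molkind == "water") / 3
  n_sol <- sum(a$molkind == "solute")
  n_ion <- sum(a$molkind == "ion")
  n_cons <- n_solute_constraints(top)
  n_global <- if (rototranslational) 6 else if (com_removal) 3 else 0
  n_dof_solute <- if (n_sol > 0) max(3 * n_sol - n_cons - n_global, 0) else 0
  list(n_dof_solute = n_dof_solute,
       n_dof_solvent_trans = 3 * n_wat,
       n_dof_solvent_rot = 3 * n_wat,
       n_dof_ion = 3 * n_ion)
}

# number of constrained solute bonds (all solute bonds are SHAKE-constrained
# during dynamics)
n_solute_constraints <- function(topology) {
  b <- topology$bonds
  if (nrow(b) == 0) return(0L)
  sol <- topology$atoms$molkind == "solute"
  sum(sol[b$i] & sol[b$j])
}
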