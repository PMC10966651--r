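# Trajectory analysis: superposition RMSD and its size-normalized variant,
# RMSF, radius of gyration, head-to-tail distance, hydrogen-bond counts,
# solvent-accessible surface area with a polar/nonpolar residue split,
# secondary-structure frequencies, block-averaged uncertainties and the
# paired condition-ratio statistic.

#' Optimal superposition and RMSD
#'
#' Least-squares (Kabsch) superposition of `frame` onto `reference` over
#' the selected atoms, with reflections excluded, followed by the
#' root-mean-square deviation after the fit.
#'
#' @param frame,reference n x 3 coordinate matrices, nm.
#' @param atom_selection indices of atoms used for the fit (>= 3,
#'   non-collinear); default all.
#' @return list with `rotation` (3 x 3), `rmsd` (nm), and `fitted` (the
#'   full transformed frame).
#' @export
superpose_rmsd <- function(frame, reference, atom_selection = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  sel <- atom_selection %||% seq_len(nrow(frame))
  if (length(sel) < 3) stop("need at least 3 atoms for superposition")
  A <- frame[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))   # t(A0) %*% B0
  # guard against collinear selections: smallest two singular values ~ 0
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-30))
    stop("degenerate fit: selected atoms are (near-)collinear")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)     # rotation such that x_fit = R x
  fitted <- sweep(sweep(frame, 2, ca) %*% t(R), 2, cb, "+")
  dev <- fitted[sel, , drop = FALSE] - B
  list(rotation = R, rmsd = sqrt(mean(rowSums(dev^2))), fitted = fitted)
}

#' Size-normalized RMSD (RMSD100)
#'
#' Carugo-Pongor normalization to the equivalent RMSD of a 100-residue
#' structure: `RMSD100 = RMSD / (1 + ln sqrt(N/100))`. The formula has not
#' been validated below 40 residues (a warning is issued) and its
#' denominator crosses zero near N = 14 (an error).
#'
#' @param rmsd nm.
#' @param n_residues number of residues (>= 1).
#' @return nm.
#' @export
rmsd100 <- function(rmsd, n_residues) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  denom <- 1 + log(sqrt(n_residues / 100))
  if (denom <= 0)
    stop("RMSD100 undefined: normalization denominator <= 0 for N = ",
         n_residues)
  if (n_residues < 40)
    warning("RMSD100 has not been validated for structures with fewer than 40 residues")
  rmsd / denom
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed onto `fit_reference` over the selection; the RMSF
#' of each selected atom is the square root of its time-averaged squared
#' deviation from its time-averaged position.
#'
#' @param trajectory an [mw_trajectory()] or list of coordinate matrices.
#' @param atom_selection indices (default all atoms).
#' @param fit_reference reference coordinates for superposition (default:
#'   first frame).
#' @param fit superpose each frame onto the reference first (default TRUE;
#'   set FALSE when frames are already aligned, e.g. for solutes under
#'   roto-translational constraints).
#' @return numeric vector, nm, one value per selected atom.
#' @export
rmsf <- function(trajectory, atom_selection = NULL, fit_reference = NULL,
                 fit = TRUE) {
  frames <- traj_frames(trajectory)
  if (length(frames) < 2) stop("RMSF requires at least 2 frames")
  sel <- atom_selection %||% seq_len(nrow(frames[[1]]))
  ref <- fit_reference %||% frames[[1]]
  fitted <- lapply(frames, function(fr) {
    if (fit) superpose_rmsd(fr, ref, sel)$fitted[sel, , drop = FALSE]
    else fr[sel, , drop = FALSE]
  })
  arr <- simplify2array(fitted)         # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  sq <- vapply(seq_along(fitted), function(k)
    rowSums((fitted[[k]] - mean_pos)^2), numeric(length(sel)))
  sqrt(rowMeans(matrix(sq, nrow = length(sel))))
}

#' Radius of gyration
#'
#' `sqrt(sum w_i |x_i - xbar|^2 / sum w_i)` over the selection, optionally
#' mass-weighted.
#'
#' @param frame n x 3 coordinates, nm.
#' @param atom_selection indices (default all).
#' @param masses per-atom masses (required when `mass_weighted`).
#' @param mass_weighted logical (default FALSE: geometric).
#' @return nm.
#' @export
radius_of_gyration <- function(frame, atom_selection = NULL, masses = NULL,
                               mass_weighted = FALSE) {
  frame <- as.matrix(frame)
  sel <- atom_selection %||% seq_len(nrow(frame))
  if (length(sel) == 0) stop("empty selection")
  x <- frame[sel, , drop = FALSE]
  w <- if (mass_weighted) masses[sel] else rep(1, length(sel))
  ctr <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)) / sum(w))
}

#' Head-to-tail distance
#'
#' Euclidean distance between the tagged terminal atoms (minimum image is
#' deliberately not applied: the solute is kept whole).
#'
#' @param frame n x 3 coordinates, nm.
#' @param head_atom,tail_atom atom indices; default: the topology tags set
#'   by [make_toy_solute()] when `topology` is supplied.
#' @param topology optional [mw_topology()] carrying the tags.
#' @return nm.
#' @export
head_to_tail <- function(frame, head_atom = NULL, tail_atom = NULL,
                         topology = NULL) {
  if (is.null(head_atom) && !is.null(topology)) head_atom <- topology$head_atom
  if (is.null(tail_atom) && !is.null(topology)) tail_atom <- topology$tail_atom
  if (is.null(head_atom) || is.null(tail_atom) ||
      is.na(head_atom) || is.na(tail_atom))
    stop("head/tail atoms are not tagged; pass head_atom and tail_atom")
  vec_norm(frame[head_atom, ] - frame[tail_atom, ])
}

#' Hydrogen-bond criteria
#'
#' Geometric criteria: a bond is counted when the hydrogen-acceptor
#' distance is at most `max_h_acceptor_distance` and the
#' donor-hydrogen-acceptor angle is at least `min_donor_angle`.
#'
#' @param max_h_acceptor_distance nm (default 0.25).
#' @param min_donor_angle degrees (default 135).
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_h_acceptor_distance = 0.25,
                           min_donor_angle = 135) {
  stopifnot_scalar_pos(max_h_acceptor_distance, "max_h_acceptor_distance")
  if (min_donor_angle <= 0 || min_donor_angle > 180)
    stop("min_donor_angle must be in (0, 180]")
  structure(list(max_h_acceptor_distance = max_h_acceptor_distance,
                 min_donor_angle = min_donor_angle),
            class = "hbond_criteria")
}

# donor/acceptor tables derived from a topology.
# Waters donate through their explicit H sites. Toy-solute backbone N sites
# donate through an implied amide hydrogen placed 0.1 nm from N along the
# direction opposite the preceding carbonyl C=O vector (the DSSP
# convention); the first residue's N has no preceding carbonyl and does
# not donate. Acceptors are all O sites (backbone carbonyl and water
# oxygen).
hbond_sites <- function(topology) {
  a <- topology$atoms
  don_h <- which(a$molkind == "water" & a$name != "OW")
  # each water H's donor heavy atom is its O
  wt <- water_triplets(topology)
  omap <- integer(nrow(a))
  if (nrow(wt)) {
    omap[wt[, 2]] <- wt[, 1]
    omap[wt[, 3]] <- wt[, 1]
  }
  don_d <- omap[don_h]
  sol_n <- which(a$molkind == "solute" & a$name == "N")
  # preceding carbonyl C and O per backbone N (same chain, previous residue)
  prevC <- prevO <- integer(0)
  keepN <- integer(0)
  if (length(sol_n)) {
    for (ni in sol_n) {
      r <- a$resid[ni]
      pc <- which(a$molkind == "solute" & a$name == "C" & a$resid == r - 1)
      po <- which(a$molkind == "solute" & a$name == "O" & a$resid == r - 1)
      if (length(pc) == 1 && length(po) == 1) {
        keepN <- c(keepN, ni); prevC <- c(prevC, pc); prevO <- c(prevO, po)
      }
    }
  }
  acc <- which(a$name %in% c("O", "OW"))
  list(water_h = don_h, water_d = don_d,
       amide_n = keepN, amide_prev_c = prevC, amide_prev_o = prevO,
       acceptors = acc)
}

# implied amide H coordinates for the tagged backbone N atoms
amide_h_positions <- function(frame, sites) {
  if (length(sites$amide_n) == 0) return(matrix(0, 0, 3))
  dir <- frame[sites$amide_prev_c, , drop = FALSE] -
    frame[sites$amide_prev_o, , drop = FALSE]
  dir <- dir / sqrt(rowSums(dir^2))
  frame[sites$amide_n, , drop = FALSE] + 0.1 * dir
}

# count bonds between explicit (donor, H) arrays and acceptor positions
count_hb <- function(dpos, hpos, apos, criteria, box = NULL) {
  if (nrow(hpos) == 0 || nrow(apos) == 0) return(0L)
  # donor-H-acceptor angle >= min_donor_angle; the angle at the hydrogen
  # between H->D and H->A. Equivalently (H->A).(D->H) / (|..||..|) >=
  # cos(180 - min_angle).
  cosmin <- cos((180 - criteria$min_donor_angle) * pi / 180)
  n <- 0L
  for (k in seq_len(nrow(hpos))) {
    dv <- sweep(apos, 2, hpos[k, ], "-")
    if (!is.null(box)) dv <- min_image(dv, box)
    r <- sqrt(rowSums(dv^2))
    ok <- which(r <= criteria$max_h_acceptor_distance & r > 1e-6)
    if (!length(ok)) next
    hd <- hpos[k, ] - dpos[k, ]
    if (!is.null(box)) hd <- min_image(hd, box)
    uhd <- hd / vec_norm(hd)
    cosang <- (dv[ok, , drop = FALSE] %*% uhd) / r[ok]
    n <- n + sum(cosang >= cosmin)
  }
  n
}

#' Hydrogen-bond statistics over a trajectory
#'
#' Counts, per frame: total intra-solute hydrogen bonds (`n_hb_pp`), the
#' backbone-backbone subset (`n_hb_pp_backbone`, amide N-H donors to
#' carbonyl O acceptors), and solute-water bonds in both directions
#' (`n_hb_pw`). A bond is counted on the geometric criteria of
#' [hbond_criteria()].
#'
#' @param trajectory an [mw_trajectory()] or list of frames.
#' @param topology the system topology.
#' @param criteria an [hbond_criteria()].
#' @param box optional box for minimum-image distances (taken from the
#'   trajectory when available).
#' @return data.frame with one row per frame: `n_hb_pp`,
#'   `n_hb_pp_backbone`, `n_hb_pw`.
#' @export
hbond_statistics <- function(trajectory, topology,
                             criteria = hbond_criteria(), box = NULL) {
  frames <- traj_frames(trajectory)
  if (is.null(box) && inherits(trajectory, "mw_trajectory"))
    box <- trajectory$box
  sites <- hbond_sites(topology)
  a <- topology$atoms
  if (length(sites$amide_n) == 0 && length(sites$water_h) == 0)
    warning("no hydrogen-bond donors found")
  acc_sol <- sites$acceptors[a$molkind[sites$acceptors] == "solute"]
  acc_wat <- sites$acceptors[a$molkind[sites$acceptors] == "water"]
  out <- lapply(frames, function(fr) {
    hN <- amide_h_positions(fr, sites)
    dN <- fr[sites$amide_n, , drop = FALSE]
    hW <- fr[sites$water_h, , drop = FALSE]
    dW <- fr[sites$water_d, , drop = FALSE]
    pp_bb <- count_hb(dN, hN, fr[acc_sol, , drop = FALSE], criteria, box)
    # total intra-solute: currently identical donor set (backbone amides);
    # sidechain beads carry no explicit hydrogens in the toy model
    pp <- pp_bb
    pw <- count_hb(dN, hN, fr[acc_wat, , drop = FALSE], criteria, box) +
      count_hb(dW, hW, fr[acc_sol, , drop = FALSE], criteria, box)
    data.frame(n_hb_pp = pp, n_hb_pp_backbone = pp_bb, n_hb_pw = pw)
  })
  do.call(rbind, out)
}

#' Default atomic radii for SASA, nm
#' @return named vector of radii by atom name class.
#' @export
sasa_radii <- function() {
  c(N = 0.155, CA = 0.17, C = 0.17, O = 0.152, CB = 0.18,
    OW = 0.152, HW1 = 0.0, HW2 = 0.0, NA. = 0.2, CL = 0.2)
}

#' Residue polarity classification
#'
#' The polar and nonpolar residue lists used for the SASA split.
#' Classification is configurable; these defaults assign Ala, Cys, Ile,
#' Leu, Met, Phe, Trp, Tyr and Val as nonpolar and Arg, Asn, Asp, Glu,
#' Gly, Gln, His, Lys, Pro, Ser and Thr as polar.
#'
#' @return list with `polar` and `nonpolar` residue-name vectors.
#' @export
residue_polarity <- function() {
  list(polar = c("ARG", "ASN", "ASP", "GLU", "GLY", "GLN", "HIS", "LYS",
                 "PRO", "SER", "THR"),
       nonpolar = c("ALA", "CYS", "ILE", "LEU", "MET", "PHE", "TRP", "TYR",
                    "VAL"))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Golden-spiral sample points on each atom's probe-inflated sphere are
#' tested against all neighbouring inflated spheres; the accessible
#' fraction times the sphere area gives the per-atom SASA. Per-residue
#' sums are classified polar/nonpolar by residue name.
#'
#' @param frame n x 3 coordinates, nm (typically solute only).
#' @param radii per-atom radii, nm; or NULL to look up by atom name in
#'   `radii_table`.
#' @param probe_radius nm (default 0.14).
#' @param n_points sphere sample points (>= 100; default 960).
#' @param atoms data.frame with `name`, `resid`, `resname` (for per-residue
#'   classification); optional when `radii` is given and no split is needed.
#' @param radii_table named radius lookup (default [sasa_radii()]).
#' @param polarity classification lists (default [residue_polarity()]).
#' @return list with `total`, `polar`, `nonpolar` (nm^2) and `per_atom`.
#' @export
sasa <- function(frame, radii = NULL, probe_radius = 0.14, n_points = 960,
                 atoms = NULL, radii_table = sasa_radii(),
                 polarity = residue_polarity()) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (n_points < 100) stop("n_points must be >= 100")
  if (is.null(radii)) {
    if (is.null(atoms)) stop("need per-atom radii or an atoms table")
    key <- ifelse(atoms$name %in% names(radii_table), atoms$name,
                  substr(atoms$name, 1, 2))
    radii <- radii_table[key]
    if (any(is.na(radii)))
      stop("missing radius for atom type(s): ",
           paste(unique(atoms$name[is.na(radii)]), collapse = ", "))
  }
  pts <- sphere_points(n_points)
  inflated <- radii + probe_radius
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    if (inflated[i] <= probe_radius) next  # zero-radius site (e.g. water H)
    ri <- inflated[i]
    d2 <- rowSums(sweep(frame, 2, frame[i, ], "-")^2)
    nb <- which(d2 < (ri + inflated)^2 & seq_len(n) != i & inflated > probe_radius)
    sp <- sweep(pts * ri, 2, frame[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(sp, 2, frame[j, ], "-")^2)
      acc <- acc & dj2 > inflated[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * ri^2 * mean(acc)
  }
  total <- sum(per_atom)
  polar <- nonpolar <- NA_real_
  if (!is.null(atoms) && "resname" %in% names(atoms)) {
    is_polar <- atoms$resname %in% polarity$polar
    is_nonpolar <- atoms$resname %in% polarity$nonpolar
    other <- !(is_polar | is_nonpolar)
    if (any(other & per_atom > 0))
      warning("unclassified residues contribute SASA: ",
              paste(unique(atoms$resname[other]), collapse = ", "))
    polar <- sum(per_atom[is_polar])
    nonpolar <- sum(per_atom[is_nonpolar])
  }
  list(total = total, polar = polar, nonpolar = nonpolar, per_atom = per_atom)
}

#' Secondary-structure frequencies
#'
#' A simplified Kabsch-Sander-style assignment. Backbone hydrogen-bond
#' energies use the electrostatic model
#' `E = q1 q2 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 * 4.184` (kJ/mol,
#' distances in Angstrom internally; q1 q2 = 0.42 * 0.20) with a bond
#' assigned below -2.09 kJ/mol (-0.5 kcal/mol); amide hydrogens are
#' implied as in [hbond_statistics()]. Two consecutive i -> i+4 turns mark
#' helix residues; bridge patterns between strands mark sheet; the rest is
#' coil. Frequencies are averaged over frames and residues and sum to 1.
#'
#' @param trajectory an [mw_trajectory()] or list of frames.
#' @param topology the system topology (backbone N, C, O sites required;
#'   residues missing them are assigned coil).
#' @return list with `helix`, `sheet`, `coil` fractions.
#' @export
secondary_structure_frequencies <- function(trajectory, topology) {
  frames <- traj_frames(trajectory)
  a <- topology$atoms
  res <- sort(unique(a$resid[a$molkind == "solute"]))
  nres <- length(res)
  idx_of <- function(nm) vapply(res, function(r) {
    k <- which(a$molkind == "solute" & a$resid == r & a$name == nm)
    if (length(k) == 1) k else NA_integer_
  }, integer(1))
  iN <- idx_of("N"); iC <- idx_of("C"); iO <- idx_of("O")
  counts <- c(helix = 0, sheet = 0, coil = 0)
  sites <- hbond_sites(topology)
  for (fr in frames) {
    hb <- matrix(FALSE, nres, nres)   # donor residue -> acceptor residue
    hN <- amide_h_positions(fr, sites)
    hres <- a$resid[sites$amide_n]
    for (k in seq_along(sites$amide_n)) {
      di <- match(hres[k], res)
      for (aj in seq_len(nres)) {
        if (is.na(iC[aj]) || is.na(iO[aj]) || aj == di) next
        rON <- vec_norm(fr[sites$amide_n[k], ] - fr[iO[aj], ]) * 10
        rCH <- vec_norm(hN[k, ] - fr[iC[aj], ]) * 10
        rOH <- vec_norm(hN[k, ] - fr[iO[aj], ]) * 10
        rCN <- vec_norm(fr[sites$amide_n[k], ] - fr[iC[aj], ]) * 10
        e <- 0.42 * 0.20 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332 * 4.184
        if (e < -2.09) hb[di, aj] <- TRUE
      }
    }
    state <- rep("coil", nres)
    # helix: two consecutive i -> i+4 turns mark residues i+1..i+4
    turn <- rep(FALSE, nres)
    for (i in seq_len(nres - 4)) if (hb[i + 4, i]) turn[i] <- TRUE
    for (i in which(turn)) {
      if (i > 1 && turn[i - 1]) state[i:(min(i + 3, nres))] <- "helix"
    }
    # sheet: bridge patterns between non-adjacent residues
    for (i in seq_len(nres)) {
      for (j in seq_len(nres)) {
        if (abs(i - j) < 3) next
        anti <- (hb[i, j] && hb[j, i]) ||
          (i > 1 && j < nres && i < nres && j > 1 &&
             hb[i - 1, j + 1] && hb[j - 1, i + 1])
        par <- (i > 1 && i < nres && hb[i - 1, j] && hb[j, i + 1])
        if ((anti || par) && state[i] != "helix") state[i] <- "sheet"
      }
    }
    counts <- counts + table(factor(state, levels = c("helix", "sheet", "coil")))
  }
  tot <- sum(counts)
  list(helix = unname(counts["helix"] / tot),
       sheet = unname(counts["sheet"] / tot),
       coil = unname(counts["coil"] / tot))
}

#' Block-averaged mean and standard error
#'
#' Flyvbjerg-Petersen blocking for correlated series: the series is
#' repeatedly halved by averaging adjacent pairs; at each level the naive
#' SEM estimate `sqrt(var/(n-1))` is recorded. The reported SEM is taken
#' from the first plateau (relative change below 5% over two successive
#' levels), or the deepest level with at least four blocks.
#'
#' @param series numeric vector, length >= 16.
#' @return list with `mean`, `sem`, and the per-level `sem_levels`.
#' @export
block_average <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 16) stop("series too short for block averaging (need >= 16)")
  sems <- numeric(0)
  x <- series
  while (length(x) >= 4) {
    sems <- c(sems, sqrt(stats::var(x) / (length(x) - 1)))
    nhalf <- floor(length(x) / 2)
    x <- (x[2 * seq_len(nhalf) - 1] + x[2 * seq_len(nhalf)]) / 2
  }
  sem <- sems[length(sems)]
  if (length(sems) >= 3) {
    for (k in 3:length(sems)) {
      base <- max(sems[k], .Machine$double.eps)
      if (abs(sems[k] - sems[k - 1]) < 0.05 * base &&
          abs(sems[k - 1] - sems[k - 2]) < 0.05 * base) {
        sem <- sems[k]
        break
      }
    }
  }
  list(mean = mean(series), sem = sem, sem_levels = sems)
}

#' Paired condition comparison (relative change under microwave heating)
#'
#' For each paired system the relative change is
#' `(mean_MW / mean_eq) - 1`, so quantities that shrink under the
#' microwave condition come out negative. The reported change is the mean
#' over systems and its SEM is the standard deviation of the per-system
#' changes divided by `sqrt(n_systems)`. The literal ratio orientation
#' `(mean_eq / mean_MW) - 1` is available via `literal_order = TRUE`.
#'
#' @param values_eq,values_mw numeric vectors of per-system means, paired
#'   by position.
#' @param literal_order flip the ratio orientation.
#' @return list with `mean_change`, `sem_change`, `per_system`, and the
#'   sign `convention` used.
#' @export
condition_comparison <- function(values_eq, values_mw, literal_order = FALSE) {
  if (length(values_eq) != length(values_mw))
    stop("condition value vectors must be paired")
  num <- if (literal_order) values_eq else values_mw
  den <- if (literal_order) values_mw else values_eq
  ok <- abs(den) > .Machine$double.eps
  if (!all(ok))
    warning(sum(!ok), " system(s) excluded: zero denominator")
  change <- num[ok] / den[ok] - 1
  list(mean_change = mean(change),
       sem_change = if (length(change) > 1) sd(change) / sqrt(length(change)) else 0,
       per_system = change,
       convention = if (literal_order) "eq/mw - 1" else "mw/eq - 1")
}

#' Per-trajectory analysis summary
#'
#' Computes every structural and energetic summary the package reports for
#' one production trajectory: backbone RMSD to a reference (raw and
#' RMSD100-normalized), backbone RMSF, radius of gyration, head-to-tail
#' distance, hydrogen-bond counts, SASA with the polar/nonpolar split,
#' secondary-structure frequencies, and the mean energy decomposition.
#' Scalar time series carry block-averaged SEMs.
#'
#' @param trajectory an [mw_trajectory()] with energies.
#' @param topology the system topology.
#' @param reference reference coordinates for RMSD (n_atoms x 3; e.g. the
#'   starting structure).
#' @param criteria an [hbond_criteria()].
#' @return list of class `analysis_summary`; quantities are lists with
#'   `mean` and `sem` where a time series underlies them.
#' @export
analysis_summary <- function(trajectory, topology, reference,
                             criteria = hbond_criteria()) {
  frames <- traj_frames(trajectory)
  a <- topology$atoms
  sol <- which(a$molkind == "solute")
  bb <- which(a$molkind == "solute" & a$name %in% c("N", "CA", "C", "O"))
  nres <- length(unique(a$resid[sol]))
  msem <- function(x) {
    if (length(x) >= 16) {
      ba <- block_average(x)
      list(mean = ba$mean, sem = ba$sem)
    } else list(mean = mean(x), sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0)
  }
  rmsd_t <- vapply(frames, function(fr)
    superpose_rmsd(fr, reference, bb)$rmsd, numeric(1))
  rg_t <- vapply(frames, function(fr)
    radius_of_gyration(fr, sol, a$mass, mass_weighted = TRUE), numeric(1))
  h2t_t <- vapply(frames, function(fr)
    head_to_tail(fr, topology = topology), numeric(1))
  hb <- hbond_statistics(trajectory, topology, criteria)
  sasa_t <- lapply(frames, function(fr)
    sasa(fr[sol, , drop = FALSE], atoms = a[sol, ]))
  rmsf_v <- rmsf(trajectory, bb)
  rmsd_s <- msem(rmsd_t)
  en <- trajectory$energies
  esum <- NULL
  if (!is.null(en) && nrow(en) > 0) {
    esum <- list(
      e_vdw_pp = msem(en$e_vdw_pp), e_es_pp = msem(en$e_es_pp),
      e_tot_pp = msem(en$e_vdw_pp + en$e_es_pp),
      e_vdw_pw = msem(en$e_vdw_pw), e_es_pw = msem(en$e_es_pw),
      e_tot_pw = msem(en$e_vdw_pw + en$e_es_pw))
  }
  ss <- secondary_structure_frequencies(trajectory, topology)
  r100 <- function(v) tryCatch(suppressWarnings(rmsd100(v, nres)),
                               error = function(e) NA_real_)
  structure(list(
    rmsd = rmsd_s,
    rmsd100 = list(mean = r100(rmsd_s$mean), sem = r100(rmsd_s$sem)),
    rmsf = list(mean = mean(rmsf_v), per_atom = rmsf_v),
    rgyr = msem(rg_t),
    head_to_tail = msem(h2t_t),
    n_hb_pp = msem(hb$n_hb_pp),
    n_hb_pp_backbone = msem(hb$n_hb_pp_backbone),
    n_hb_pw = msem(hb$n_hb_pw),
    sasa_total = msem(vapply(sasa_t, `[[`, numeric(1), "total")),
    sasa_polar = msem(vapply(sasa_t, `[[`, numeric(1), "polar")),
    sasa_nonpolar = msem(vapply(sasa_t, `[[`, numeric(1), "nonpolar")),
    helix_frequency = ss$helix, sheet_frequency = ss$sheet,
    coil_frequency = ss$coil,
    energy = esum, n_frames = length(frames), n_residues = nres),
    class = "analysis_summary")
}

# accept either an mw_trajectory or a bare list of coordinate matrices
traj_frames <- function(trajectory) {
  if (inherits(trajectory, "mw_trajectory")) trajectory$frames
  else if (is.list(trajectory)) trajectory
  else stop("not a trajectory")
}
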