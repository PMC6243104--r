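# Per-state structural characterization: hydrogen bonds, Shrake-Rupley
# solvent-accessible surface area, Kabsch superposition and RMSD lookup.

# Bondi van der Waals radii (Angstrom). VMD's internal radii differ
# slightly, so absolute SASA values computed here can differ from VMD's by
# a few percent on the same coordinates.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

atomic_radii <- function(elements) {
  r <- BONDI_RADII[toupper(elements)]
  if (any(is.na(r))) {
    abort(paste0("no van der Waals radius tabulated for element(s): ",
                 paste(unique(elements[is.na(r)]), collapse = ", ")),
          "radius_error")
  }
  unname(r)
}

# Deterministic, seedless quasi-uniform sphere points (golden-section /
# Fibonacci lattice).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

hbond_partners <- function(topology, coords) {
  # H atoms are bonded to the nearest N/O heavy atom within 1.25 A.
  h_idx <- which(topology$element == "H")
  heavy <- which(topology$element %in% c("N", "O"))
  bonds <- list()
  if (length(h_idx) > 0 && length(heavy) > 0) {
    D <- sqrt(dist_sq(coords[h_idx, , drop = FALSE], coords[heavy, , drop = FALSE]))
    nearest <- max.col(-D, ties.method = "first")
    ok <- D[cbind(seq_along(h_idx), nearest)] <= 1.25
    bonds <- data.frame(h = h_idx[ok], donor = heavy[nearest[ok]])
  } else {
    bonds <- data.frame(h = integer(0), donor = integer(0))
  }
  donors <- unique(bonds$donor)
  # acceptors: all O; N only when it carries no hydrogen (documented
  # N/O-based rule rather than force-field typing)
  n_no_h <- setdiff(which(topology$element == "N"), donors)
  acceptors <- sort(c(which(topology$element == "O"), n_no_h))
  list(bonds = bonds, donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in one frame
#'
#' A bond is reported when the donor-acceptor distance is at most
#' `dist_cutoff` and the D-H...A angle deviates from linearity (180 deg) by
#' at most `angle_cutoff` — the convention used by VMD's hydrogen-bond
#' criterion. Donors are N/O atoms carrying a hydrogen (found by a 1.25 A
#' covalent-distance rule); acceptors are O atoms plus N atoms without
#' hydrogens. Pairs within one residue are excluded.
#'
#' @param coords Atoms x 3 coordinate matrix (Angstrom).
#' @param topology Topology data.frame (see [read_pdb()]); hydrogens must
#'   be present.
#' @param dist_cutoff Donor-acceptor distance cutoff in Angstrom
#'   (default 3.2).
#' @param angle_cutoff Deviation-from-linearity cutoff in degrees
#'   (default 20).
#' @return data.frame(donor, hydrogen, acceptor, donor_label,
#'   acceptor_label, distance, angle_dev).
#' @export
find_hbonds <- function(coords, topology, dist_cutoff = 3.2, angle_cutoff = 20) {
  coords <- as.matrix(coords)
  if (!any(topology$element == "H")) {
    abort("no hydrogens in topology; hydrogen-bond detection requires explicit hydrogens",
          "hbond_error")
  }
  hp <- hbond_partners(topology, coords)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
                      donor_label = character(0), acceptor_label = character(0),
                      distance = numeric(0), angle_dev = numeric(0))
  if (nrow(hp$bonds) == 0 || length(hp$acceptors) == 0) return(empty)
  out <- list()
  lab <- function(i) sprintf("%s%d:%s", topology$chain[i], topology$resid[i], topology$name[i])
  reskey <- paste(topology$chain, topology$resid)
  for (b in seq_len(nrow(hp$bonds))) {
    d <- hp$bonds$donor[b]; h <- hp$bonds$h[b]
    acc <- hp$acceptors[reskey[hp$acceptors] != reskey[d]]
    if (length(acc) == 0) next
    da <- sqrt(dist_sq(coords[d, , drop = FALSE], coords[acc, , drop = FALSE]))[1, ]
    near <- acc[da <= dist_cutoff]
    if (length(near) == 0) next
    hd <- coords[d, ] - coords[h, ]
    ha <- coords[near, , drop = FALSE] - matrix(coords[h, ], length(near), 3, byrow = TRUE)
    cosang <- (ha %*% hd) / (sqrt(sum(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- rad2deg(acos(pmin(1, pmax(-1, cosang))))   # angle at H
    dev <- 180 - ang
    keep <- dev <= angle_cutoff
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      donor = d, hydrogen = h, acceptor = near[keep],
      donor_label = lab(d), acceptor_label = lab(near[keep]),
      distance = da[match(near[keep], acc)], angle_dev = dev[keep]
    )
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond occupancy per macrostate
#'
#' Fraction of the frames assigned to each state in which a given
#' donor-acceptor pair is bonded.
#'
#' @param bond_lists List (one per frame, in stacked frame order) of
#'   data.frames from [find_hbonds()].
#' @param state_labels Integer state label per frame (NA = unassigned).
#' @param donor_label,acceptor_label Labels as produced by [find_hbonds()]
#'   (e.g. `"A93:OG"`, `"B207:O"`).
#' @return data.frame(state, n_frames, occupancy); states with no frames
#'   get `NA` occupancy (flagged, not dropped).
#' @export
hbond_occupancy <- function(bond_lists, state_labels, donor_label, acceptor_label) {
  if (length(bond_lists) != length(state_labels)) {
    abort("bond_lists and state_labels must have one entry per frame", "argument_error")
  }
  present <- vapply(bond_lists, function(b) {
    nrow(b) > 0 && any(b$donor_label == donor_label & b$acceptor_label == acceptor_label)
  }, logical(1))
  states <- sort(unique(state_labels[!is.na(state_labels)]))
  out <- data.frame(state = states,
                    n_frames = vapply(states, function(s) sum(state_labels == s, na.rm = TRUE), numeric(1)))
  out$occupancy <- vapply(states, function(s) {
    i <- which(state_labels == s)
    if (length(i) == 0) NA_real_ else mean(present[i])
  }, numeric(1))
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the selected atoms using a fixed
#' golden-section point set (seedless, deterministic). Only the selected
#' atoms participate: both as area contributors and as occluders, matching
#' the convention of computing a loop's SASA with only the loop included
#' in the calculation.
#'
#' @param coords Atoms x 3 coordinate matrix (Angstrom).
#' @param topology Topology data.frame (for elements).
#' @param selection Optional `loop_selection` or integer atom indices
#'   (default: all atoms).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @return list(total = total SASA in Angstrom^2, per_atom).
#' @export
shrake_rupley_sasa <- function(coords, topology, selection = NULL,
                               probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  idx <- if (is.null(selection)) seq_len(nrow(coords))
         else if (inherits(selection, "loop_selection")) selection$atoms
         else as.integer(selection)
  R <- atomic_radii(topology$element[idx]) + probe
  P <- coords[idx, , drop = FALSE]
  pts <- sphere_points(n_points)
  per_atom <- numeric(length(idx))
  for (a in seq_along(idx)) {
    sp <- pts * R[a]
    sp <- sweep(sp, 2, P[a, ], "+")
    others <- setdiff(seq_along(idx), a)
    if (length(others) > 0) {
      d2 <- dist_sq(matrix(P[a, ], 1), P[others, , drop = FALSE])[1, ]
      near <- others[d2 < (R[a] + R[others])^2]
    } else near <- integer(0)
    acc <- rep(TRUE, n_points)
    for (o in near) {
      if (!any(acc)) break
      d2o <- dist_sq(sp[acc, , drop = FALSE], P[o, , drop = FALSE])[, 1]
      acc[acc] <- d2o >= R[o]^2
    }
    per_atom[a] <- mean(acc) * 4 * pi * R[a]^2
  }
  list(total = sum(per_atom), per_atom = per_atom, atoms = idx)
}

#' Kabsch optimal superposition
#'
#' Closed-form least-squares rigid alignment of `P` onto `Q` (paired rows),
#' with the determinant correction that excludes reflections.
#'
#' @param P,Q n x 3 coordinate matrices with corresponding rows.
#' @return list(R = 3 x 3 rotation, t = translation such that
#'   `P %*% R + t` superposes onto `Q`, rmsd = post-alignment RMSD).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)   # so that P %*% R aligns onto Q
  t_vec <- cq - cp %*% R
  aligned <- P %*% R + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  list(R = R, t = drop(t_vec), rmsd = sqrt(mean(rowSums((aligned - Q)^2))),
       aligned = aligned)
}

match_atoms <- function(top_a, top_b) {
  key <- function(tp) paste(tp$chain, tp$resid, tp$name, sep = "|")
  ka <- key(top_a); kb <- key(top_b)
  m <- match(ka, kb)
  if (any(is.na(m))) {
    abort(paste0("atom correspondence failure; unmatched: ",
                 paste(utils::head(ka[is.na(m)], 10), collapse = ", ")),
          "mapping_error")
  }
  m
}

#' Nearest simulation frame to a reference conformation by RMSD
#'
#' Every frame is superposed onto the reference with the Kabsch algorithm
#' over `align_sel` (e.g. a stable domain), then the RMSD is evaluated over
#' `rmsd_sel` (e.g. loop C-alpha atoms). Atom correspondence is resolved by
#' (chain, resid, atom name).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param reference A structure as returned by [read_pdb()] (first frame
#'   used).
#' @param align_sel,rmsd_sel `loop_selection`s or integer atom index
#'   vectors into the ensemble topology (`rmsd_sel` default: `align_sel`).
#' @return list(trajectory, frame, rmsd, rmsd_all = list of per-frame RMSD
#'   vectors).
#' @export
nearest_frame_by_rmsd <- function(ensemble, reference, align_sel, rmsd_sel = NULL) {
  as_idx <- function(s) if (inherits(s, "loop_selection")) s$atoms else as.integer(s)
  ai <- as_idx(align_sel)
  ri <- if (is.null(rmsd_sel)) ai else as_idx(rmsd_sel)
  map <- match_atoms(ensemble$topology, reference$topology)
  ref <- reference$coords[1, , ]
  ref_a <- ref[map[ai], , drop = FALSE]
  ref_r <- ref[map[ri], , drop = FALSE]
  best <- list(trajectory = NA_integer_, frame = NA_integer_, rmsd = Inf)
  rmsd_all <- vector("list", length(ensemble$coords))
  for (t in seq_along(ensemble$coords)) {
    tr <- ensemble$coords[[t]]
    nf <- dim(tr)[1]
    rms <- numeric(nf)
    for (f in seq_len(nf)) {
      fit <- kabsch(tr[f, ai, ], ref_a)
      moved <- tr[f, ri, ] %*% fit$R + matrix(fit$t, length(ri), 3, byrow = TRUE)
      rms[f] <- sqrt(mean(rowSums((moved - ref_r)^2)))
    }
    rmsd_all[[t]] <- rms
    if (min(rms) < best$rmsd) {
      best <- list(trajectory = t, frame = which.min(rms), rmsd = min(rms))
    }
  }
  c(best, list(rmsd_all = rmsd_all))
}

#' Centroid phi/psi table in degrees
#'
#' Backbone dihedrals of representative (centroid) frames, reported per
#' state and residue in degrees for side-by-side comparison of macrostate
#' geometries. Undefinable terminal angles are `NA`, not fabricated.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param centroids data.frame(state, trajectory, frame).
#' @param selection A `loop_selection`.
#' @return data.frame(state, chain, resid, resname, angle, value_deg).
#' @export
centroid_dihedral_table <- function(ensemble, centroids, selection) {
  out <- list()
  for (i in seq_len(nrow(centroids))) {
    tr <- ensemble$coords[[centroids$trajectory[i]]]
    one <- ensemble_from_arrays(
      list(array(tr[centroids$frame[i], , ], dim = c(1, dim(tr)[2], 3))),
      ensemble$topology, ensemble$frame_interval)
    ser <- backbone_dihedrals(one, selection)
    out[[i]] <- data.frame(state = centroids$state[i], ser$info,
                           value_deg = rad2deg(ser$angles[[1]][1, ]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
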