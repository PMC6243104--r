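# Backbone dihedral featurization.
#
# phi(i) = dihedral(C[i-1], N[i], CA[i], C[i])
# psi(i) = dihedral(N[i], CA[i], C[i], N[i+1])
# Angles are radians on (-pi, pi]; the IUPAC sign convention of the
# standard atan2 formula is used.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Dihedral angle of four points
#'
#' Vectorized over rows: each argument is an n x 3 matrix (or length-3
#' vector). Returns the signed torsion about the p2-p3 axis in radians.
#'
#' @param p1,p2,p3,p4 Coordinates (n x 3 matrices or length-3 vectors).
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, nrow = 1) else p
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross3(b2n, n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(y, x))
}

#' Backbone phi/psi time series for a loop selection
#'
#' Computes per-frame phi and psi for every selected residue where the four
#' required atoms exist (phi needs the preceding residue's C, psi the
#' following residue's N; the flanking residues need not themselves be
#' selected). Angles undefinable at chain termini are omitted and recorded
#' in the `omitted` attribute rather than fabricated.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param selection A `loop_selection`.
#' @return A `dihedral_series`: list(angles = list of frames x n_angles
#'   matrices in radians, info = data.frame(chain, resid, resname, angle),
#'   frame_interval).
#' @export
backbone_dihedrals <- function(ensemble, selection) {
  top <- ensemble$topology
  find_atom <- function(serial_resid, name) {
    i <- which(top$serial_resid == serial_resid & top$name == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  res <- selection$residues
  defs <- list(); omitted <- character(0)
  for (r in seq_len(nrow(res))) {
    sr <- res$serial_resid[r]
    lab <- sprintf("%s%d", res$chain[r], res$resid[r])
    n_i <- find_atom(sr, "N"); ca_i <- find_atom(sr, "CA"); c_i <- find_atom(sr, "C")
    if (any(is.na(c(n_i, ca_i, c_i)))) {
      abort(sprintf("residue %s lacks backbone atoms needed for dihedrals", lab),
            "featurization_error")
    }
    # previous/next residues by contiguous serial numbering within a chain
    prev_ok <- sr > 1 && top$chain[match(sr - 1L, top$serial_resid)] == res$chain[r]
    nxt_ok <- any(top$serial_resid == sr + 1L) &&
      top$chain[match(sr + 1L, top$serial_resid)] == res$chain[r]
    cprev <- if (prev_ok) find_atom(sr - 1L, "C") else NA_integer_
    nnext <- if (nxt_ok) find_atom(sr + 1L, "N") else NA_integer_
    if (!is.na(cprev)) {
      defs[[length(defs) + 1]] <- list(chain = res$chain[r], resid = res$resid[r],
                                       resname = res$resname[r], angle = "phi",
                                       atoms = c(cprev, n_i, ca_i, c_i))
    } else omitted <- c(omitted, paste0("phi ", lab))
    if (!is.na(nnext)) {
      defs[[length(defs) + 1]] <- list(chain = res$chain[r], resid = res$resid[r],
                                       resname = res$resname[r], angle = "psi",
                                       atoms = c(n_i, ca_i, c_i, nnext))
    } else omitted <- c(omitted, paste0("psi ", lab))
  }
  if (length(defs) == 0) abort("no definable dihedrals in selection", "featurization_error")
  info <- data.frame(
    chain = vapply(defs, `[[`, character(1), "chain"),
    resid = as.integer(vapply(defs, function(d) as.numeric(d$resid), numeric(1))),
    resname = vapply(defs, `[[`, character(1), "resname"),
    angle = vapply(defs, `[[`, character(1), "angle"),
    stringsAsFactors = FALSE
  )
  angles <- lapply(ensemble$coords, function(tr) {
    out <- matrix(NA_real_, nrow = dim(tr)[1], ncol = length(defs))
    for (j in seq_along(defs)) {
      a <- defs[[j]]$atoms
      out[, j] <- dihedral_angle(tr[, a[1], ], tr[, a[2], ],
                                 tr[, a[3], ], tr[, a[4], ])
    }
    out
  })
  structure(list(angles = angles, info = info,
                 frame_interval = ensemble$frame_interval, omitted = omitted),
            class = "dihedral_series")
}

#' Construct a dihedral series from angle matrices
#'
#' Used by the synthetic generator and by tests that start from angles
#' rather than Cartesian coordinates.
#'
#' @param angles List of frames x n_angles matrices (radians).
#' @param info data.frame(chain, resid, resname, angle), one row per column.
#' @param frame_interval Frame spacing in ns.
#' @export
dihedral_series <- function(angles, info, frame_interval) {
  if (!is.list(angles)) angles <- list(angles)
  stopifnot(all(vapply(angles, ncol, integer(1)) == nrow(info)))
  structure(list(angles = lapply(angles, function(a) wrap_angle(a)),
                 info = info, frame_interval = frame_interval,
                 omitted = character(0)),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %d trajectories, %d angles (%d phi, %d psi)\n",
              length(x$angles), nrow(x$info),
              sum(x$info$angle == "phi"), sum(x$info$angle == "psi")))
  invisible(x)
}

angle_names <- function(info) {
  sprintf("%s_%s%d", info$angle, info$chain, info$resid)
}

#' Circular (sin, cos) embedding of a dihedral series
#'
#' Maps each angle theta to the pair (sin theta, cos theta) so that linear
#' covariance analysis is well defined on the circle: raw angles have a
#' branch cut at +/-pi where a small physical motion looks like a jump of
#' 2*pi. The mapping is invertible up to angle identity via atan2.
#'
#' @param series A `dihedral_series`.
#' @param mode `"sincos"` (default) or `"raw"` (angles used as-is; only
#'   sensible when all angles stay far from the branch cut).
#' @return A `feature_matrix`: list(data = list of frames x d matrices,
#'   names, mode, info, frame_interval).
#' @export
circular_embed <- function(series, mode = c("sincos", "raw")) {
  mode <- match.arg(mode)
  nm <- angle_names(series$info)
  if (mode == "raw") {
    dat <- series$angles
    names_out <- nm
  } else {
    dat <- lapply(series$angles, function(a) {
      out <- matrix(NA_real_, nrow = nrow(a), ncol = 2 * ncol(a))
      out[, seq(1, 2 * ncol(a), by = 2)] <- sin(a)
      out[, seq(2, 2 * ncol(a), by = 2)] <- cos(a)
      out
    })
    names_out <- as.vector(rbind(paste0("sin_", nm), paste0("cos_", nm)))
  }
  structure(list(data = dat, names = names_out, mode = mode,
                 info = series$info, frame_interval = series$frame_interval),
            class = "feature_matrix")
}

#' Export a dihedral series as long-format CSV
#'
#' Columns: trajectory, frame, chain, resid, angle, value_deg.
#'
#' @param series A `dihedral_series`.
#' @param path Output CSV path.
#' @export
export_dihedrals <- function(series, path) {
  nm <- angle_names(series$info)
  rows <- lapply(seq_along(series$angles), function(t) {
    a <- series$angles[[t]]
    data.frame(
      trajectory = t,
      frame = rep(seq_len(nrow(a)), times = ncol(a)),
      chain = rep(series$info$chain, each = nrow(a)),
      resid = rep(series$info$resid, each = nrow(a)),
      angle = rep(series$info$angle, each = nrow(a)),
      value_deg = rad2deg(as.vector(a))
    )
  })
  write_table(do.call(rbind, rows), path)
}
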