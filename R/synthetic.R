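# Synthetic dihedral trajectories with known metastable structure.
#
# The generator emulates exactly the statistical structure the analysis
# assumes: a hidden Markov chain over K metastable states at the frame
# level, with independent von Mises emissions per backbone angle around
# state-specific means. It produces the multi-trajectory phi/psi series the
# pipeline consumes, plus the true hidden labels for parameter-recovery
# tests. It does not attempt realistic Cartesian loop ensembles (no loop
# closure); toy Cartesian fixtures for the structural operators are built
# separately by make_toy_structures().

#' Draw from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; circular analogue of the normal
#' distribution with mean direction `mu` and concentration `kappa`
#' (circular variance ~ 1/kappa for large kappa).
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (> 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) abort("kappa must be positive", "argument_error")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 10
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    out <- c(out, theta)
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Specify a synthetic hidden-Markov dihedral world
#'
#' @param T_true K x K row-stochastic transition matrix of the hidden chain
#'   at unit frame lag.
#' @param means K x n_angles matrix of state mean dihedrals (radians).
#' @param kappa Von Mises concentration, scalar or per-state vector.
#' @param n_trajectories Number of independent trajectories.
#' @param n_frames Frames per trajectory.
#' @param frame_interval Frame spacing in ns.
#' @param seed RNG seed; the entire data set is reproducible from it.
#' @param info Optional angle annotation data.frame(chain, resid, resname,
#'   angle); defaults to phi/psi pairs of consecutive residues.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(T_true, means, kappa, n_trajectories, n_frames,
                           frame_interval, seed, info = NULL) {
  T_true <- as.matrix(T_true); dimnames(T_true) <- NULL
  means <- as.matrix(means); dimnames(means) <- NULL
  K <- nrow(T_true)
  if (ncol(T_true) != K || any(T_true < 0) || any(abs(rowSums(T_true) - 1) > 1e-10)) {
    abort("T_true must be a square row-stochastic matrix", "spec_error")
  }
  if (nrow(means) != K) abort("means must have one row per hidden state", "spec_error")
  if (any(kappa <= 0)) abort("kappa must be positive", "spec_error")
  kappa <- rep(kappa, length.out = K)
  n_angles <- ncol(means)
  if (is.null(info)) {
    n_res <- ceiling(n_angles / 2)
    info <- data.frame(
      chain = "B",
      resid = rep(205 + seq_len(n_res) - 1, each = 2)[seq_len(n_angles)],
      resname = "ALA",
      angle = rep(c("phi", "psi"), n_res)[seq_len(n_angles)]
    )
  }
  structure(list(K = K, T_true = T_true, means = wrap_angle(means),
                 kappa = kappa, n_trajectories = as.integer(n_trajectories),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed),
                 info = info),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> K = %d states, %d x %d frames, %d angles, seed %d\n",
              x$K, x$n_trajectories, x$n_frames, ncol(x$means), x$seed))
  invisible(x)
}

#' Default four-state synthetic world
#'
#' Emulates a loop with four metastable backbone conformations sampled by
#' ten independent trajectories: a hidden chain with self-transition
#' probabilities between 0.987 and 0.995 whose three relaxation timescales
#' (128, 107, 55 frames) are well separated from the frame-level noise; a
#' hub-like state 2 that is the only state exchanging with all others; a
#' dominant state 4 (stationary population 0.47) and a sparsely populated
#' state 1 (0.07). Emissions are von Mises (kappa = 25, circular sd about
#' 11.5 degrees) around four backbone conformations that differ in most of
#' the 12 phi/psi angles of a six-residue loop. The frame interval is 1 ns
#' so the default analysis lags (5/8/115 ns) probe the same regimes,
#' relative to the slow timescales, as in a real loop analysis.
#'
#' @param seed RNG seed (default 2018).
#' @return A `synthetic_spec`.
#' @export
default_4state_spec <- function(seed = 2018) {
  T_true <- rbind(
    c(0.98950, 0.00700, 0.00350, 0.00000),
    c(0.00300, 0.98650, 0.00300, 0.00750),
    c(0.00090, 0.00140, 0.99400, 0.00370),
    c(0.00000, 0.00280, 0.00220, 0.99500)
  )
  # four backbone conformations (degrees): extended, helical, left-handed
  # mix, irregular turn; phi/psi interleaved over six residues
  means_deg <- rbind(
    c(-140, 135, -130, 140, -120, 125, -135, 130, -125, 145, -130, 135),
    c( -60, -45,  -65, -40,  -58, -48,  -62, -42,  -60, -45,  -63, -38),
    c(  60,  40,   55,  45,  -75, 150,   65,  35,  -70, 160,   58,  42),
    c( -90,   0,   70, -60, -100, 100,  -60, -30, -150, 155,   80, -10)
  )
  synthetic_spec(T_true = T_true, means = deg2rad(means_deg), kappa = 25,
                 n_trajectories = 10, n_frames = 30000,
                 frame_interval = 1, seed = seed)
}

sample_chain <- function(T_true, n, start_dist) {
  K <- nrow(T_true)
  cum <- t(apply(T_true, 1, cumsum))
  s <- integer(n)
  u <- stats::runif(n)
  s[1] <- findInterval(u[1], cumsum(start_dist)) + 1L
  if (s[1] > K) s[1] <- K
  if (n < 2) return(s)
  for (t in 2:n) {
    s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
    if (s[t] > K) s[t] <- K
  }
  s
}

#' Generate hidden-Markov von Mises dihedral trajectories
#'
#' Each trajectory samples its hidden chain from `T_true`, started from the
#' chain's stationary distribution, then draws every angle independently
#' from a von Mises around the hidden state's mean.
#'
#' @param spec A `synthetic_spec`.
#' @return list(series = `dihedral_series`, hidden = list of true hidden
#'   label vectors, spec).
#' @export
generate_hmm_trajectories <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("spec must be a synthetic_spec", "spec_error")
  pi0 <- stationary_distribution(spec$T_true)
  n_angles <- ncol(spec$means)
  with_seed(spec$seed, {
    hidden <- vector("list", spec$n_trajectories)
    angles <- vector("list", spec$n_trajectories)
    for (tr in seq_len(spec$n_trajectories)) {
      s <- sample_chain(spec$T_true, spec$n_frames, pi0)
      A <- matrix(NA_real_, spec$n_frames, n_angles)
      for (k in seq_len(spec$K)) {
        idx <- which(s == k)
        if (length(idx) == 0) next
        for (j in seq_len(n_angles)) {
          A[idx, j] <- rvonmises(length(idx), spec$means[k, j], spec$kappa[k])
        }
      }
      hidden[[tr]] <- s
      angles[[tr]] <- A
    }
    list(series = dihedral_series(angles, spec$info, spec$frame_interval),
         hidden = hidden, spec = spec)
  })
}

# --- toy Cartesian fixtures -------------------------------------------------

# Place a fourth atom from three predecessors by internal coordinates
# (NeRF): bond length, bond angle at `c`, and torsion about b-c.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg); tor <- deg2rad(torsion_deg)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an idealized backbone from phi/psi angles
#'
#' Constructs N-CA-C backbone (plus carbonyl O) Cartesian coordinates for a
#' polyalanine-like chain with ideal bond lengths and angles and trans
#' peptide bonds, so that measuring the dihedrals of the result returns the
#' requested phi/psi (construction by inverse).
#'
#' @param phi,psi Vectors of backbone torsions in degrees (length =
#'   residue count; `phi[1]` and `psi[n]` are unused/undefined).
#' @param chain Chain identifier (default "A").
#' @return list(topology, coords (1 x atoms x 3)) as from [read_pdb()].
#' @export
build_backbone <- function(phi, psi, chain = "A") {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  coords <- list(); atoms <- list()
  add <- function(xyz, name, resid, element) {
    coords[[length(coords) + 1]] <<- xyz
    atoms[[length(atoms) + 1]] <<- data.frame(name = name, resid = resid,
                                              element = element)
  }
  # first residue: N at origin, CA on x, C in the xy-plane
  add(c(0, 0, 0), "N", 1, "N")
  add(c(b_nca, 0, 0), "CA", 1, "C")
  ang <- deg2rad(a_ncac)
  add(c(b_nca - b_cac * cos(ang), b_cac * sin(ang), 0), "C", 1, "C")
  get_xyz <- function(i) coords[[i]]
  idx_of <- function(resid, name) {
    for (i in seq_along(atoms)) {
      if (atoms[[i]]$resid == resid && atoms[[i]]$name == name) return(i)
    }
    NA_integer_
  }
  for (r in seq_len(n_res)) {
    n_i <- idx_of(r, "N"); ca_i <- idx_of(r, "CA"); c_i <- idx_of(r, "C")
    # carbonyl O: torsion psi + 180 about CA-C from N
    o_tor <- if (r < n_res) psi[r] + 180 else 0
    add(place_atom(get_xyz(n_i), get_xyz(ca_i), get_xyz(c_i), b_co, a_caco, o_tor),
        "O", r, "O")
    if (r == n_res) break
    # next N: torsion psi(r) about CA-C
    add(place_atom(get_xyz(n_i), get_xyz(ca_i), get_xyz(c_i), b_cn, a_cacn, psi[r]),
        "N", r + 1, "N")
    nn_i <- idx_of(r + 1, "N")
    # next CA: omega = 180 (trans) about C-N
    add(place_atom(get_xyz(ca_i), get_xyz(c_i), get_xyz(nn_i), b_nca, a_cnca, 180),
        "CA", r + 1, "C")
    nca_i <- idx_of(r + 1, "CA")
    # next C: torsion phi(r+1) about N-CA
    add(place_atom(get_xyz(c_i), get_xyz(nn_i), get_xyz(nca_i), b_cac, a_ncac, phi[r + 1]),
        "C", r + 1, "C")
  }
  tab <- do.call(rbind, atoms)
  topology <- data.frame(serial = seq_len(nrow(tab)), name = tab$name,
                         resname = "ALA", chain = chain, resid = tab$resid,
                         element = tab$element,
                         serial_resid = tab$resid, stringsAsFactors = FALSE)
  co <- do.call(rbind, coords)
  list(topology = topology, coords = array(co, dim = c(1, nrow(co), 3)))
}

#' Build a donor-H-acceptor hydrogen-bond test geometry
#'
#' Places an N-H donor group and an acceptor O so that the donor-acceptor
#' distance is exactly `dist` Angstrom and the D-H...A deviation from
#' linearity is exactly `angle_dev` degrees.
#'
#' @param dist Donor-acceptor distance (Angstrom).
#' @param angle_dev Deviation from linearity (degrees).
#' @return list(topology, coords (1 x 3 x 3)).
#' @export
build_hbond_triad <- function(dist, angle_dev) {
  d <- deg2rad(angle_dev)
  Dxyz <- c(0, 0, 0); Hxyz <- c(0, 0, 1.0)
  L <- -cos(d) + sqrt(cos(d)^2 - 1 + dist^2)
  Axyz <- Hxyz + L * c(sin(d), 0, cos(d))
  topology <- data.frame(
    serial = 1:3, name = c("N", "H", "O"), resname = c("GLY", "GLY", "GLY"),
    chain = "A", resid = c(1L, 1L, 2L), element = c("N", "H", "O"),
    serial_resid = c(1L, 1L, 2L), stringsAsFactors = FALSE
  )
  co <- rbind(Dxyz, Hxyz, Axyz)
  list(topology = topology, coords = array(co, dim = c(1, 3, 3)))
}

#' Write toy PDB fixtures for the structural operators
#'
#' Writes, under `dir`: a 6-residue idealized backbone at known phi/psi
#' (`peptide.pdb`) plus a rigidly rotated and translated copy
#' (`peptide_rt.pdb`), hydrogen-bond triads straddling the cutoffs
#' (`hbond_*.pdb`), and 1- and 2-atom SASA fixtures (`sphere*.pdb`).
#'
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths.
#' @export
make_toy_structures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c()
  phi <- c(NA, -60, -120, 60, -90, -140); phi[1] <- 0
  psi <- c(-45, 130, 40, -30, 155, 0)
  pep <- build_backbone(phi, psi)
  out["peptide"] <- write_pdb(pep$topology, pep$coords, file.path(dir, "peptide.pdb"))
  th <- deg2rad(35); ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- pep$coords[1, , ] %*% R + matrix(c(5, -3, 8), dim(pep$coords)[2], 3, byrow = TRUE)
  out["peptide_rt"] <- write_pdb(pep$topology, array(moved, dim = dim(pep$coords)),
                                 file.path(dir, "peptide_rt.pdb"))
  for (case in list(c("good", 2.9, 5), c("bent", 2.9, 25), c("far", 3.3, 0))) {
    tri <- build_hbond_triad(as.numeric(case[2]), as.numeric(case[3]))
    out[paste0("hbond_", case[1])] <- write_pdb(tri$topology, tri$coords,
                                                file.path(dir, paste0("hbond_", case[1], ".pdb")))
  }
  one <- data.frame(serial = 1L, name = "C", resname = "UNK", chain = "A",
                    resid = 1L, element = "C", serial_resid = 1L)
  out["sphere1"] <- write_pdb(one, matrix(c(0, 0, 0), 1, 3), file.path(dir, "sphere1.pdb"))
  two <- data.frame(serial = 1:2, name = c("C", "C"), resname = "UNK", chain = "A",
                    resid = 1:2, element = "C", serial_resid = 1:2)
  out["sphere2"] <- write_pdb(two, rbind(c(0, 0, 0), c(2, 0, 0)), file.path(dir, "sphere2.pdb"))
  out
}
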