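# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# Standard projection formula for a torsion angle (independent of the
# package's cross-product implementation).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  cx <- c(b1[2] * v[3] - b1[3] * v[2],
          b1[3] * v[1] - b1[1] * v[3],
          b1[1] * v[2] - b1[2] * v[1])
  atan2(sum(cx * w), sum(v * w))
}

# Dense generalized-eigenproblem solve via explicit inverse (oracle for
# the Cholesky-based tICA path).
oracle_generalized_eigen <- function(Ct, C0) {
  e <- eigen(solve(C0) %*% Ct)
  sort(Re(e$values), decreasing = TRUE)
}

# Explicit double-loop transition counting.
oracle_count <- function(s, lag, n) {
  C <- matrix(0, n, n)
  for (t in seq_len(length(s) - lag)) {
    C[s[t], s[t + lag]] <- C[s[t], s[t + lag]] + 1
  }
  C
}

# Kosaraju strongly-connected-components (no igraph).
oracle_scc <- function(adj) {
  n <- nrow(adj)
  visited <- rep(FALSE, n); order <- integer(0)
  dfs1 <- function(v) {
    stack <- v
    path <- integer(0)
    # iterative DFS with post-order
    state <- rep(0L, n)
    st <- c(v)
    while (length(st) > 0) {
      u <- st[length(st)]
      if (!visited[u]) {
        visited[u] <<- TRUE
        nb <- which(adj[u, ] & !visited)
        st <- c(st, nb)
      } else {
        st <- st[-length(st)]
        if (state[u] == 0L) { state[u] <- 1L; order <<- c(order, u) }
      }
    }
  }
  for (v in seq_len(n)) if (!visited[v]) dfs1(v)
  comp <- rep(0L, n); c_id <- 0L
  for (v in rev(order)) {
    if (comp[v] != 0L) next
    c_id <- c_id + 1L
    st <- c(v)
    while (length(st) > 0) {
      u <- st[length(st)]; st <- st[-length(st)]
      if (comp[u] != 0L) next
      comp[u] <- c_id
      st <- c(st, which(adj[, u] & comp == 0L))
    }
  }
  comp
}

# Reversible 2-state MLE by brute-force likelihood grid search over
# (T12, T21), refined around the optimum.
oracle_rev_mle_2state <- function(C) {
  loglik <- function(t12, t21) {
    Tm <- rbind(c(1 - t12, t12), c(t21, 1 - t21))
    if (any(Tm <= 0)) return(-Inf)
    sum(C * log(Tm))
  }
  lo <- c(1e-4, 1e-4); hi <- c(1 - 1e-4, 1 - 1e-4)
  best <- c(0.5, 0.5)
  for (round in 1:8) {
    g1 <- seq(lo[1], hi[1], length.out = 60)
    g2 <- seq(lo[2], hi[2], length.out = 60)
    ll <- outer(g1, g2, Vectorize(loglik))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    span <- (hi - lo) / 10
    lo <- pmax(c(1e-6, 1e-6), best - span)
    hi <- pmin(c(1 - 1e-6, 1 - 1e-6), best + span)
  }
  rbind(c(1 - best[1], best[1]), c(best[2], 1 - best[2]))
}

# Quaternion (Kearsley) optimal-superposition RMSD oracle.
oracle_quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  xm <- Pc[, 1] - Qc[, 1]; ym <- Pc[, 2] - Qc[, 2]; zm <- Pc[, 3] - Qc[, 3]
  xp <- Pc[, 1] + Qc[, 1]; yp <- Pc[, 2] + Qc[, 2]; zp <- Pc[, 3] + Qc[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  K[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  K[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  K[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  K[1, 2] <- K[2, 1] <- sum(yp * zm - ym * zp)
  K[1, 3] <- K[3, 1] <- sum(xm * zp - xp * zm)
  K[1, 4] <- K[4, 1] <- sum(xp * ym - xm * yp)
  K[2, 3] <- K[3, 2] <- sum(xm * ym - xp * yp)
  K[2, 4] <- K[4, 2] <- sum(xm * zm - xp * zp)
  K[3, 4] <- K[4, 3] <- sum(ym * zm - yp * zp)
  lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, lam) / nrow(P))
}

# Analytic SASA of two identical spheres of radius R at center distance d:
# each sphere loses a cap of height h = R - d/2.
oracle_two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Tiny Cartesian ensemble: jittered copies of an idealized backbone.
toy_ensemble <- function(n_traj = 2, n_frames = 4, n_res = 6, seed = 42,
                         jitter = 0.01) {
  phi <- c(0, -60, -120, 60, -90, -140)[seq_len(n_res)]
  psi <- c(-45, 130, 40, -30, 155, 0)[seq_len(n_res)]
  bb <- build_backbone(phi, psi)
  na <- dim(bb$coords)[2]
  withr::with_seed(seed, {
    coords <- lapply(seq_len(n_traj), function(t) {
      arr <- array(NA_real_, dim = c(n_frames, na, 3))
      for (f in seq_len(n_frames)) {
        arr[f, , ] <- bb$coords[1, , ] + stats::rnorm(na * 3, sd = jitter)
      }
      arr
    })
    ensemble_from_arrays(coords, bb$topology, frame_interval = 0.5)
  })
}

# Cartesian ensemble hopping between two backbone conformations with a
# sticky hidden chain, so structural pipeline stages see metastable input.
toy_metastable_ensemble <- function(n_traj = 2, n_frames = 150, seed = 99,
                                    stay = 0.95, jitter = 0.02) {
  phiA <- c(0, -60, -120, 60, -90, -140); psiA <- c(-45, 130, 40, -30, 155, 0)
  phiB <- c(0, 60, 80, -70, 120, 50);     psiB <- c(120, -40, -120, 150, -60, 80)
  bbA <- build_backbone(phiA, psiA)
  bbB <- build_backbone(phiB, psiB)
  na <- dim(bbA$coords)[2]
  withr::with_seed(seed, {
    coords <- list(); hidden <- list()
    for (t in seq_len(n_traj)) {
      s <- integer(n_frames); s[1] <- sample(1:2, 1)
      for (f in 2:n_frames) {
        s[f] <- if (stats::runif(1) < stay) s[f - 1] else 3L - s[f - 1]
      }
      arr <- array(NA_real_, dim = c(n_frames, na, 3))
      for (f in seq_len(n_frames)) {
        base <- if (s[f] == 1) bbA$coords[1, , ] else bbB$coords[1, , ]
        arr[f, , ] <- base + stats::rnorm(na * 3, sd = jitter)
      }
      coords[[t]] <- arr; hidden[[t]] <- s
    }
    list(ensemble = ensemble_from_arrays(coords, bbA$topology, frame_interval = 1),
         hidden = hidden)
  })
}

# Small fast synthetic spec (same chain/means as the default, fewer frames).
small_4state_spec <- function(seed = 7, n_trajectories = 4, n_frames = 4000) {
  d <- default_4state_spec(seed)
  synthetic_spec(T_true = d$T_true, means = d$means, kappa = d$kappa,
                 n_trajectories = n_trajectories, n_frames = n_frames,
                 frame_interval = d$frame_interval, seed = seed, info = d$info)
}
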