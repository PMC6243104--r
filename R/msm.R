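# Microstate Markov model estimation.
#
# Transition counting is sliding-window within trajectories. The
# non-reversible maximum-likelihood transition matrix is the row-normalized
# count matrix; the reversible MLE maximizes prod T_ij^c_ij subject to
# detailed balance pi_i T_ij = pi_j T_ji via the standard fixed-point
# iteration on the unnormalized edge weights x_ij:
#   x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)
# with c_i, x_i row sums; at a fixed point T_ij = x_ij / x_i satisfies the
# stationarity conditions of the constrained likelihood.

#' Count state-to-state transitions at a lag
#'
#' A transition i -> j is counted whenever a trajectory is in state i at
#' frame t and state j at frame t + lag, for every valid t (sliding
#' window), never across trajectory boundaries. `NA` labels split a
#' trajectory into independent segments.
#'
#' @param labels List of per-trajectory integer label vectors (states
#'   `1..n_states`), or a single vector.
#' @param lag Lag in frames (>= 1).
#' @param n_states Number of states (default: maximum observed label).
#' @return A `count_matrix`: list(counts (n x n), lag_frames, mode).
#' @export
count_transitions <- function(labels, lag, n_states = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  lag <- as.integer(lag)
  if (lag < 1) abort("lag must be >= 1 frame", "argument_error")
  if (is.null(n_states)) n_states <- max(unlist(labels), na.rm = TRUE)
  counts <- matrix(0, n_states, n_states)
  any_pairs <- FALSE
  for (s in labels) {
    L <- length(s)
    if (L <= lag) next
    from <- s[seq_len(L - lag)]
    to <- s[(lag + 1):L]
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) next
    any_pairs <- TRUE
    idx <- (from[ok] - 1L) * n_states + to[ok]
    tab <- tabulate(idx, nbins = n_states * n_states)
    counts <- counts + matrix(tab, n_states, n_states, byrow = TRUE)
  }
  if (!any_pairs) abort("no trajectory longer than the lag; no transitions to count",
                        "empty_count_error")
  structure(list(counts = counts, lag_frames = lag, mode = "sliding"),
            class = "count_matrix")
}

#' Largest strongly connected set of a count matrix
#'
#' Restricts the counts to the largest strongly connected component of the
#' directed graph with an edge i -> j wherever `counts[i, j] > 0`, so the
#' maximum-likelihood chain is irreducible. The fraction of counts removed
#' is reported.
#'
#' @param counts A `count_matrix` or a plain matrix.
#' @return list(active = retained state indices, counts = trimmed
#'   `count_matrix`, fraction_trimmed).
#' @export
largest_connected_set <- function(counts) {
  cm <- if (inherits(counts, "count_matrix")) counts else
    structure(list(counts = as.matrix(counts), lag_frames = NA_integer_, mode = "sliding"),
              class = "count_matrix")
  C <- cm$counts
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, nbins = comp$no)
  # ties: prefer the component holding the most counts, then lowest index
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mass <- vapply(best, function(b) {
      i <- which(comp$membership == b); sum(C[i, i])
    }, numeric(1))
    best <- best[mass == max(mass)]
  }
  if (length(best) > 1) {
    # still tied: keep the component containing the lowest state index
    first <- vapply(best, function(b) min(which(comp$membership == b)), integer(1))
    best <- best[which.min(first)]
  }
  active <- which(comp$membership == best)
  trimmed <- cm
  trimmed$counts <- C[active, active, drop = FALSE]
  list(active = active, counts = trimmed,
       fraction_trimmed = 1 - sum(trimmed$counts) / sum(C))
}

rev_mle <- function(C, tol = 1e-12, max_iter = 1e6) {
  k <- nrow(C)
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  Tprev <- x / rowSums(x)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    xnew <- Csym / denom
    xnew[Csym == 0] <- 0
    xnew <- xnew / sum(xnew)
    Tm <- xnew / rowSums(xnew)
    delta <- max(abs(Tm - Tprev))
    x <- xnew; Tprev <- Tm
    if (delta < tol) return(list(T = Tm, pi = rowSums(x), iterations = it))
  }
  abort(sprintf("reversible MLE did not converge in %g iterations (residual %.3g)",
                max_iter, delta), "numerical_error")
}

#' Maximum-likelihood transition matrix from counts
#'
#' Non-reversible: closed-form row normalization. Reversible (default):
#' detailed-balance-constrained maximizer via fixed-point iteration,
#' converged when the elementwise change of T drops below `tol`. States
#' outside the largest strongly connected component are trimmed first
#' (with a message); estimated quantities refer to the active set.
#'
#' @param counts A `count_matrix` or plain matrix.
#' @param reversible Enforce detailed balance (default TRUE).
#' @param tol Convergence tolerance for the reversible fixed point
#'   (default 1e-12).
#' @param max_iter Iteration cap (default 1e6).
#' @param frame_interval Optional ns per frame, to report the lag in ns.
#' @return An `msm_model`: transition matrix `T` (row-stochastic over the
#'   active set), stationary distribution `pi`, eigenvalues (descending by
#'   modulus), implied timescales, active state indices, lag, counts.
#' @export
mle_transition_matrix <- function(counts, reversible = TRUE, tol = 1e-12,
                                  max_iter = 1e6, frame_interval = NA_real_) {
  cm <- if (inherits(counts, "count_matrix")) counts else
    structure(list(counts = as.matrix(counts), lag_frames = 1L, mode = "sliding"),
              class = "count_matrix")
  lcs <- largest_connected_set(cm)
  if (lcs$fraction_trimmed > 0) {
    message(sprintf("ergodic trimming removed %d state(s) and %.2f%% of counts",
                    nrow(cm$counts) - length(lcs$active), 100 * lcs$fraction_trimmed))
  }
  C <- lcs$counts$counts
  if (any(rowSums(C) == 0)) abort("a retained state has no outgoing counts", "estimation_error")
  if (reversible) {
    fit <- rev_mle(C, tol = tol, max_iter = max_iter)
    Tm <- fit$T
    pi <- fit$pi / sum(fit$pi)
    # real spectrum via the pi-symmetrized similar matrix
    s <- sqrt(pi)
    S <- (s %o% (1 / s)) * Tm
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE)$values
    eigenvalues <- sort(ev, decreasing = TRUE)
  } else {
    Tm <- C / rowSums(C)
    ev <- eigen(Tm, only.values = TRUE)$values
    if (any(abs(Im(ev)) > 1e-12)) {
      warning("non-reversible transition matrix has complex eigenvalues; reporting moduli")
    }
    eigenvalues <- Mod(ev)[order(-Mod(ev))]
    pi <- stationary_distribution(Tm)
  }
  tau <- cm$lag_frames
  lam <- eigenvalues[-1]
  its <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  its[ok] <- -tau / log(lam[ok])
  structure(list(
    T = Tm, pi = pi, eigenvalues = eigenvalues,
    implied_timescales_frames = its,
    lag_frames = tau,
    lag_ns = if (is.finite(frame_interval)) tau * frame_interval else NA_real_,
    active = lcs$active, fraction_trimmed = lcs$fraction_trimmed,
    reversible = reversible, counts = C
  ), class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model> %d states, lag %s frames, %s\n",
              nrow(x$T), x$lag_frames,
              if (x$reversible) "reversible" else "non-reversible"))
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector at eigenvalue 1, normalized to sum 1.
#'
#' @param x An `msm_model` or a row-stochastic matrix.
#' @return Numeric vector `pi` with `pi %*% T = pi`, entries >= 0.
#' @export
stationary_distribution <- function(x) {
  Tm <- if (inherits(x, "msm_model")) x$T else as.matrix(x)
  ev <- eigen(t(Tm))
  d <- abs(ev$values - 1)
  ord <- order(d)
  if (length(d) > 1 && d[ord[2]] < 1e-10) {
    abort("eigenvalue 1 has multiplicity > 1: chain is reducible", "reducibility_error")
  }
  v <- Re(ev$vectors[, ord[1]])
  v <- v / sum(v)
  if (any(v < -1e-8)) abort("stationary eigenvector has negative entries", "numerical_error")
  v[v < 0] <- 0
  v / sum(v)
}

#' Implied timescales over a grid of lags
#'
#' For each lag tau, estimates an MSM and reports
#' `t_i(tau) = -tau / log(lambda_i(tau))` for the `n_timescales` slowest
#' non-stationary eigenvalues. Non-positive (or >= 1) eigenvalues yield
#' undefined entries flagged in the `defined` column.
#'
#' @param labels List of per-trajectory label vectors.
#' @param lags Integer vector of lags in frames.
#' @param n_timescales How many timescales to report (default 5).
#' @param reversible Use the reversible estimator (default TRUE).
#' @param frame_interval Optional ns per frame for the ns columns.
#' @return An `its_table` data.frame: lag_frames, lag_ns, index,
#'   eigenvalue, timescale_frames, timescale_ns, defined, n_active.
#' @export
implied_timescales <- function(labels, lags, n_timescales = 5,
                               reversible = TRUE, frame_interval = NA_real_) {
  rows <- list()
  for (tau in as.integer(lags)) {
    cm <- count_transitions(labels, tau)
    model <- mle_transition_matrix(cm, reversible = reversible,
                                   frame_interval = frame_interval)
    lam <- model$eigenvalues[-1]
    nt <- min(n_timescales, length(lam))
    lam <- lam[seq_len(nt)]
    ts <- rep(NA_real_, nt)
    ok <- lam > 0 & lam < 1
    ts[ok] <- -tau / log(lam[ok])
    rows[[length(rows) + 1]] <- data.frame(
      lag_frames = tau,
      lag_ns = tau * frame_interval,
      index = seq_len(nt),
      eigenvalue = lam,
      timescale_frames = ts,
      timescale_ns = ts * frame_interval,
      defined = is.finite(ts),
      n_active = length(model$active)
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("its_table", "data.frame")
  out
}

#' Select the Markov lag from an implied-timescale table
#'
#' Returns the smallest lag after which the slowest `n_slow` timescales
#' change by less than `tolerance` (relative) between every pair of
#' successive lags through the end of the grid. If no lag qualifies the
#' result carries `converged = FALSE` — a reported status, not an error
#' (slow loops genuinely may not converge within the sampled timescales).
#'
#' @param its An `its_table` from [implied_timescales()].
#' @param tolerance Relative change threshold (default 0.10).
#' @param n_slow Number of slowest timescales to monitor (default 3).
#' @return list(converged, lag_frames, lag_ns, status).
#' @export
select_lag <- function(its, tolerance = 0.10, n_slow = 3) {
  lags <- sort(unique(its$lag_frames))
  if (length(lags) < 3) abort("need at least 3 lags in the ITS table", "argument_error")
  n_slow <- min(n_slow, max(its$index))
  M <- matrix(NA_real_, length(lags), n_slow)
  for (i in seq_along(lags)) {
    sub <- its[its$lag_frames == lags[i] & its$index <= n_slow, ]
    M[i, sub$index] <- sub$timescale_frames
  }
  ok_pair <- rep(FALSE, length(lags))  # ok_pair[j]: change from lag j-1 to j small
  for (j in 2:length(lags)) {
    a <- M[j - 1, ]; b <- M[j, ]
    ok_pair[j] <- all(is.finite(a)) && all(is.finite(b)) &&
      all(abs(b - a) / a < tolerance)
  }
  for (i in seq_len(length(lags) - 1)) {
    if (all(ok_pair[(i + 1):length(lags)])) {
      return(list(converged = TRUE, lag_frames = lags[i],
                  lag_ns = its$lag_ns[match(lags[i], its$lag_frames)],
                  status = "converged"))
    }
  }
  list(converged = FALSE, lag_frames = NA_integer_, lag_ns = NA_real_,
       status = "not converged: slow timescales keep changing across the lag grid")
}

#' Export an implied-timescale table as CSV
#' @param its An `its_table`.
#' @param path Output CSV path.
#' @export
export_its <- function(its, path) {
  write_table(as.data.frame(its), path)
}
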