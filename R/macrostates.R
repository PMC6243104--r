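# PCCA+ coarse-graining into metastable macrostates.
#
# PCCA+ reads the m dominant right eigenvectors of a reversible microstate
# transition matrix as coordinates on an (m-1)-simplex: each metastable
# aggregate corresponds to a vertex. The inner simplex algorithm locates m
# microstates that span the simplex (vertices), and the linear map sending
# those rows to unit vectors yields fuzzy memberships chi (rows on the
# probability simplex). Crisp states are row argmax.

#' Choose the macrostate count from an implied-timescale spectrum
#'
#' m = 1 + number of slow timescales separated from the rest by the largest
#' relative gap. If no gap exceeds a factor of 2 the result is flagged low
#' confidence.
#'
#' @param timescales Either an `its_table` (the largest lag's rows are
#'   used) or a numeric vector of timescales, descending.
#' @param max_m Upper bound on the returned count (default: all).
#' @return list(m, gap_ratio, low_confidence, timescales).
#' @export
choose_macrostate_count <- function(timescales, max_m = NULL) {
  if (inherits(timescales, "its_table") || is.data.frame(timescales)) {
    tl <- max(timescales$lag_frames)
    ts <- timescales$timescale_frames[timescales$lag_frames == tl]
    ts <- ts[order(-ts)]
  } else {
    ts <- sort(as.numeric(timescales), decreasing = TRUE)
  }
  ts <- ts[is.finite(ts)]
  if (length(ts) < 2) abort("need at least two finite timescales", "argument_error")
  if (!is.null(max_m)) ts <- ts[seq_len(min(length(ts), max_m))]
  ratios <- ts[-length(ts)] / ts[-1]
  g <- which.max(ratios)
  list(m = g + 1L, gap_ratio = ratios[g], low_confidence = ratios[g] < 2,
       timescales = ts)
}

pcca_isa <- function(evec) {
  # inner simplex algorithm: pick m rows of the eigenvector matrix that
  # span the simplex, return the membership matrix chi = evec %*% inv(V)
  n <- nrow(evec); m <- ncol(evec)
  index <- integer(m)
  # first vertex: row of maximal norm; shift it to the origin
  index[1] <- which.max(rowSums(evec^2))
  ortho <- sweep(evec, 2, evec[index[1], ])
  for (k in seq_len(m - 1)) {
    # next vertex: farthest row from the span of the chosen directions
    index[k + 1] <- which.max(rowSums(ortho^2))
    temp <- ortho[index[k + 1], ]
    nrm <- sqrt(sum(temp^2))
    if (nrm < 1e-12) abort("degenerate eigenvector geometry in PCCA+", "numerical_error")
    temp <- temp / nrm
    ortho <- ortho - outer(drop(ortho %*% temp), temp)
  }
  V <- evec[index, , drop = FALSE]
  chi <- evec %*% solve(V)
  chi[chi < 0] <- 0
  chi / rowSums(chi)
}

#' PCCA+ macrostate memberships from a microstate model
#'
#' @param model A reversible `msm_model`.
#' @param m Number of macrostates; must not exceed the number of positive
#'   eigenvalues.
#' @return A `macrostate_model`: membership matrix `chi` (k_micro x m, rows
#'   on the simplex), crisp micro-to-macro map (argmax), `m`, and the
#'   micro model. Macrostates are relabeled by decreasing aggregated
#'   microstate population so numbering is deterministic.
#' @export
pcca_plus <- function(model, m) {
  if (!inherits(model, "msm_model") || !model$reversible) {
    abort("PCCA+ requires a reversible msm_model (real spectrum)", "argument_error")
  }
  m <- as.integer(m)
  n_pos <- sum(model$eigenvalues > 0)
  if (m < 2 || m > n_pos) {
    abort(sprintf("m = %d outside valid range [2, %d] (positive eigenvalues)", m, n_pos),
          "argument_error")
  }
  lam <- model$eigenvalues
  if (m < length(lam) && abs(lam[m] - lam[m + 1]) < 1e-10) {
    abort(sprintf("eigenvalues %d and %d are degenerate at the spectral cut; choose a different m",
                  m, m + 1), "degenerate_spectrum_error")
  }
  # right eigenvectors via the pi-symmetrized matrix
  s <- sqrt(model$pi)
  S <- (s %o% (1 / s)) * model$T
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors[, seq_len(m), drop = FALSE] / s
  # pi-weighted normalization; first vector becomes the constant 1
  for (j in seq_len(m)) {
    nrm <- sqrt(sum(model$pi * psi[, j]^2))
    psi[, j] <- psi[, j] / nrm
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  psi[, 1] <- 1
  chi <- pcca_isa(psi)
  crisp <- max.col(chi, ties.method = "first")
  # deterministic macrostate order: decreasing aggregate population
  pop <- vapply(seq_len(m), function(j) sum(model$pi[crisp == j]), numeric(1))
  ord <- order(-pop)
  relabel <- match(seq_len(m), ord)
  chi <- chi[, ord, drop = FALSE]
  crisp <- relabel[crisp]
  structure(list(
    m = m, chi = chi, crisp = crisp,
    micro_model = model,
    macro_pi_from_chi = drop(crossprod(chi, model$pi))
  ), class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("<macrostate_model> %d macrostates over %d microstates\n",
              x$m, nrow(x$chi)))
  cat("  membership-aggregated populations:",
      paste(sprintf("%.3f", x$macro_pi_from_chi), collapse = ", "), "\n")
  invisible(x)
}

#' Map per-frame microstate labels to macrostate labels
#'
#' Frames whose microstate was trimmed from the active set become `NA`.
#'
#' @param labels List of per-trajectory microstate label vectors (original
#'   state numbering).
#' @param macro A `macrostate_model`.
#' @return List of per-trajectory macrostate label vectors.
#' @export
macro_labels <- function(labels, macro) {
  active <- macro$micro_model$active
  map <- rep(NA_integer_, max(unlist(labels), na.rm = TRUE))
  map[active] <- macro$crisp
  lapply(labels, function(s) map[s])
}

#' Macrostate Markov model and jump probabilities
#'
#' Maps microstate label sequences through the crisp micro-to-macro
#' assignment, then counts and estimates an MLE transition matrix at the
#' macrostate lag (configured independently of the microstate lag). The
#' jump probability i -> j is the off-diagonal entry `T[i, j]`: the
#' probability of moving between those macrostates within one macro lag.
#'
#' @param labels List of per-trajectory microstate label vectors.
#' @param macro A `macrostate_model`.
#' @param lag Macrostate lag in frames.
#' @param reversible Reversible estimator (default TRUE).
#' @param frame_interval Optional ns per frame.
#' @return list(model = coarse `msm_model`, jumps = data.frame(from, to,
#'   probability), metastability = trace of the coarse T, labels = macro
#'   label sequences).
#' @export
macrostate_msm <- function(labels, macro, lag, reversible = TRUE,
                           frame_interval = NA_real_) {
  mlab <- macro_labels(labels, macro)
  cm <- count_transitions(mlab, lag, n_states = macro$m)
  model <- mle_transition_matrix(cm, reversible = reversible,
                                 frame_interval = frame_interval)
  Tm <- model$T
  idx <- which(row(Tm) != col(Tm), arr.ind = TRUE)
  jumps <- data.frame(from = model$active[idx[, 1]], to = model$active[idx[, 2]],
                      probability = Tm[idx])
  jumps <- jumps[order(jumps$from, jumps$to), ]
  rownames(jumps) <- NULL
  list(model = model, jumps = jumps, metastability = sum(diag(Tm)), labels = mlab)
}

#' Centroid frame of a cluster in projection space
#'
#' The member frame minimizing the summed Euclidean distance to all other
#' members in the retained tICA dimensions; ties break to the earliest
#' (trajectory, frame).
#'
#' @param X Numeric matrix of member coordinates (rows ordered by
#'   (trajectory, frame)).
#' @param ids Optional data.frame(trajectory, frame) aligned with `X`.
#' @param n_max Optional cap: with more members than this, an evenly
#'   strided subset is scanned (documented approximation for very large
#'   states).
#' @return list(index = row index into `X`, id = its (trajectory, frame)
#'   row if `ids` given, cost = summed distance).
#' @export
cluster_centroid <- function(X, ids = NULL, n_max = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) abort("empty member set", "argument_error")
  sub <- seq_len(n)
  if (!is.null(n_max) && n > n_max) {
    sub <- unique(round(seq(1, n, length.out = n_max)))
  }
  Xs <- X[sub, , drop = FALSE]
  m <- nrow(Xs)
  cost <- numeric(m)
  chunk <- max(1L, floor(2e7 / m))
  for (s in seq(1, m, by = chunk)) {
    e <- min(m, s + chunk - 1)
    D <- sqrt(dist_sq(Xs[s:e, , drop = FALSE], Xs))
    cost[s:e] <- rowSums(D)
  }
  best <- sub[which.min(cost)]   # which.min: earliest on ties
  list(index = best,
       id = if (!is.null(ids)) ids[best, , drop = FALSE] else NULL,
       cost = min(cost))
}
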