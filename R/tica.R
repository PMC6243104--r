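# Time-lagged independent component analysis.
#
# For features x_t, tICA solves the generalized eigenproblem
#   C_tau v = lambda C_0 v
# where C_0 is the instantaneous covariance and C_tau the time-lagged
# covariance at lag tau, symmetrized as (C_tau + C_tau^T)/2. Eigenvectors
# are C_0-orthonormal (v' C_0 v = 1), so each projected component has unit
# variance at lag 0; eigenvalues are autocorrelations of the projected
# components at lag tau. Lagged pairs are formed inside each trajectory
# only. The symmetric estimator (averaging statistics of the forward and
# time-shifted frame sets) plus a small diagonal shrinkage on C_0 keeps the
# eigenproblem real and well posed.

#' Estimate a tICA model
#'
#' @param features A `feature_matrix` (see [circular_embed()]), or a list of
#'   frames x d numeric matrices.
#' @param lag Lag time. Interpreted in frames when `lag_unit = "frames"`
#'   (default), or in ns (converted via the feature matrix frame interval).
#' @param lag_unit `"frames"` or `"ns"`.
#' @param n_components Number of components retained for projection
#'   (default 16, or `"var90"` for the smallest k whose cumulative
#'   eigenvalue fraction reaches 0.9).
#' @param shrinkage Diagonal shrinkage added to C0 as
#'   `shrinkage * trace(C0)/d` (default 1e-6).
#' @return A `tica_model` with mean, C0, Ctau, eigenvalues (descending),
#'   C0-orthonormal eigenvectors, lag, and retained component count.
#' @export
estimate_tica <- function(features, lag, lag_unit = c("frames", "ns"),
                          n_components = 16, shrinkage = 1e-6) {
  lag_unit <- match.arg(lag_unit)
  dat <- if (inherits(features, "feature_matrix")) features$data else features
  if (!is.list(dat)) dat <- list(dat)
  frame_interval <- if (inherits(features, "feature_matrix")) features$frame_interval else NA_real_
  tau <- if (lag_unit == "ns") ns_to_frames(lag, frame_interval) else as.integer(lag)
  if (tau < 1) abort("lag must be at least one frame", "estimation_error")
  lens <- vapply(dat, nrow, integer(1))
  if (any(lens <= tau)) {
    abort(sprintf("lag (%d frames) must be shorter than every trajectory (min length %d)",
                  tau, min(lens)), "estimation_error")
  }
  d <- ncol(dat[[1]])
  s0 <- numeric(d); S00 <- matrix(0, d, d); S0t <- matrix(0, d, d)
  st <- numeric(d); Stt <- matrix(0, d, d)
  n_pairs <- 0
  for (X in dat) {
    L <- nrow(X)
    X0 <- X[seq_len(L - tau), , drop = FALSE]
    Xt <- X[(tau + 1):L, , drop = FALSE]
    s0 <- s0 + colSums(X0); st <- st + colSums(Xt)
    S00 <- S00 + crossprod(X0); Stt <- Stt + crossprod(Xt)
    S0t <- S0t + crossprod(X0, Xt)
    n_pairs <- n_pairs + (L - tau)
  }
  mu <- (s0 + st) / (2 * n_pairs)
  C0 <- (S00 + Stt) / (2 * n_pairs) - tcrossprod(mu)
  Ct <- S0t / n_pairs - tcrossprod(mu)
  Ct <- (Ct + t(Ct)) / 2
  delta <- shrinkage * sum(diag(C0)) / d
  C0r <- C0 + diag(delta, d)
  U <- tryCatch(chol(C0r), error = function(e) {
    abort("C0 is singular even after shrinkage regularization", "numerical_error")
  })
  # whiten: eigenproblem of U^-T Ct U^-1 (symmetric)
  Y <- forwardsolve(t(U), Ct)
  A <- t(forwardsolve(t(U), t(Y)))
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  vecs <- backsolve(U, eig$vectors)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  k <- if (identical(n_components, "var90")) {
    pos <- pmax(eig$values, 0)
    which(cumsum(pos) / sum(pos) >= 0.9)[1]
  } else {
    min(as.integer(n_components), d)
  }
  structure(list(
    lag_frames = tau,
    lag_ns = if (is.finite(frame_interval)) tau * frame_interval else NA_real_,
    frame_interval = frame_interval,
    mean = mu, C0 = C0, Ctau = Ct, shrinkage_delta = delta,
    eigenvalues = eig$values, eigenvectors = vecs,
    n_components = k, n_pairs = n_pairs,
    feature_names = if (inherits(features, "feature_matrix")) features$names else colnames(dat[[1]])
  ), class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag %d frames%s, %d features, %d components retained\n",
              x$lag_frames,
              if (is.finite(x$lag_ns)) sprintf(" (%g ns)", x$lag_ns) else "",
              length(x$mean), x$n_components))
  cat("  top eigenvalues:", paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Project features onto tICA components
#'
#' @param model A `tica_model`.
#' @param features A `feature_matrix` or list of frames x d matrices with
#'   the model's feature dimension.
#' @param k Number of components (default: the model's retained count).
#' @return A `projected_data`: list(data = list of frames x k matrices, k,
#'   frame_interval, model lag).
#' @export
tica_project <- function(model, features, k = model$n_components) {
  dat <- if (inherits(features, "feature_matrix")) features$data else features
  if (!is.list(dat)) dat <- list(dat)
  d <- length(model$mean)
  if (ncol(dat[[1]]) != d) {
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(dat[[1]]), d), "projection_error")
  }
  if (k > ncol(model$eigenvectors)) abort("k exceeds available components", "projection_error")
  W <- model$eigenvectors[, seq_len(k), drop = FALSE]
  proj <- lapply(dat, function(X) sweep(X, 2, model$mean) %*% W)
  structure(list(data = proj, k = k,
                 frame_interval = model$frame_interval,
                 lag_frames = model$lag_frames),
            class = "projected_data")
}

#' Project an external conformation into a trained tICA space
#'
#' Computes the loop dihedrals of a single external structure (e.g. a bound
#' crystal conformation), embeds them with the same feature construction as
#' the training data, and applies the model's projection matrix, yielding a
#' single point for overlay on the simulation density landscape.
#'
#' @param model A `tica_model` trained on embedded loop dihedrals.
#' @param structure_path PDB file of the external conformation.
#' @param selection_spec Residue-range text, as in [select_loop()]; must
#'   produce the identical angle list as the training data.
#' @param mode Embedding mode used in training ("sincos" or "raw").
#' @param training_info The `info` table of the training dihedral series
#'   (used to verify the feature correspondence).
#' @return 1 x k matrix of tICA coordinates.
#' @export
project_external <- function(model, structure_path, selection_spec,
                             mode = "sincos", training_info = NULL) {
  st <- read_pdb(structure_path)
  ens <- ensemble_from_arrays(list(st$coords), st$topology, frame_interval = 1)
  sel <- select_loop(ens, selection_spec)
  series <- backbone_dihedrals(ens, sel)
  fm <- circular_embed(series, mode = mode)
  if (!is.null(training_info)) {
    want <- angle_names(training_info); got <- angle_names(series$info)
    if (!identical(want, got)) {
      missing <- setdiff(want, got); extra <- setdiff(got, want)
      abort(paste0("external structure feature set mismatch; missing: ",
                   paste(missing, collapse = ", "), "; unexpected: ",
                   paste(extra, collapse = ", ")), "mapping_error")
    }
  }
  if (ncol(fm$data[[1]]) != length(model$mean)) {
    abort("external structure yields a different feature dimension than the model",
          "mapping_error")
  }
  tica_project(model, fm)$data[[1]]
}

#' Save a tICA model as a plain-text archive
#'
#' Writes a JSON file with all fields (mean, covariances, eigenpairs, lag,
#' feature names) at full double precision so projections are reproducible
#' across sessions.
#'
#' @param model A `tica_model`.
#' @param path Output JSON path.
#' @export
save_tica <- function(model, path) {
  # doubles are stored as %.17g strings: 17 significant digits round-trip
  # IEEE 754 exactly, which plain JSON numbers (15 digits) do not
  fmt <- function(x) {
    out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
    if (!is.null(dim(x))) { dim(out) <- dim(x); out <- as.data.frame(out) }
    out
  }
  obj <- unclass(model)
  for (f in c("mean", "C0", "Ctau", "eigenvalues", "eigenvectors",
              "shrinkage_delta", "lag_ns", "frame_interval")) {
    obj[[f]] <- fmt(obj[[f]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Load a tICA model saved by [save_tica()]
#' @param path JSON path.
#' @export
load_tica <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unfmt <- function(x) {
    if (is.data.frame(x)) {
      m <- apply(as.matrix(x), c(1, 2), as.numeric)
      dimnames(m) <- NULL
      m
    } else suppressWarnings(as.numeric(x))
  }
  for (f in c("mean", "C0", "Ctau", "eigenvalues", "eigenvectors",
              "shrinkage_delta", "lag_ns", "frame_interval")) {
    obj[[f]] <- unfmt(obj[[f]])
  }
  structure(obj, class = "tica_model")
}
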