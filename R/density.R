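# Gaussian kernel density estimation of projected data.
#
# The estimator matches the classical full-covariance Gaussian KDE: the
# bandwidth matrix is H = f^2 * Sigma with Sigma the sample covariance and
# f = n^(-1/(d+4)) Scott's-Rule factor. The density at a grid node g is
#   (1/n) sum_i N(g; x_i, H)
# evaluated exactly (no binning), chunked over samples to bound memory.

#' Kernel density estimate on a regular grid
#'
#' @param projected A `projected_data`, or a numeric matrix of samples.
#' @param dims Component indices to use (length 1 or 2; default `c(1, 2)`).
#' @param grid_size Nodes per axis (default 128).
#' @param pad Grid extent beyond the data range, in marginal bandwidths
#'   (default 3).
#' @param n_max Optional cap on sample count; when exceeded, an evenly
#'   strided subset is used (deterministic).
#' @return A `density_grid`: list(axes, values, H, n, dims). `values` is a
#'   vector (1-D) or grid_size x grid_size matrix (2-D, rows = first axis).
#' @export
kde_density <- function(projected, dims = c(1, 2), grid_size = 128, pad = 3,
                        n_max = NULL) {
  X <- if (inherits(projected, "projected_data")) do.call(rbind, projected$data) else as.matrix(projected)
  if (max(dims) > ncol(X)) abort("requested dims exceed available components", "argument_error")
  X <- X[, dims, drop = FALSE]
  if (nrow(X) < 2) abort("need at least 2 samples for a KDE", "degenerate_data_error")
  if (!is.null(n_max) && nrow(X) > n_max) {
    idx <- unique(round(seq(1, nrow(X), length.out = n_max)))
    X <- X[idx, , drop = FALSE]
  }
  n <- nrow(X); d <- ncol(X)
  Sigma <- stats::cov(X)
  if (any(!is.finite(Sigma)) || min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("degenerate data covariance (all points identical?)", "degenerate_data_error")
  }
  f <- n^(-1 / (d + 4))
  H <- f^2 * Sigma
  bw <- sqrt(diag(H))
  axes <- lapply(seq_len(d), function(j) {
    seq(min(X[, j]) - pad * bw[j], max(X[, j]) + pad * bw[j], length.out = grid_size)
  })
  U <- chol(H)
  Z <- X %*% solve(U)                      # whitened samples
  norm_const <- 1 / (n * (2 * pi)^(d / 2) * sqrt(det(H)))
  if (d == 1) {
    G <- matrix(axes[[1]], ncol = 1)
  } else {
    G <- as.matrix(expand.grid(axes[[1]], axes[[2]]))  # first axis varies fastest
  }
  Gz <- G %*% solve(U)
  g2 <- rowSums(Gz^2)
  dens <- numeric(nrow(Gz))
  chunk <- max(1L, floor(2e7 / nrow(Gz)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    Zc <- Z[s:e, , drop = FALSE]
    D2 <- outer(g2, rowSums(Zc^2), "+") - 2 * Gz %*% t(Zc)
    D2[D2 < 0] <- 0
    dens <- dens + rowSums(exp(-0.5 * D2))
  }
  dens <- dens * norm_const
  values <- if (d == 1) dens else matrix(dens, nrow = grid_size)  # [axis1, axis2]
  structure(list(axes = axes, values = values, H = H, n = n, dims = dims),
            class = "density_grid")
}

#' Numerical integral of a density grid
#' @param grid A `density_grid`.
#' @export
integrate_grid <- function(grid) {
  steps <- vapply(grid$axes, function(a) a[2] - a[1], numeric(1))
  sum(grid$values) * prod(steps)
}

#' Find local density maxima (modes)
#'
#' Strict local maxima over the 8-neighborhood (2-D) or 2-neighborhood
#' (1-D), kept when their height is at least `min_prominence` of the global
#' maximum. Metastable conformational islands appear as such modes in the
#' projected free-energy landscape.
#'
#' @param grid A `density_grid`.
#' @param min_prominence Height threshold as a fraction of the global
#'   maximum (default 0.05).
#' @return data.frame of mode coordinates and densities, sorted by density
#'   (descending). May be empty.
#' @export
find_modes <- function(grid, min_prominence = 0.05) {
  v <- grid$values
  thresh <- min_prominence * max(v)
  if (is.matrix(v)) {
    nr <- nrow(v); nc <- ncol(v)
    vp <- matrix(-Inf, nr + 2, nc + 2)
    vp[2:(nr + 1), 2:(nc + 1)] <- v
    is_max <- matrix(TRUE, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- vp[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
      is_max <- is_max & (v > nb)
    }
    idx <- which(is_max & v >= thresh, arr.ind = TRUE)
    out <- data.frame(x = grid$axes[[1]][idx[, 1]],
                      y = grid$axes[[2]][idx[, 2]],
                      density = v[idx])
  } else {
    n <- length(v)
    left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
    idx <- which(v > left & v > right & v >= thresh)
    out <- data.frame(x = grid$axes[[1]][idx], density = v[idx])
  }
  out[order(-out$density), , drop = FALSE]
}

#' Export a density grid as plain-text files
#'
#' Writes `<stem>_density.csv` (the value matrix) and `<stem>_axis<i>.csv`.
#'
#' @param grid A `density_grid`.
#' @param stem Output path stem.
#' @export
export_grid <- function(grid, stem) {
  utils::write.csv(as.data.frame(grid$values), paste0(stem, "_density.csv"), row.names = FALSE)
  for (i in seq_along(grid$axes)) {
    utils::write.csv(data.frame(coord = grid$axes[[i]]),
                     sprintf("%s_axis%d.csv", stem, i), row.names = FALSE)
  }
  invisible(stem)
}
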