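# K-medoids microstate clustering (PAM-style alternation).
#
# Distances are Euclidean in the retained tICA space. Seeding is
# k-means++-style on medoids under a fixed seed; sweeps alternate a
# nearest-medoid assignment (ties -> lowest medoid index) with an exact
# medoid update (the member minimizing summed Euclidean distance to its
# cluster, ties -> earliest point) until the labels reach a fixed point or
# `max_iter` sweeps.

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  medoids <- integer(k)
  medoids[1] <- sample.int(n, 1)
  d2 <- dist_sq(X, X[medoids[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      cand <- setdiff(seq_len(n), medoids[seq_len(j)])
      medoids[j + 1] <- cand[sample.int(length(cand), 1)]
    } else {
      medoids[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, dist_sq(X, X[medoids[j + 1], , drop = FALSE])[, 1])
  }
  medoids
}

#' K-medoids clustering of projected frames
#'
#' @param projected A `projected_data` or a numeric matrix (rows = frames).
#' @param k Number of clusters; must not exceed the number of frames.
#' @param seed RNG seed controlling the k-means++-style initialization
#'   (default 2018). Results are deterministic given (data, k, seed).
#' @param max_iter Maximum number of assign/update sweeps (default 100).
#' @return A `kmedoids_clustering`: medoid identities (global index and
#'   (trajectory, frame)), medoid coordinates, per-trajectory label lists,
#'   total within-cluster distance, seed and sweep count.
#' @export
kmedoids <- function(projected, k, seed = 2018, max_iter = 100) {
  if (inherits(projected, "projected_data")) {
    st <- stack_trajectories(projected$data)
  } else {
    X <- as.matrix(projected)
    st <- list(X = X, ids = data.frame(trajectory = 1L, frame = seq_len(nrow(X))),
               lengths = nrow(X))
  }
  X <- st$X
  n <- nrow(X)
  if (k > n) abort(sprintf("k = %d exceeds the number of frames (%d)", k, n), "argument_error")
  medoids <- with_seed(seed, kmeanspp_init(X, k))
  labels <- integer(n)
  iter <- 0
  repeat {
    iter <- iter + 1
    D <- dist_sq(X, X[medoids, , drop = FALSE])
    new_labels <- max.col(-D, ties.method = "first")
    if (iter > 1 && all(new_labels == labels)) { labels <- new_labels; break }
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members) == 0) next   # empty cluster keeps its medoid
      Dj <- sqrt(dist_sq(X[members, , drop = FALSE], X[members, , drop = FALSE]))
      cost <- rowSums(Dj)
      medoids[j] <- members[which.min(cost)]  # which.min -> earliest on ties
    }
    if (iter >= max_iter) break
  }
  D <- sqrt(dist_sq(X, X[medoids, , drop = FALSE]))
  labels <- max.col(-D, ties.method = "first")
  cost <- sum(D[cbind(seq_len(n), labels)])
  lab_list <- split(labels, st$ids$trajectory)
  names(lab_list) <- NULL
  structure(list(
    k = k,
    medoid_index = medoids,
    medoid_id = st$ids[medoids, , drop = FALSE],
    medoids = X[medoids, , drop = FALSE],
    labels = lab_list,
    cost = cost,
    seed = seed,
    iterations = iter
  ), class = "kmedoids_clustering")
}

#' @export
print.kmedoids_clustering <- function(x, ...) {
  cat(sprintf("<kmedoids_clustering> k = %d, cost = %.4g, %d sweeps (seed %d)\n",
              x$k, x$cost, x$iterations, x$seed))
  invisible(x)
}

#' Assign points to the nearest medoid
#'
#' Uses the same tie-break as [kmedoids()]: the lowest-index medoid wins.
#'
#' @param clustering A `kmedoids_clustering`.
#' @param points A `projected_data`, or a numeric matrix with the medoid
#'   dimensionality.
#' @return Integer labels in `1..k`; a list of per-trajectory vectors if
#'   `points` is `projected_data`, otherwise a vector.
#' @export
assign_clusters <- function(clustering, points) {
  one <- function(M) {
    M <- as.matrix(M)
    if (ncol(M) != ncol(clustering$medoids)) {
      abort("dimensionality does not match the medoids", "argument_error")
    }
    max.col(-dist_sq(M, clustering$medoids), ties.method = "first")
  }
  if (inherits(points, "projected_data")) lapply(points$data, one) else one(points)
}

#' Export per-frame microstate labels as CSV
#'
#' @param labels List of per-trajectory label vectors.
#' @param path Output CSV path (columns trajectory, frame, microstate).
#' @export
export_labels <- function(labels, path) {
  df <- data.frame(
    trajectory = rep(seq_along(labels), lengths(labels)),
    frame = unlist(lapply(lengths(labels), seq_len), use.names = FALSE),
    microstate = unlist(labels, use.names = FALSE)
  )
  write_table(df, path)
}
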