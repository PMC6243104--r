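#' @keywords internal
"_PACKAGE"

# Error constructor with a package-specific condition class so callers can
# distinguish, e.g., selection errors from numerical errors.
abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("loopmsm_", class), "loopmsm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Wrap angles onto the half-open interval (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles mapped to `(-pi, pi]`; `-pi` maps to `pi`.
#' @export
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of known hidden states by the estimated
#' macrostate assignment. 1 means identical partitions (up to relabeling),
#' 0 is the expectation under independent random labelings.
#'
#' @param a,b Vectors of labels of equal length (any atomic type).
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors differ in length", "argument_error")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a_comb <- sum(choose(rowSums(tab), 2))
  b_comb <- sum(choose(colSums(tab), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  max_index <- (a_comb + b_comb) / 2
  if (max_index == expected) return(1)
  (sum_comb - expected) / (max_index - expected)
}

# Convert a lag in nanoseconds to an integer lag in frames. Non-integer
# ratios are rounded with a warning, per the stated frame-time contract.
ns_to_frames <- function(lag_ns, frame_interval) {
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be a positive number of nanoseconds", "argument_error")
  }
  raw <- lag_ns / frame_interval
  fr <- as.integer(round(raw))
  if (abs(raw - fr) > 1e-9) {
    warning(sprintf("lag %.6g ns is not a multiple of frame_interval %.6g ns; rounded to %d frames",
                    lag_ns, frame_interval, fr))
  }
  if (fr < 1L) abort("lag must be at least one frame", "argument_error")
  fr
}

# Squared Euclidean distances between rows of X (n x d) and rows of M (k x d).
# Negative round-off is clamped at zero.
dist_sq <- function(X, M) {
  D <- outer(rowSums(X^2), rep(1, nrow(M))) +
    outer(rep(1, nrow(X)), rowSums(M^2)) - 2 * X %*% t(M)
  D[D < 0] <- 0
  D
}

# Stack a list of per-trajectory matrices into one matrix plus an id table.
stack_trajectories <- function(mats) {
  n <- vapply(mats, nrow, integer(1))
  ids <- data.frame(
    trajectory = rep(seq_along(mats), n),
    frame = unlist(lapply(n, seq_len), use.names = FALSE)
  )
  list(X = do.call(rbind, mats), ids = ids, lengths = n)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
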