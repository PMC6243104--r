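test_that("transition counting matches the stated convention and a brute-force oracle", {
  # canonical example: [1, 2] at lag 1 -> one count in cell (1, 2)
  cm <- count_transitions(list(c(1L, 2L)), lag = 1, n_states = 2)
  expect_equal(cm$counts, rbind(c(0, 1), c(0, 0)))
  # constant sequence of length L at lag tau -> L - tau self-counts
  cm2 <- count_transitions(list(rep(2L, 40)), lag = 7, n_states = 2)
  expect_equal(cm2$counts[2, 2], 33)
  expect_equal(sum(cm2$counts), 33)
  # random sequence vs double-loop oracle, several lags
  set.seed(51)
  s <- sample.int(4, 500, replace = TRUE)
  for (lag in c(1, 3, 10)) {
    got <- count_transitions(list(s), lag = lag, n_states = 4)$counts
    expect_equal(got, oracle_count(s, lag, 4))
  }
  # boundaries: two trajectories never pool across the gap
  got2 <- count_transitions(list(s[1:250], s[251:500]), lag = 3, n_states = 4)$counts
  expect_equal(got2, oracle_count(s[1:250], 3, 4) + oracle_count(s[251:500], 3, 4))
  expect_error(count_transitions(list(c(1L, 2L)), lag = 5),
               class = "loopmsm_empty_count_error")
})

test_that("largest_connected_set matches a Kosaraju oracle and keeps the big block", {
  # two disconnected blocks of sizes 3 and 2 -> 3-block retained
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 5; C[4:5, 4:5] <- 5
  lcs <- largest_connected_set(C)
  expect_equal(lcs$active, 1:3)
  # fully connected counts -> identity restriction
  full <- matrix(1, 4, 4)
  expect_equal(largest_connected_set(full)$active, 1:4)
  expect_equal(largest_connected_set(full)$fraction_trimmed, 0)
  # random sparse counts vs oracle
  set.seed(52)
  for (rep in 1:20) {
    n <- 8
    A <- matrix(stats::rbinom(n * n, 1, 0.2), n, n)
    lcs <- largest_connected_set(A)
    comp <- oracle_scc(A > 0)
    sizes <- tabulate(comp)
    expect_equal(length(lcs$active), max(sizes))
    # the returned set is one oracle component
    expect_length(unique(comp[lcs$active]), 1)
  }
})

test_that("MLE estimators: closed form, brute-force reversible oracle, detailed balance", {
  # symmetric counts: both estimators give the row-normalized matrix
  sym <- rbind(c(9, 1), c(1, 9))
  for (rev in c(TRUE, FALSE)) {
    m <- mle_transition_matrix(sym, reversible = rev)
    expect_equal(m$T, rbind(c(0.9, 0.1), c(0.1, 0.9)), tolerance = 1e-10)
  }
  # non-reversible closed form
  C <- rbind(c(5, 3), c(2, 6))
  mnr <- mle_transition_matrix(C, reversible = FALSE)
  expect_equal(mnr$T, rbind(c(0.625, 0.375), c(0.25, 0.75)), tolerance = 1e-14)
  # reversible vs brute-force constrained-likelihood grid search
  mr <- mle_transition_matrix(C, reversible = TRUE)
  expect_equal(mr$T, oracle_rev_mle_2state(C), tolerance = 1e-6)
  # detailed balance residual
  F <- mr$pi * mr$T
  expect_lt(max(abs(F - t(F))), 1e-8)
  # rows sum to one
  set.seed(53)
  Cr <- matrix(stats::rpois(25, 8) + 1, 5, 5)
  mrr <- mle_transition_matrix(Cr, reversible = TRUE)
  expect_lt(max(abs(rowSums(mrr$T) - 1)), 1e-12)
  Frr <- mrr$pi * mrr$T
  expect_lt(max(abs(Frr - t(Frr))), 1e-8)
  # reversible likelihood cannot exceed the unconstrained optimum
  ll <- function(Tm) sum(Cr[Cr > 0] * log(Tm[Cr > 0]))
  mnr2 <- suppressWarnings(mle_transition_matrix(Cr, reversible = FALSE))
  expect_lte(ll(mrr$T), ll(mnr2$T) + 1e-10)
})

test_that("stationary distribution: analytic case, power-iteration oracle, error paths", {
  expect_equal(stationary_distribution(rbind(c(0.9, 0.1), c(0.2, 0.8))),
               c(2 / 3, 1 / 3), tolerance = 1e-10)
  # doubly stochastic -> uniform
  Td <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3), c(0.3, 0.2, 0.5))
  expect_equal(stationary_distribution(Td), rep(1 / 3, 3), tolerance = 1e-10)
  # power-iteration oracle: pi equals a row of T^(2^20)
  set.seed(54)
  Tm <- matrix(stats::runif(16), 4, 4); Tm <- Tm / rowSums(Tm)
  P <- Tm
  for (i in 1:20) P <- P %*% P
  expect_equal(stationary_distribution(Tm), P[1, ], tolerance = 1e-10)
  # reducible chain -> multiplicity error
  Tr <- diag(2)
  expect_error(stationary_distribution(Tr), class = "loopmsm_reducibility_error")
})

test_that("implied timescales follow the formula and are flat for an exact chain", {
  # direct formula: lambda = 0.5 observed at tau = 2 frames -> t = 2/ln 2
  cm <- structure(list(counts = rbind(c(75, 25), c(25, 75)), lag_frames = 2L,
                       mode = "sliding"), class = "count_matrix")
  m2 <- mle_transition_matrix(cm)
  expect_equal(m2$implied_timescales_frames[1], 2 / log(2), tolerance = 1e-12)
  # 3-state chain with second eigenvalue exactly 0.9 (uniform off-diagonal):
  # ITS should be flat near -1/ln 0.9 across lags
  lam2 <- 0.9
  eps <- (1 - lam2) / 3
  T3 <- matrix(eps, 3, 3); diag(T3) <- 1 - 2 * eps
  lams <- sort(eigen(T3, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(lams[2], lam2, tolerance = 1e-12)
  labs <- lapply(1:6, function(i) {
    set.seed(550 + i)
    s <- integer(20000); s[1] <- sample.int(3, 1)
    cum <- t(apply(T3, 1, cumsum))
    u <- stats::runif(20000)
    for (t in 2:20000) s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
    s
  })
  its <- implied_timescales(labs, lags = 1:10, n_timescales = 2)
  ref <- -1 / log(lam2)
  slow <- its$timescale_frames[its$index == 1]
  expect_true(all(abs(slow - ref) / ref < 0.15))
  # stationary eigenvalue excluded
  expect_true(all(its$eigenvalue < 1))
  # select_lag returns a small lag for an exact chain
  sel <- select_lag(its, n_slow = 2)
  expect_true(sel$converged)
  expect_lte(sel$lag_frames, 2)
})

test_that("select_lag handles flat, rising, and short tables", {
  flat <- data.frame(lag_frames = rep(1:5, each = 3), lag_ns = rep(1:5, each = 3),
                     index = rep(1:3, 5), eigenvalue = 0.9,
                     timescale_frames = rep(c(100, 50, 20), 5),
                     timescale_ns = rep(c(100, 50, 20), 5), defined = TRUE)
  class(flat) <- c("its_table", "data.frame")
  sel <- select_lag(flat)
  expect_true(sel$converged)
  expect_equal(sel$lag_frames, 1)
  rising <- flat
  rising$timescale_frames <- rising$timescale_frames * 1.2^rep(1:5, each = 3)
  sel2 <- select_lag(rising)
  expect_false(sel2$converged)
  expect_match(sel2$status, "not converged")
  expect_error(select_lag(flat[flat$lag_frames <= 2, ]), class = "loopmsm_argument_error")
})

test_that("estimated T converges to the generator chain on exact-Markov data", {
  set.seed(56)
  T0 <- rbind(c(0.90, 0.08, 0.02), c(0.05, 0.90, 0.05), c(0.02, 0.08, 0.90))
  cum <- t(apply(T0, 1, cumsum))
  s <- integer(60000); s[1] <- 1L
  u <- stats::runif(60000)
  for (t in 2:60000) s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
  m <- mle_transition_matrix(count_transitions(list(s), 1), reversible = TRUE)
  counts_per_row <- rowSums(count_transitions(list(s), 1)$counts)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(T0[i, j] * (1 - T0[i, j]) / counts_per_row[i])
    expect_lt(abs(m$T[i, j] - T0[i, j]), 3 * se + 1e-3)
  }
})
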