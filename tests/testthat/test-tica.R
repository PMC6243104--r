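make_ar1 <- function(n, coefs, seed = 1) {
  set.seed(seed)
  X <- matrix(0, n, length(coefs))
  for (j in seq_along(coefs)) {
    x <- numeric(n)
    e <- stats::rnorm(n)
    for (t in 2:n) x[t] <- coefs[j] * x[t - 1] + e[t]
    X[, j] <- x
  }
  X
}

test_that("i.i.d. features have no slow process", {
  set.seed(21)
  X <- matrix(stats::rnorm(10000 * 4), ncol = 4)
  m <- estimate_tica(list(X), lag = 1)
  expect_lt(max(abs(m$eigenvalues)), 0.05)
})

test_that("AR(1) channels recover their autocorrelation coefficients", {
  X <- make_ar1(50000, c(0.95, 0.50), seed = 22)
  m <- estimate_tica(list(X), lag = 1)
  expect_equal(m$eigenvalues[1], 0.95, tolerance = 0.02 / 0.95)
  expect_equal(m$eigenvalues[2], 0.50, tolerance = 0.05 / 0.50)
})

test_that("eigenvalues match a dense generalized-eigenproblem oracle", {
  set.seed(23)
  X <- make_ar1(1000, c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1), seed = 23)
  X <- X %*% matrix(stats::rnorm(36), 6, 6)   # mix the channels
  m <- estimate_tica(list(X), lag = 2)
  C0r <- m$C0 + diag(m$shrinkage_delta, 6)
  expect_equal(m$eigenvalues, oracle_generalized_eigen(m$Ctau, C0r),
               tolerance = 1e-8)
  # C0-orthonormality of the eigenvector columns
  g <- t(m$eigenvectors) %*% C0r %*% m$eigenvectors
  expect_lt(max(abs(g - diag(6))), 1e-8)
})

test_that("lagged pairs never cross trajectory boundaries and ordering is irrelevant", {
  set.seed(24)
  xs <- lapply(1:4, function(i) make_ar1(800, c(0.8, 0.4), seed = 24 + i))
  m1 <- estimate_tica(xs, lag = 3)
  m2 <- estimate_tica(rev(xs), lag = 3)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-12)
  # two separate short trajectories differ from their concatenation
  mcat <- estimate_tica(list(do.call(rbind, xs[1:2])), lag = 3)
  msep <- estimate_tica(xs[1:2], lag = 3)
  expect_false(isTRUE(all.equal(mcat$Ctau, msep$Ctau, tolerance = 1e-12)))
})

test_that("lag validation and ns conversion behave", {
  X <- matrix(stats::rnorm(50 * 2), 50, 2)
  expect_error(estimate_tica(list(X), lag = 50), class = "loopmsm_estimation_error")
  info <- data.frame(chain = "A", resid = 1, resname = "ALA", angle = "phi")
  ser <- dihedral_series(list(matrix(stats::runif(100, -1, 1), 100, 1)), info, 0.5)
  fm <- circular_embed(ser)
  m <- estimate_tica(fm, lag = 5, lag_unit = "ns")
  expect_identical(m$lag_frames, 10L)
  expect_equal(m$lag_ns, 5)
})

test_that("projection is centered, unit-variance at lag 0, and linear", {
  set.seed(26)
  X <- make_ar1(10000, c(0.9, 0.6, 0.3), seed = 26)
  m <- estimate_tica(list(X), lag = 1, n_components = 3)
  pr <- tica_project(m, list(X))
  expect_equal(ncol(pr$data[[1]]), 3)
  # mean feature vector projects to the origin
  expect_equal(as.vector(tica_project(m, list(matrix(m$mean, 1)))$data[[1]]),
               rep(0, 3), tolerance = 1e-12)
  # unit lag-0 variance within sampling tolerance
  v <- apply(pr$data[[1]], 2, stats::var)
  expect_true(all(abs(v - 1) < 0.1))
  # affine linearity: project(mean + a*delta) - project(mean) scales with a
  delta <- stats::rnorm(3)
  p1 <- tica_project(m, list(matrix(m$mean + delta, 1)))$data[[1]]
  p3 <- tica_project(m, list(matrix(m$mean + 3 * delta, 1)))$data[[1]]
  expect_equal(as.vector(p3), as.vector(3 * p1), tolerance = 1e-10)
  # dimension mismatch
  expect_error(tica_project(m, list(matrix(0, 1, 4))), class = "loopmsm_projection_error")
})

test_that("projecting a training frame reproduces its stored projection", {
  set.seed(27)
  X <- make_ar1(500, c(0.8, 0.5), seed = 27)
  m <- estimate_tica(list(X), lag = 1, n_components = 2)
  pr <- tica_project(m, list(X))
  single <- tica_project(m, list(X[123, , drop = FALSE]))
  expect_equal(as.vector(single$data[[1]]), as.vector(pr$data[[1]][123, ]),
               tolerance = 1e-10)
})

test_that("external-structure projection maps a known conformation to one point", {
  ens <- toy_ensemble(n_traj = 2, n_frames = 30, jitter = 0.05)
  sel <- select_loop(ens, "2-5")
  ser <- backbone_dihedrals(ens, sel)
  fm <- circular_embed(ser)
  m <- estimate_tica(fm, lag = 1, n_components = 2)
  dir <- withr::local_tempdir()
  ext <- file.path(dir, "ext.pdb")
  write_pdb(ens$topology, ens$coords[[1]][5, , ], ext)
  xy <- project_external(m, ext, "2-5", training_info = ser$info)
  expect_equal(dim(xy), c(1, 2))
  pr <- tica_project(m, fm, k = 2)
  # PDB stores 3 decimals, so agreement is to writer precision only
  expect_equal(as.vector(xy), as.vector(pr$data[[1]][5, ]), tolerance = 0.03)
  # feature-set mismatch is an explicit mapping error
  expect_error(project_external(m, ext, "2-4", training_info = ser$info),
               class = "loopmsm_mapping_error")
})

test_that("model serialization round-trips bit-for-bit", {
  set.seed(28)
  X <- make_ar1(300, c(0.7, 0.4), seed = 28)
  m <- estimate_tica(list(X), lag = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_tica(m, path)
  m2 <- load_tica(path)
  expect_identical(m2$eigenvalues, m$eigenvalues)
  expect_identical(m2$eigenvectors, m$eigenvectors)
  expect_identical(m2$mean, m$mean)
  p1 <- tica_project(m, list(X))$data[[1]]
  p2 <- tica_project(m2, list(X))$data[[1]]
  expect_identical(p1, p2)
})
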