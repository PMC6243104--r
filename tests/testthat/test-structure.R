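test_that("hydrogen-bond detection is exact on a (distance, angle) grid around the cutoffs", {
  for (dist in c(2.6, 2.9, 3.15, 3.199, 3.25, 3.4)) {
    for (dev in c(0, 5, 15, 19.5, 20.5, 25, 40)) {
      tri <- build_hbond_triad(dist, dev)
      hb <- find_hbonds(tri$coords[1, , ], tri$topology)
      should <- dist <= 3.2 && dev <= 20
      expect_equal(nrow(hb) == 1, should,
                   info = sprintf("dist=%.2f dev=%.1f", dist, dev))
      if (nrow(hb) == 1) {
        expect_equal(hb$distance, dist, tolerance = 1e-10)
        expect_equal(hb$angle_dev, dev, tolerance = 1e-8)
      }
    }
  }
})

test_that("hydrogen-bond detection is invariant under rigid motion and honours custom cutoffs", {
  tri <- build_hbond_triad(2.9, 5)
  set.seed(71)
  R <- random_rotation()
  moved <- tri$coords[1, , ] %*% R + matrix(c(2, -1, 4), 3, 3, byrow = TRUE)
  hb <- find_hbonds(moved, tri$topology)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-10)
  # tighter cutoffs reject the same geometry
  expect_equal(nrow(find_hbonds(moved, tri$topology, dist_cutoff = 2.5)), 0)
  expect_equal(nrow(find_hbonds(moved, tri$topology, angle_cutoff = 3)), 0)
  # no hydrogens -> explicit error
  noH <- tri$topology[tri$topology$element != "H", ]
  expect_error(find_hbonds(tri$coords[1, -2, ], noH), class = "loopmsm_hbond_error")
})

test_that("hbond_occupancy computes per-state fractions with flagged empty states", {
  present <- data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L,
                        donor_label = "A1:N", acceptor_label = "A2:O",
                        distance = 2.9, angle_dev = 5)
  absent <- present[0, ]
  # 8-frame toy: state A = frames 1-4 (bond in 2), state B = frames 5-8 (all bonded)
  bonds <- list(present, absent, present, absent, present, present, present, present)
  labels <- c(1, 1, 1, 1, 2, 2, 2, 2)
  occ <- hbond_occupancy(bonds, labels, "A1:N", "A2:O")
  expect_equal(occ$occupancy[occ$state == 1], 0.5)
  expect_equal(occ$occupancy[occ$state == 2], 1.0)
  # never-formed pair
  occ0 <- hbond_occupancy(bonds, labels, "A1:N", "A9:O")
  expect_true(all(occ0$occupancy == 0))
})

test_that("SASA matches analytic values for isolated and paired spheres", {
  top1 <- data.frame(serial = 1L, name = "C", resname = "UNK", chain = "A",
                     resid = 1L, element = "C", serial_resid = 1L)
  s1 <- shrake_rupley_sasa(matrix(0, 1, 3), top1)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # two identical spheres at several separations vs spherical-cap formula
  top2 <- data.frame(serial = 1:2, name = "C", resname = "UNK", chain = "A",
                     resid = 1:2, element = "C", serial_resid = 1:2)
  R <- 1.7 + 1.4
  for (d in c(1.0, 2.5, 4.0, 5.5, 6.5)) {
    s2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), top2)
    expect_equal(s2$total, oracle_two_sphere_sasa(R, d), tolerance = 0.01 * 8 * pi * R^2)
  }
  # fully enclosed atom ~ 0: surround with a tight shell
  shell <- sphere_points_shell <- NULL
  pts <- rbind(c(0, 0, 0),
               3.0 * rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1),
                           c(1,1,0)/sqrt(2), c(-1,1,0)/sqrt(2), c(1,-1,0)/sqrt(2), c(-1,-1,0)/sqrt(2),
                           c(1,0,1)/sqrt(2), c(-1,0,1)/sqrt(2), c(1,0,-1)/sqrt(2), c(-1,0,-1)/sqrt(2),
                           c(0,1,1)/sqrt(2), c(0,-1,1)/sqrt(2), c(0,1,-1)/sqrt(2), c(0,-1,-1)/sqrt(2)))
  topn <- data.frame(serial = seq_len(nrow(pts)), name = "C", resname = "UNK",
                     chain = "A", resid = seq_len(nrow(pts)), element = "C",
                     serial_resid = seq_len(nrow(pts)))
  sn <- shrake_rupley_sasa(pts, topn)
  expect_lt(sn$per_atom[1], 1)
  # union SASA never exceeds the sum of isolated-atom SASAs
  iso <- sum(vapply(seq_len(nrow(pts)), function(i)
    shrake_rupley_sasa(pts[i, , drop = FALSE], topn[i, , drop = FALSE])$total, numeric(1)))
  expect_lte(sn$total, iso + 1e-9)
  # unknown element
  bad <- top1; bad$element <- "XX"
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), bad), class = "loopmsm_radius_error")
})

test_that("Kabsch alignment: rigid copies, quaternion oracle, never worse than unaligned", {
  set.seed(72)
  P <- matrix(stats::rnorm(45), 15, 3)
  R <- random_rotation()
  Q <- P %*% R + matrix(c(1, -2, 3), 15, 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-10)
  # 3-point toy vs quaternion characteristic-polynomial oracle
  for (i in 1:20) {
    A <- matrix(stats::rnorm(9), 3, 3)
    B <- matrix(stats::rnorm(9), 3, 3)
    expect_equal(kabsch(A, B)$rmsd, oracle_quaternion_rmsd(A, B), tolerance = 1e-10)
  }
  # alignment never increases RMSD
  for (i in 1:10) {
    A <- matrix(stats::rnorm(30), 10, 3)
    B <- matrix(stats::rnorm(30), 10, 3)
    before <- sqrt(mean(rowSums((A - B)^2)))
    expect_lte(kabsch(A, B)$rmsd, before + 1e-12)
  }
})

test_that("nearest_frame_by_rmsd finds exact and transformed copies", {
  ens <- toy_ensemble(n_traj = 2, n_frames = 5, jitter = 0.3, seed = 73)
  sel <- select_loop(ens, "1-6")
  ca <- sel$atoms[ens$topology$name[sel$atoms] == "CA"]
  # reference identical to trajectory 2, frame 3
  ref_co <- ens$coords[[2]][3, , ]
  ref <- list(topology = ens$topology,
              coords = array(ref_co, dim = c(1, nrow(ens$topology), 3)))
  hit <- nearest_frame_by_rmsd(ens, ref, align_sel = sel$atoms, rmsd_sel = ca)
  expect_equal(hit$trajectory, 2)
  expect_equal(hit$frame, 3)
  expect_lt(hit$rmsd, 1e-10)
  # rigid-transformed copy of the same frame
  set.seed(74)
  R <- random_rotation()
  ref2 <- ref
  ref2$coords[1, , ] <- ref_co %*% R + matrix(c(4, 4, -2), nrow(ref_co), 3, byrow = TRUE)
  hit2 <- nearest_frame_by_rmsd(ens, ref2, align_sel = sel$atoms, rmsd_sel = ca)
  expect_equal(hit2$trajectory, 2)
  expect_equal(hit2$frame, 3)
  expect_lt(hit2$rmsd, 1e-10)
  # correspondence failure lists unmatched atoms
  ref3 <- ref
  ref3$topology$name[1] <- "XX"
  expect_error(nearest_frame_by_rmsd(ens, ref3, align_sel = sel$atoms),
               class = "loopmsm_mapping_error")
})

test_that("centroid dihedral tables equal direct featurization in degrees", {
  ens <- toy_ensemble(n_traj = 2, n_frames = 4, seed = 75)
  sel <- select_loop(ens, "1-6")
  cen <- data.frame(state = c(1, 2), trajectory = c(1, 2), frame = c(2, 4))
  tab <- centroid_dihedral_table(ens, cen, sel)
  ser <- backbone_dihedrals(ens, sel)
  for (i in 1:2) {
    sub <- tab[tab$state == i, ]
    expect_equal(sub$value_deg,
                 180 / pi * ser$angles[[cen$trajectory[i]]][cen$frame[i], ],
                 tolerance = 1e-10)
  }
  # identical centroid frames give identical tables
  cen2 <- data.frame(state = c(1, 2), trajectory = c(1, 1), frame = c(2, 2))
  tab2 <- centroid_dihedral_table(ens, cen2, sel)
  expect_equal(tab2$value_deg[tab2$state == 1], tab2$value_deg[tab2$state == 2])
})
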