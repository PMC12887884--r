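test_that("fibril axis follows layer centroids, with the short-fibril fallback", {
  fib <- build_fibril(tau_template(), n_layers = 10)
  expect_equal(abs(fibril_axis(fib)), c(0, 0, 1), tolerance = 1e-12)
  # equivariance: rotating the fibril rotates the axis
  R <- rotation_about(c(1, 2, 0.5), 0.9)
  rot <- fib
  rot$atoms[, c("x", "y", "z")] <-
    as.matrix(fib$atoms[, c("x", "y", "z")]) %*% t(R)
  expect_equal(fibril_axis(rot), as.numeric(R %*% fibril_axis(fib)),
               tolerance = 1e-9)
  # 5 layers: endpoints of the standard rule coincide, fallback engages
  fib5 <- build_fibril(tau_template(), n_layers = 5)
  expect_equal(abs(fibril_axis(fib5)), c(0, 0, 1), tolerance = 1e-12)
})

test_that("glycan axis is the ring-centroid chord and transforms rigidly", {
  gly <- build_glycan(8)
  expect_equal(glycan_axis(gly), c(1, 0, 0), tolerance = 1e-12)
  R <- rotation_about(c(0, 1, 0), pi / 2)
  expect_equal(glycan_axis(gly, rigid_pose(R, c(5, 5, 5))),
               as.numeric(R %*% c(1, 0, 0)), tolerance = 1e-12)
})

test_that("orientation angle is the folded axis angle with inclusive filter", {
  fib <- build_fibril(tau_template(), n_layers = 10)
  gly <- build_glycan(8)
  # chain along z = parallel to the fibril axis
  along <- rigid_pose(rotation_about(c(0, 1, 0), -pi / 2), c(40, 0, 20))
  expect_equal(orientation_angle(fib, gly, along), 0, tolerance = 1e-9)
  # chain along x = perpendicular
  perp <- rigid_pose(t = c(40, 0, 20))
  expect_equal(orientation_angle(fib, gly, perp), 90, tolerance = 1e-9)
  expect_false(is_aligned(fib, gly, perp))
  # antiparallel folds to 0
  anti <- rigid_pose(rotation_about(c(0, 1, 0), pi / 2), c(40, 0, 20))
  expect_equal(orientation_angle(fib, gly, anti), 0, tolerance = 1e-9)
  # boundary 45 degrees is aligned (inclusive)
  tilt <- rigid_pose(rotation_about(c(0, 1, 0), -pi / 4), c(40, 0, 20))
  expect_equal(orientation_angle(fib, gly, tilt), 45, tolerance = 1e-9)
  expect_true(is_aligned(fib, gly, tilt))
  # the filter partitions any pose set
  set.seed(11)
  poses <- replicate(25, random_pose_near(fib$center, 30),
                     simplify = FALSE)
  ang <- vapply(poses, function(p) orientation_angle(fib, gly, p),
                numeric(1))
  expect_true(all(ang >= 0 & ang <= 90))
  aligned <- ang <= 45
  expect_equal(sum(aligned) + sum(!aligned), 25L)
})

test_that("pose features equal the brute-force nearest-atom scan", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(8)
  set.seed(31)
  for (i in 1:100) {
    pose <- random_pose_near(fib$center, radius = runif(1, 5, 25))
    expect_equal(pose_features(pose, fib, gly, 1L),
                 oracle_features(pose, fib, gly, 1L), tolerance = 1e-9)
  }
  # composite site: features taken over the union of residues
  f12 <- pose_features(rigid_pose(t = c(10, 10, 5)), fib, gly, c(1L, 5L))
  expect_equal(f12, pmin(
    pose_features(rigid_pose(t = c(10, 10, 5)), fib, gly, 1L),
    pose_features(rigid_pose(t = c(10, 10, 5)), fib, gly, 5L)))
})

test_that("features and angle are invariant under a common rigid motion", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(4)
  pose <- rigid_pose(random_orientation(), c(12, 4, 8))
  R <- rotation_about(c(1, 1, 1), 1.1); tr <- c(-7, 3, 12)
  fib2 <- fib
  fib2$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(fib$atoms[, c("x", "y", "z")]) %*% t(R), 2, tr, "+")
  pose2 <- rigid_pose(R %*% pose$R, as.numeric(R %*% pose$t) + tr)
  expect_equal(pose_features(pose2, fib2, gly, 1L),
               pose_features(pose, fib, gly, 1L), tolerance = 1e-9)
  expect_equal(orientation_angle(fib2, gly, pose2),
               orientation_angle(fib, gly, pose), tolerance = 1e-7)
})

test_that("distance RMSD has the closed-form value and metric properties", {
  expect_equal(distance_rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(distance_rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- runif(5); b <- runif(5)
  expect_equal(distance_rmsd(a, b), distance_rmsd(b, a))
  expect_error(distance_rmsd(1:3, 1:4), "length")
})

test_that("Ward clustering recovers planted blobs and selects true medoids", {
  set.seed(77)
  blob1 <- matrix(rnorm(40, mean = 0, sd = 0.3), ncol = 4)
  blob2 <- matrix(rnorm(40, mean = 8, sd = 0.3), ncol = 4)
  feats <- rbind(blob1, blob2)
  cl <- ward_cluster(feats, k = 2)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  expect_equal(length(unique(cl$labels[11:20])), 1L)
  expect_false(cl$labels[1] == cl$labels[11])
  # medoids: exhaustive within-cluster scan
  for (c_ in 1:2) {
    members <- which(cl$labels == c_)
    expect_equal(oracle_medoid(feats, members),
                 cl$medoid_indices[c_])
  }
  # linkage heights never decrease
  expect_true(all(diff(cl$height) >= -1e-12))
  # k = n: every pose its own cluster and medoid
  cln <- ward_cluster(feats[1:6, ], k = 6)
  expect_setequal(cln$medoid_indices, 1:6)
  expect_equal(sort(unique(cln$labels)), 1:6)
  # duplicated points merge at height zero
  dup <- rbind(feats[1, ], feats[1, ], feats[15, ])
  expect_equal(min(ward_cluster(dup, 2)$height), 0)
  expect_error(ward_cluster(feats, 25), "k must be")
})

test_that("local pose refinement lowers the interaction energy", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(8)
  set.seed(5)
  pose <- rigid_pose(random_orientation(), fib$center + c(0, 18, 0))
  e0 <- interaction_energy(fib, gly, pose)
  ref <- refine_pose(fib, gly, pose, n_iter = 60)
  expect_lte(ref$energy, e0)
  expect_equal(ref$energy, interaction_energy(fib, gly, ref$pose),
               tolerance = 1e-9)
})
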