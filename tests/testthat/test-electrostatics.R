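test_that("Debye length matches the closed form and its limits", {
  # frozen from the closed form kappa^-1 = sqrt(eps eps0 kB T / (2 NA e^2 I))
  expect_equal(debye_length(solvent_params(310.15, 78, 1, 0.150)),
               7.985511291140136, tolerance = 1e-10)
  # zero ionic strength: pure Coulomb mode signalled by an infinite length
  expect_identical(debye_length(solvent_params(ionic_strength = 0)), Inf)
  # quadrupling the ionic strength halves the screening length
  expect_equal(debye_length(solvent_params(ionic_strength = 0.6)),
               debye_length(solvent_params(ionic_strength = 0.15)) / 2,
               tolerance = 1e-12)
})

test_that("potential reduces to Coulomb, is symmetric, and decays", {
  vac <- solvent_params(dielectric = 1, ionic_strength = 0)
  # single +1 charge, kappa = 0, 10 A: ke/(eps r)
  expect_equal(potential_at(c(0, 0, 0), 1, c(10, 0, 0), vac),
               33.2063713, tolerance = 1e-9)
  # +-1 dipole, equidistant query
  expect_equal(potential_at(rbind(c(-1, 0, 0), c(1, 0, 0)), c(1, -1),
                            c(0, 5, 0), solvent_params()), 0,
               tolerance = 1e-12)
  # monotonic decay with distance for a single positive source
  r <- seq(2, 40, by = 0.5)
  v <- potential_at(c(0, 0, 0), 1, cbind(r, 0, 0), solvent_params())
  expect_true(all(diff(v) < 0))
  # coincident query rejected
  expect_error(potential_at(c(0, 0, 0), 1, c(0, 0, 0)), "coincides")
})

test_that("superposition holds for random charge sets", {
  set.seed(42)
  solv <- solvent_params()
  for (rep in 1:5) {
    pts <- matrix(rnorm(15, sd = 5), ncol = 3)
    q <- sample(c(-1, 1), 5, replace = TRUE)
    query <- c(12, 3, -4)
    single <- vapply(1:5, function(i)
      potential_at(pts[i, ], q[i], query, solv), numeric(1))
    expect_equal(potential_at(pts, q, query, solv), sum(single),
                 tolerance = 1e-12)
  }
})

test_that("screening: |potential| non-increasing in ionic strength", {
  v <- vapply(c(0, 0.05, 0.15, 0.5, 1.5), function(I)
    abs(potential_at(c(0, 0, 0), 1, c(8, 0, 0),
                     solvent_params(ionic_strength = I))), numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("force is the negative gradient of the interaction energy", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(4)
  solv <- solvent_params()
  set.seed(7)
  for (rep in 1:3) {
    pose <- random_pose_near(fib$center, radius = 18)
    ft <- force_torque_on_glycan(fib, gly, pose, solv)
    h <- 1e-4
    num <- vapply(1:3, function(ax) {
      dp <- c(0, 0, 0); dp[ax] <- h
      ep <- interaction_energy(fib, gly,
                               rigid_pose(pose$R, pose$t + dp), solv)
      em <- interaction_energy(fib, gly,
                               rigid_pose(pose$R, pose$t - dp), solv)
      -(ep - em) / (2 * h)
    }, numeric(1))
    expect_equal(ft$force, num,
                 tolerance = 1e-4 * max(1, sqrt(sum(num^2))))
    # energy value consistent between the two kernels
    expect_equal(ft$energy, interaction_energy(fib, gly, pose, solv),
                 tolerance = 1e-10)
  }
})

test_that("torque matches the numerical rotational derivative", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(4)
  solv <- solvent_params()
  set.seed(8)
  pose <- random_pose_near(fib$center, radius = 16)
  ft <- force_torque_on_glycan(fib, gly, pose, solv)
  h <- 1e-5
  num <- vapply(1:3, function(ax) {
    w <- c(0, 0, 0); w[ax] <- h
    rotp <- rigid_pose(rotation_about(w, h) %*% pose$R, pose$t)
    rotm <- rigid_pose(rotation_about(w, -h) %*% pose$R, pose$t)
    -(interaction_energy(fib, gly, rotp, solv) -
        interaction_energy(fib, gly, rotm, solv)) / (2 * h)
  }, numeric(1))
  expect_equal(ft$torque, num,
               tolerance = 1e-3 * max(1, sqrt(sum(num^2))))
})

test_that("attraction and symmetry have the expected signs", {
  fib <- fake_fibril(data.frame(resno = 1, layer = 0:4, x = 0, y = 0,
                                z = (0:4) * 4.8))
  gly <- fake_glycan(data.frame(hcg_id = 1:2, unit = 1,
                                group_type = "OS6X",
                                x = c(-1, 1), y = 0, z = 0))
  pose <- rigid_pose(t = c(30, 0, 9.6))
  ft <- force_torque_on_glycan(fib, gly, pose, soft_core = FALSE)
  # net anion pulled toward the cationic ladder: radial force negative
  expect_lt(ft$force[1], 0)
  # symmetric arrangement about the ladder midplane: zero axial force
  expect_equal(ft$force[3], 0, tolerance = 1e-9)
  expect_lt(interaction_energy(fib, gly, pose, soft_core = FALSE), 0)
})

test_that("potential grid interpolation is exact at nodes and for linear fields", {
  fib <- two_ladder_fibril(4)
  solv <- solvent_params()
  grid <- precompute_grid(fib, solv, spacing = 2, padding = 6)
  # node identity
  node <- grid$origin + grid$spacing * c(3, 2, 4)
  expect_equal(interpolate_potential(grid, node),
               potential_at(grid$sources$pos, grid$sources$q, node, solv),
               tolerance = 1e-12)
  # trilinear reproduces a linear field exactly at an edge midpoint
  lin <- grid
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1]
  lin$values <- array(rep(2 * xs + 1, prod(grid$dims[2:3])), grid$dims)
  mid <- grid$origin + grid$spacing * c(1.5, 0, 0)
  expect_equal(interpolate_potential(lin, mid), 2 * mid[1] + 1,
               tolerance = 1e-12)
  # uniform synthetic grid interpolates to the constant anywhere inside
  uni <- grid; uni$values <- array(3.25, grid$dims)
  set.seed(3)
  inside <- sweep(matrix(runif(9, 0.1, 0.9), 3) %*% diag(grid$dims - 1), 2,
                  grid$origin / grid$spacing[1], "+") * grid$spacing[1]
  expect_equal(interpolate_potential(uni, inside), rep(3.25, 3),
               tolerance = 1e-12)
  # outside the box: documented fall back to the direct sum
  far <- grid$origin - c(50, 0, 0)
  expect_equal(interpolate_potential(grid, far),
               potential_at(grid$sources$pos, grid$sources$q, far, solv),
               tolerance = 1e-12)
  # interpolation error bounded near 1 A spacing
  g1 <- precompute_grid(fib, solv, spacing = 1, padding = 6)
  set.seed(4)
  pts <- cbind(runif(20, -5, 20), runif(20, 5, 15), runif(20, 5, 30))
  vi <- interpolate_potential(g1, pts)
  vd <- potential_at(g1$sources$pos, g1$sources$q, pts, solv)
  expect_lt(max(abs(vi - vd) / pmax(abs(vd), 1e-3)), 0.05)
})
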