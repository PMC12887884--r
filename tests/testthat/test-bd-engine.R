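test_that("field-free bd_step reproduces the closed-form displacement", {
  solv <- solvent_params()
  D_t <- translational_diffusion(solv, 8)
  D_r <- rotational_diffusion(solv, 8)
  kBT <- 0.0019872041 * solv$temperature
  set.seed(99)
  xi <- rnorm(3); rnorm(3)        # the draws bd_step will consume
  set.seed(99)
  p1 <- bd_step(rigid_pose(), dt = 1, D_t = D_t, D_r = D_r, kBT = kBT)
  expect_equal(p1$t, sqrt(2 * D_t * 1) * xi, tolerance = 1e-12)

  # with a force, the deterministic drift adds (D_t/kBT) F dt
  F <- c(1, -2, 0.5)
  set.seed(99)
  p2 <- bd_step(rigid_pose(), force = F, dt = 0.5, D_t = D_t, D_r = D_r,
                kBT = kBT)
  expect_equal(p2$t, (D_t / kBT) * F * 0.5 + sqrt(2 * D_t * 0.5) * xi,
               tolerance = 1e-12)
})

test_that("compiled trajectory kernel matches the R reference step for step", {
  # an uncharged fibril keeps the field at zero; the kernel and the R
  # reference then consume the identical RNG stream
  fib <- build_fibril(build_cross_section("KAA", "ladder_line"), 3)
  fib$atoms$charge <- 0
  gly <- build_glycan(4)
  params <- bd_params(b_radius = 300, q_radius = 1e6, max_steps = 40,
                      seed = 5, dt_far = 1.0)
  out <- run_trajectory(fib, gly, params, stream_id = 2, pair_id = 1,
                        record_stride = 1)
  expect_equal(out$status, "max_steps")

  solv <- params$solvent
  D_t <- translational_diffusion(solv, params$hydrodynamic_radius)
  D_r <- rotational_diffusion(solv, params$hydrodynamic_radius)
  kBT <- 0.0019872041 * solv$temperature
  set.seed(out$stream_id)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  pose <- rigid_pose(random_orientation(), fib$center + 300 * u)
  expect_equal(pose$t, out$start, tolerance = 1e-12)
  for (k in 1:40)
    pose <- bd_step(pose, dt = 1, D_t = D_t, D_r = D_r, kBT = kBT)
  expect_equal(out$positions[40, ], pose$t, tolerance = 1e-8)
  expect_equal(out$orientations[40, ], as.numeric(pose$R[, 3]),
               tolerance = 1e-6)
})

test_that("field-free MSD grows as 6 D_t t and orientations decorrelate as exp(-2 D_r t)", {
  fib <- build_fibril(build_cross_section("K", "ladder_line"), 3)
  fib$atoms$charge <- 0                       # pure diffusion
  gly <- build_glycan(8)
  params <- bd_params(b_radius = 500, q_radius = 1e6, max_steps = 1e4,
                      seed = 3)
  solv <- params$solvent
  D_t <- translational_diffusion(solv, params$hydrodynamic_radius)
  D_r <- rotational_diffusion(solv, params$hydrodynamic_radius)

  n_rep <- 100; stride <- 2000; T_end <- 1e4
  disp2 <- matrix(NA_real_, n_rep, T_end / stride)
  dot1 <- numeric(n_rep)
  u0 <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    out <- run_trajectory(fib, gly, params, stream_id = r,
                          record_stride = stride)
    disp2[r, ] <- rowSums((out$positions -
                             matrix(out$start, nrow(out$positions), 3,
                                    byrow = TRUE))^2)
    # orientation autocorrelation over one stride (2000 ps)
    dot1[r] <- sum(out$orientations[1, ] * out$orientations[2, ])
  }
  # MSD at the final time: within 3 standard errors of 6 D t
  t_end <- T_end * params$dt_far
  ratio <- disp2[, ncol(disp2)] / (6 * D_t * t_end)
  se <- sd(ratio) / sqrt(n_rep)
  expect_lt(abs(mean(ratio) - 1), 3 * se)
  # linearity: MSD at half time is about half the final MSD
  expect_equal(mean(disp2[, 2]) / mean(disp2[, 4]), 0.5, tolerance = 0.25)
  # rotational decorrelation over lag tau: <u(t) u(t+tau)> = exp(-2 D_r tau)
  expected <- exp(-2 * D_r * stride * params$dt_far)
  se_rot <- sd(dot1) / sqrt(n_rep)
  expect_lt(abs(mean(dot1) - expected), 3 * se_rot)
})

test_that("reaction criterion counts pairs and attributes the site", {
  fib <- fake_fibril(data.frame(resno = rep(c(5L, 9L), each = 3),
                                layer = rep(0:2, 2),
                                x = rep(c(0, 20), each = 3), y = 0,
                                z = rep((0:2) * 4.8, 2)))
  gly <- build_glycan(4)
  refs <- list(glycan_local = matrix(c(0, 0, 0,  0, 0, 4.8,  0, 0, 9.6),
                                     ncol = 3, byrow = TRUE),
               fibril_pos = as.matrix(fib$atoms[, c("x", "y", "z")]),
               fibril_res = fib$atoms$resno)
  params <- bd_params()
  # all pairs beyond 7.5 A: no reaction
  expect_true(is.na(check_reaction(rigid_pose(t = c(40, 0, 0)), refs,
                                   params)))
  # exactly 3 pairs at 7.4 A to the resno-5 ladder
  expect_equal(check_reaction(rigid_pose(t = c(-7.4, 0, 0)), refs, params),
               5L)
  # two contacts only (pull one sulfur out of range axially): no reaction
  refs2 <- refs
  refs2$glycan_local[3, 3] <- 50
  expect_true(is.na(check_reaction(rigid_pose(t = c(-7.4, 0, 0)), refs2,
                                   params)))
})

test_that("reaction detection matches the brute-force oracle on random poses", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(8)
  refs <- reference_atom_sets(fib, gly)
  params <- bd_params()
  set.seed(123)
  n_agree <- 0
  for (i in 1:120) {
    pose <- random_pose_near(fib$center, radius = runif(1, 5, 30))
    a <- check_reaction(pose, refs, params)
    b <- oracle_reaction(pose, refs, params)
    expect_identical(a, b)
    if (!is.na(a)) n_agree <- n_agree + 1
  }
  expect_gt(n_agree, 5)   # the sample must actually contain reactions
})

test_that("ensemble bookkeeping: counts, determinism, substreams", {
  fib <- two_ladder_fibril(4)
  gly <- build_glycan(4)
  params <- bd_params(max_steps = 50, b_radius = 50, q_radius = 100,
                      seed = 21)
  out1 <- run_ensemble(fib, gly, 5, params)
  expect_equal(nrow(out1), 5L)
  out2 <- run_ensemble(fib, gly, 5, params)
  expect_identical(as.data.frame(out1), as.data.frame(out2))
  # replicate 3 of the ensemble equals the standalone trajectory
  solo <- run_trajectory(fib, gly, params, stream_id = 3, pair_id = 1)
  expect_equal(solo$n_steps, out1$n_steps[3])
  expect_equal(solo$final_pose$t, attr(out1, "poses")[[3]]$t)
  # max_steps = 0: immediate cap with zero steps
  cap <- run_trajectory(fib, gly, bd_params(max_steps = 0, b_radius = 50,
                                            q_radius = 100))
  expect_equal(cap$status, "max_steps")
  expect_equal(cap$n_steps, 0)
  # multi-pair ensembles enumerate |fibrils| x |glycans| x n
  out3 <- run_ensemble(list(fib, fib), list(gly), 2, params)
  expect_equal(nrow(out3), 4L)
})

test_that("free diffusion with a tight escape surface mostly escapes", {
  fib <- two_ladder_fibril(4)
  fib$atoms$charge <- 0
  gly <- build_glycan(4)
  params <- bd_params(b_radius = 60, q_radius = 66, max_steps = 3e4,
                      seed = 2)
  out <- run_ensemble(fib, gly, 40, params)
  expect_gt(mean(out$status == "escaped"), 0.9)
})

test_that("NAM rate formula honours its limits", {
  D <- 0.04
  expect_equal(nam_rate(0, 50, 500, D), 0)
  expect_equal(nam_rate(1, 50, 500, D), 4 * pi * D * 50, tolerance = 1e-12)
  # q >> b: k ~ kD(b) beta
  expect_equal(nam_rate(0.5, 50, 5e6, D), 4 * pi * D * 50 * 0.5,
               tolerance = 1e-4)
  expect_error(nam_rate(0.5, 50, 50, D), "q_radius")
})
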