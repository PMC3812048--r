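test_that("RMSD steering terminates at the stop criterion", {
  fp <- flat_pot(2, lim = 15)
  st <- langevin_settings(seed = 3, stride = 5)

  # already within stop_rmsd: zero steering steps
  res0 <- steer_path(c(0, 0), c(0.01, 0.01), fp, st, stop_rmsd = 0.02)
  expect_equal(res0$steps, 0)
  expect_lte(res0$final_rmsd, 0.02)

  # flat potential, straight-line approach: reaches 0.02 A
  res <- steer_path(c(-3, 0), c(3, 0), fp, st, speed = 5e-4, stop_rmsd = 0.02)
  expect_lte(res$final_rmsd, 0.02)
  expect_gt(res$steps, 0)
  # and the initial string it emits respects the spacing contract
  expect_lt(mean(stringpmf:::adjacent_rmsd(res$string$images)), 0.2)

  # the restraint tracks the analytic ramp: the realized RMSD never exceeds
  # the closed-form schedule by more than the restraint's thermal width
  quad <- quad_pot(k = 1)
  st2 <- langevin_settings(seed = 8, stride = 50)
  r0 <- sqrt(mean((c(-4, -4) - c(0, 0))^2))
  res2 <- steer_path(c(-4, -4), c(0, 0), quad, st2, speed = 2e-4,
                     stop_rmsd = 0.02, k_steer = 400)
  tr <- res2$trajectory
  steps <- (seq_len(nrow(tr)) - 1) * 50
  rmsd_t <- apply(tr, 1, function(x) sqrt(mean(x^2)))
  ramp <- pmax(0, r0 - 2e-4 * steps)
  slack <- 6 * sqrt(kT0 / 400)
  expect_true(all(rmsd_t <= ramp + slack))
  # non-convergence inside a tiny budget errors with the final RMSD
  expect_error(steer_path(c(-4, 0), c(4, 0), fp, st, speed = 1e-6,
                          stop_rmsd = 0.001, max_steps = 100),
               "final RMSD")
})

test_that("subsample_to_images satisfies the adjacent-spacing contract", {
  # dense straight-line trajectory of arc length 1.0, threshold 0.2:
  # at least 6 images and mean spacing below threshold
  traj <- cbind(seq(0, 1, length.out = 2001),
                seq(0, 1, length.out = 2001))  # CV-RMSD arc length 1.0 A
  st <- subsample_to_images(traj, 0.2)
  expect_gte(nrow(st$images), 6)
  expect_lte(mean(stringpmf:::adjacent_rmsd(st$images)), 0.2)
  expect_equal(st$images[1, ], traj[1, ])
  expect_equal(st$images[nrow(st$images), ], traj[2001, ])

  # a trajectory whose steps already sit just under the threshold is kept
  coarse <- cbind(seq(0, 1.9, by = 0.19), 0)
  stc <- subsample_to_images(coarse, 0.2 * sqrt(2))  # per-step rmsd 0.134
  expect_lte(mean(stringpmf:::adjacent_rmsd(stc$images)), 0.2 * sqrt(2))

  # random walk: spacing verified by direct recomputation from the output
  set.seed(21)
  rw <- apply(matrix(rnorm(2 * 400, 0, 0.05), ncol = 2), 2, cumsum)
  str_rw <- subsample_to_images(rw, 0.25)
  sp <- stringpmf:::adjacent_rmsd(str_rw$images)
  expect_lt(mean(sp), 0.25)
  expect_error(subsample_to_images(rw[1, , drop = FALSE]), "at least 2")
})

test_that("swarm drift matches the overdamped closed form and is reproducible", {
  # zero diffusion at a gradient-zero point: exactly zero drift
  quad <- quad_pot(k = 2)
  sw <- swarm_settings(n_trajectories = 10, swarm_steps = 20)
  d0 <- swarm_drift(c(0, 0), quad, langevin_settings(diffusion = 0), sw, seed = 1)
  expect_equal(d0, c(0, 0))

  # near-constant force c: drift = beta D c t within 3 SE
  lin <- model_potential(list(harmonic_term(c(50, 0), c(0.02, 0))),
                         domain = rbind(c(-20, -20), c(40, 20)),
                         wall_height = 0)
  sw2 <- swarm_settings(n_trajectories = 400, swarm_steps = 50)
  ls <- langevin_settings()    # D = 0.01, dt = 0.25
  dr <- swarm_drift(c(0, 0), lin, ls, sw2, seed = 99)
  expected <- (1 / kT0) * 0.01 * 1 * 50 * 0.25
  se <- sqrt(2 * 0.01 * 50 * 0.25 / 400)
  expect_lt(abs(dr[1] - expected), 3 * se)
  expect_lt(abs(dr[2]), 3 * se)

  # same seed: identical drift
  expect_identical(dr, swarm_drift(c(0, 0), lin, ls, sw2, seed = 99))
})

test_that("constrained relaxation equilibrates at the restraint width", {
  fp <- flat_pot(2, lim = 20)
  ls <- langevin_settings(timestep = 0.1)
  # k = 40: stationary spread sqrt(kBT/k) ~ 0.12 A per coordinate
  set.seed(31)
  sp40 <- replicate(400, relax_to_cv(c(0.3, -0.2), c(0, 0), fp, ls, 1250, 40))
  sd40 <- apply(sp40, 1, sd)
  se <- sqrt(kT0 / 40) / sqrt(2 * 400) * 2
  for (j in 1:2) expect_lt(abs(sd40[j] - sqrt(kT0 / 40)), 4 * se)
  # quadrupled stiffness halves the spread
  set.seed(32)
  sp160 <- replicate(400, relax_to_cv(c(0.3, -0.2), c(0, 0), fp, ls, 1250, 160))
  ratio <- mean(apply(sp40, 1, sd)) / mean(apply(sp160, 1, sd))
  expect_equal(ratio, 2, tolerance = 0.15)
  # relaxing onto the current CV keeps the state nearby
  out <- relax_to_cv(c(1, 1), c(1, 1), fp, ls, 2000, 40)
  expect_lt(sqrt(mean((out - c(1, 1))^2)), 5 * sqrt(kT0 / 40))
})

test_that("reparametrize yields machine-evenly spaced images and is idempotent", {
  # already equidistant collinear images: unchanged to 1e-12
  line <- cbind(seq(0, 4, length.out = 9), seq(0, 2, length.out = 9))
  expect_equal(reparametrize(line), line, tolerance = 1e-12)

  # 3 collinear images at arc fractions {0, 0.9, 1}: middle moves to 0.5
  tri <- rbind(c(0, 0), c(0.9, 0), c(1, 0))
  expect_equal(reparametrize(tri)[2, ], c(0.5, 0), tolerance = 1e-12)

  # quarter circle, random spacing: equal adjacent distances to 1e-9
  set.seed(41)
  th <- sort(c(0, runif(18, 0, pi / 2), pi / 2))
  arc <- cbind(5 * cos(th), 5 * sin(th))
  rp <- reparametrize(arc)
  sp <- sqrt(rowSums(diff(rp)^2))
  expect_lt(sd(sp) / mean(sp), 1e-9)
  expect_equal(rp[1, ], arc[1, ])
  expect_equal(rp[20, ], arc[20, ])
  # matches an equal-arc interpolation oracle to within corner-cutting error
  seg <- sqrt(rowSums(diff(arc)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, max(s), length.out = 20)
  oracle <- apply(arc, 2, function(col) approx(s, col, tgt, ties = "ordered")$y)
  expect_lt(max(abs(rp - oracle)), 0.02)

  # idempotence
  expect_equal(reparametrize(rp), rp, tolerance = 1e-12)

  # duplicate consecutive images collapse, then proceed
  dup <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 0))
  rd <- reparametrize(dup)
  expect_equal(nrow(rd), 4)
  expect_equal(sqrt(rowSums(diff(rd)^2)), rep(2 / 3, 3), tolerance = 1e-9)
  expect_error(reparametrize(rbind(c(1, 1), c(1, 1), c(1, 1))), "arc length")
})

test_that("iterate_string applies the 4-step iteration and respects fixed endpoints", {
  pot <- build_cycle_potential(cycle_design("three-well"))
  img0 <- cbind(seq(5, 11, length.out = 11), seq(-1.5, -1.5, length.out = 11))
  st0 <- transition_string(img0)

  # n_iterations = 0: input returned unchanged
  expect_identical(iterate_string(st0, pot, swarm_settings(),
                                  langevin_settings(), 0), st0)

  # zero diffusion on a flat potential: zero drift, an already-equidistant
  # string is exactly invariant
  fp <- flat_pot(2, lim = 20)
  sflat <- transition_string(cbind(seq(-2, 2, length.out = 7), 0))
  out <- iterate_string(sflat, fp, swarm_settings(n_trajectories = 5,
                                                  swarm_steps = 10,
                                                  relax_steps = 10),
                        langevin_settings(diffusion = 0), 3, seed = 5)
  expect_equal(out$images, sflat$images, tolerance = 1e-12)

  # endpoints bit-identical across iterations; history recorded per iteration
  sw <- swarm_settings(n_trajectories = 20, swarm_steps = 20, relax_steps = 100)
  run <- iterate_string(st0, pot, sw, langevin_settings(), 5, seed = 17)
  expect_length(run$history, 6)
  for (h in run$history) {
    expect_identical(h[1, ], img0[1, ])
    expect_identical(h[11, ], img0[11, ])
  }
  # determinism: same seed, same result
  run2 <- iterate_string(st0, pot, sw, langevin_settings(), 5, seed = 17)
  expect_identical(run$images, run2$images)
})

test_that("a converged string tracks the valley floor of a quadratic valley", {
  # valley along the x-axis: y-curvature only; the MFEP is y = 0
  valley <- model_potential(list(harmonic_term(c(0, 0), c(0, 3))),
                            domain = rbind(c(-6, -6), c(6, 6)),
                            wall_height = 0)
  init <- transition_string(cbind(seq(-4, 4, length.out = 15),
                                  rep(0, 15)))
  run <- iterate_string(init, valley, swarm_settings(), langevin_settings(),
                        10, seed = 23)
  # images fluctuate about the floor within a few times the swarm noise scale
  noise <- sqrt(2 * 0.01 * 50 * 0.25 / 100)
  expect_lt(mean(abs(run$images[2:14, 2])), 2 * noise)
})

test_that("swarm size controls the converged string's distance to the MFEP oracle", {
  pot <- build_cycle_potential(cycle_design("three-well"))
  a <- descend_to_minimum(pot, c(5.5, -1.5))
  b <- descend_to_minimum(pot, c(10.5, -1.5))
  mfep <- oracle_mfep(pot, a, b, n = 151, iters = 1500)
  init <- transition_string(cbind(seq(a[1], b[1], length.out = 15),
                                  seq(a[2], b[2], length.out = 15)))
  mean_dist <- function(n_swarm, seeds) {
    mean(vapply(seeds, function(s) {
      run <- iterate_string(init, pot,
                            swarm_settings(n_trajectories = n_swarm,
                                           swarm_steps = 50,
                                           relax_steps = 200),
                            langevin_settings(), 15, seed = s)
      mean(dist_to_path(run$images, mfep))
    }, numeric(1)))
  }
  d_small <- mean_dist(5, c(1, 2, 3))
  d_large <- mean_dist(100, c(1, 2, 3))
  expect_lt(d_large, d_small)
})

test_that("convergence metrics reproduce constructed histories and detect plateaus", {
  # frozen history: both metrics identically zero, plateau
  hf <- make_string_history("frozen", n_iterations = 12)
  cf <- convergence_metrics(hf)
  expect_equal(cf$rmsd_to_initial, rep(0, 13))
  expect_equal(cf$rmsd_to_lag[5:13], rep(0, 9))
  expect_true(all(is.na(cf$rmsd_to_lag[1:4])))   # absent, not zero
  expect_true(cf$plateau)

  # drift then freeze at iteration 8: lag-4 metric hits zero exactly at 12
  a <- 0.05
  hd <- make_string_history("drift-then-freeze", n_iterations = 24,
                            amplitude = a, freeze_at = 8)
  cd <- convergence_metrics(hd)
  expect_equal(cd$rmsd_to_initial[9:25], rep(8 * a, 17), tolerance = 1e-12)
  expect_equal(cd$rmsd_to_lag[5:9], rep(4 * a, 5), tolerance = 1e-12)
  expect_equal(cd$rmsd_to_lag[13:25], rep(0, 13), tolerance = 1e-12)
  expect_gt(cd$rmsd_to_lag[11], 0)
  expect_true(cd$plateau)

  # still drifting: no plateau
  hdrift <- make_string_history("drift-then-freeze", n_iterations = 24,
                                amplitude = a, freeze_at = 100)
  expect_false(convergence_metrics(hdrift)$plateau)

  # metrics match an independent recomputation on a recorded noisy history
  hn <- make_string_history("noisy", n_iterations = 10, amplitude = 0.03,
                            seed = 4)
  cn <- convergence_metrics(hn)
  manual <- sapply(seq_along(hn), function(i) {
    mean(sqrt(rowMeans((hn[[i]] - hn[[1]])^2)))
  })
  expect_equal(cn$rmsd_to_initial, manual, tolerance = 1e-12)
})

test_that("string checkpoints round-trip exactly", {
  set.seed(55)
  st <- transition_string(cbind(sort(runif(8, 0, 5)), rnorm(8)))
  st$history <- list(st$images, st$images + 0.1)
  st$iteration <- 1L
  f <- withr::local_tempfile(fileext = ".txt")
  write_string_checkpoint(st, f)
  st2 <- read_string_checkpoint(f)
  expect_identical(st2$images, unname(st$history[[2]]))
  expect_identical(st2$history[[1]], unname(st$images))
  expect_equal(st2$iteration, 1L)
})
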