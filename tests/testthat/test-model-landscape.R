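test_that("designed cycle potentials encode their stated free-energy structure", {
  # single isolated well: energy at the center is baseline - depth
  p1 <- model_potential(list(gaussian_well(c(5.5, 0), 3, c(1, 1))),
                        domain = rbind(c(2, -5), c(12, 5)), baseline = 1,
                        wall_height = 0)
  expect_equal(potential_energy(p1, c(5.5, 0)), 1 - 3, tolerance = 1e-12)

  # apo-flat: outward/inward g-strips nearly degenerate at released z
  apo <- build_cycle_potential(cycle_design("apo-flat"))
  prof <- reference_pmf(apo, bin_size = 0.25,
                        range = rbind(c(4, -7.25), c(12, 1.25)),
                        strip = c(-7, -5))
  x <- bin_centers(prof, 1)
  w_out <- min(prof$values[x >= 5 & x <= 6])
  w_in <- min(prof$values[x >= 9.5 & x <= 10.5])
  expect_lt(abs(w_out - w_in), 1.5)

  # ion-bound: quadrature outward-vs-inward dG at bound z within 5% of the
  # designed 16 kBT
  pot <- build_cycle_potential(cycle_design("ion-bound"))
  des <- attr(pot, "design")
  prof_b <- reference_pmf(pot, bin_size = 0.25,
                          range = rbind(c(4, -7.25), c(12, 1.25)),
                          strip = c(-2, 0))
  dg <- state_delta_g(prof_b, c(4.75, 6.25), c(9.25, 11.25))
  expect_equal(dg, des$designed$bound_delta_g_kbt, tolerance = 0.05)

  # degenerate designs are rejected
  bad <- cycle_design("apo-flat")
  bad$basins[[2]]$center <- bad$basins[[1]]$center
  expect_error(build_cycle_potential(bad), "degenerate")
  bad2 <- cycle_design("apo-flat")
  bad2$basins[[1]]$center <- c(100, 0)
  expect_error(build_cycle_potential(bad2), "outside")
  bad3 <- cycle_design("apo-flat")
  bad3$basins[[1]]$depth <- -1
  expect_error(build_cycle_potential(bad3), "> 0")
})

test_that("potential evaluation: analytic gradients, linearity, domain checks", {
  pot <- build_cycle_potential(cycle_design("ion-bound"))

  # symmetric isolated well: zero gradient at its center
  iso <- model_potential(list(gaussian_well(c(1, -1), 4, c(0.8, 0.8))),
                         domain = rbind(c(-5, -5), c(5, 5)), wall_height = 0)
  expect_equal(evaluate_potential(iso, c(1, -1))$gradient, c(0, 0),
               tolerance = 1e-12)

  # gradient matches centered finite differences to 1e-6 relative
  set.seed(42)
  h <- 1e-5
  for (i in 1:20) {
    x <- c(runif(1, 4, 12), runif(1, -7, 1.5))
    g <- evaluate_potential(pot, x)$gradient
    fd <- vapply(1:2, function(j) {
      e <- rep(0, 2); e[j] <- h
      (potential_energy(pot, x + e) - potential_energy(pot, x - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd), 1e-6), 1e-6)
  }

  # construction is linear: two wells = sum of single wells plus baseline
  wa <- gaussian_well(c(-1, 0), 2, c(1, 1))
  wb <- gaussian_well(c(2, 1), 3, c(0.7, 1.2))
  dom <- rbind(c(-6, -6), c(6, 6))
  pa <- model_potential(list(wa), domain = dom, wall_height = 0)
  pb <- model_potential(list(wb), domain = dom, wall_height = 0)
  pab <- model_potential(list(wa, wb), domain = dom, baseline = 0.5,
                         wall_height = 0)
  set.seed(1)
  pts <- cbind(runif(10, -5, 5), runif(10, -5, 5))
  expect_equal(potential_energy(pab, pts),
               potential_energy(pa, pts) + potential_energy(pb, pts) + 0.5,
               tolerance = 1e-12)

  # removing all basins leaves a constant surface
  p0 <- model_potential(list(), domain = dom, baseline = 2, wall_height = 0)
  expect_equal(potential_energy(p0, pts), rep(2, 10), tolerance = 1e-15)

  expect_error(evaluate_potential(pot, c(100, 0)), "outside")
})

test_that("Langevin propagation: determinism, zero-noise limit, stationary law", {
  pot <- quad_pot(k = 2)

  # zero diffusion from a gradient-zero point: constant trajectory
  s0 <- langevin_settings(diffusion = 0, n_steps = 100, seed = 1)
  tr0 <- propagate_langevin(c(0, 0), pot, s0)
  expect_true(all(tr0 == 0))

  # same seed, same settings: bit-identical trajectories
  s <- langevin_settings(n_steps = 500, seed = 7)
  expect_identical(propagate_langevin(c(1, 1), pot, s),
                   propagate_langevin(c(1, 1), pot, s))

  # stationary variance kBT/k within 3 SE (small dt so the Euler-Maruyama
  # bias is far below the statistical error)
  sv <- langevin_settings(n_steps = 120000, timestep = 0.1, seed = 11)
  tr <- propagate_langevin(c(0, 0), pot, sv)
  tau <- 1 / (0.01 * 0.1 * 2 / kT0)          # OU correlation time in steps
  n_eff <- nrow(tr) / (2 * tau)
  se <- sqrt(2 / n_eff) * kT0 / 2
  for (j in 1:2)
    expect_lt(abs(var(tr[, j]) - kT0 / 2), 3 * se)

  # a divergent timestep aborts with a diagnostic
  steep <- model_potential(list(harmonic_term(c(0, 0), c(500, 500))),
                           domain = rbind(c(-10, -10), c(10, 10)),
                           wall_height = 0)
  expect_error(
    propagate_langevin(c(5, 5), steep,
                       langevin_settings(n_steps = 1000, timestep = 50, seed = 1)),
    "timestep")
  expect_error(propagate_langevin(c(50, 0), pot, s), "outside")
})

test_that("reference_pmf matches closed forms", {
  # flat potential: PMF identically zero
  fp <- flat_pot(2, lim = 2)
  r <- reference_pmf(fp, bin_size = 0.5)
  expect_equal(max(abs(r$values)), 0, tolerance = 1e-12)

  # 1D harmonic: PMF = x^2/2 * k within discretization error
  k <- 3
  h1 <- model_potential(list(harmonic_term(0, k)),
                        domain = matrix(c(-2, 2), 2, 1), wall_height = 0)
  r1 <- reference_pmf(h1, bin_size = 0.05, nquad = 8)
  x <- bin_centers(r1, 1)
  ref <- 0.5 * k * x^2
  expect_lt(max(abs(r1$values - (ref - min(ref)))), 0.01)

  # separable U(g,z) = f(g) + h(z): any strip yields f(g) + const
  sep <- model_potential(list(harmonic_term(c(0, 0), c(2, 0)),
                              harmonic_term(c(0, 1), c(0, 5))),
                         domain = rbind(c(-3, -3), c(3, 3)), wall_height = 0)
  s1 <- reference_pmf(sep, bin_size = 0.1, strip = c(-1, 0.5))
  s2 <- reference_pmf(sep, bin_size = 0.1, strip = c(1, 2.5))
  expect_equal(s1$values, s2$values, tolerance = 1e-9)
  xg <- bin_centers(s1, 1)
  fg <- xg^2
  expect_lt(max(abs(s1$values - (fg - min(fg)))), 0.03)

  expect_error(reference_pmf(fp, range = rbind(c(0, 0), c(0, 1))), "domain|>")
})

test_that("unbiased and bias-reweighted sampling reproduce the Boltzmann law", {
  # Boltzmann fidelity: long unbiased run vs quadrature reference
  pot <- model_potential(list(gaussian_well(c(0, 0), 2, c(1, 1)),
                              gaussian_well(c(2, 0), 1.5, c(0.8, 0.8))),
                         domain = rbind(c(-4, -4), c(6, 4)))
  s <- langevin_settings(n_steps = 400000, timestep = 0.2, seed = 3)
  tr <- propagate_langevin(c(0, 0), pot, s)
  edges_x <- seq(-4, 6, 0.25); edges_y <- seq(-4, 4, 0.25)
  ix <- findInterval(tr[, 1], edges_x, rightmost.closed = TRUE)
  iy <- findInterval(tr[, 2], edges_y, rightmost.closed = TRUE)
  cnt <- table(factor(ix, 1:(length(edges_x) - 1)),
               factor(iy, 1:(length(edges_y) - 1)))
  cnt <- matrix(as.numeric(cnt), length(edges_x) - 1)
  ref <- reference_pmf(pot, bin_size = 0.25)
  ok <- cnt >= 500
  w_hat <- -kT0 * log(cnt / sum(cnt))
  shift <- median(w_hat[ok] - ref$values[ok])   # free additive gauge
  expect_lt(max(abs(w_hat[ok] - ref$values[ok] - shift)), 0.3)

  # bias correctness: reweighted biased histogram matches the reference in
  # the window core
  bias <- harmonic_bias(c(1, 0), c(5, 5))
  sb <- langevin_settings(n_steps = 200000, timestep = 0.2, seed = 4)
  trb <- propagate_langevin(c(1, 0), pot, sb, bias)
  ixb <- findInterval(trb[, 1], edges_x, rightmost.closed = TRUE)
  iyb <- findInterval(trb[, 2], edges_y, rightmost.closed = TRUE)
  cntb <- table(factor(ixb, 1:(length(edges_x) - 1)),
                factor(iyb, 1:(length(edges_y) - 1)))
  cntb <- matrix(as.numeric(cntb), length(edges_x) - 1)
  mx <- (head(edges_x, -1) + tail(edges_x, -1)) / 2
  my <- (head(edges_y, -1) + tail(edges_y, -1)) / 2
  wb <- outer(mx, my, function(a, b) bias_energy(bias, cbind(a, b)))
  w_rew <- -kT0 * log(cntb / sum(cntb)) - wb   # reweight by exp(+bias/kT)
  core <- cntb >= 500 & abs(outer(mx, rep(1, length(my))) - 1) < 0.75 &
    abs(outer(rep(1, length(mx)), my)) < 0.75
  shift2 <- mean(w_rew[core] - ref$values[core])
  expect_lt(max(abs(w_rew[core] - ref$values[core] - shift2)), 0.3)

  # harmonic bias basics: non-negative, zero exactly at the center
  expect_equal(bias_energy(bias, c(1, 0)), 0)
  expect_true(all(bias_energy(bias, cbind(runif(20, -3, 3),
                                          runif(20, -3, 3))) >= 0))
})

test_that("designs and trajectories round-trip through their text formats", {
  des <- cycle_design("ion-bound")
  f <- withr::local_tempfile(fileext = ".json")
  write_potential_config(des, f)
  des2 <- read_potential_config(f)
  expect_equal(des2$domain, des$domain)
  for (i in seq_along(des$coupling)) {
    expect_equal(des2$coupling[[i]]$center, des$coupling[[i]]$center)
    expect_equal(des2$coupling[[i]]$depth, des$coupling[[i]]$depth)
  }
  # the rebuilt potential is numerically identical
  p1 <- build_cycle_potential(des)
  p2 <- build_cycle_potential(des2)
  pts <- cbind(runif(20, 4, 12), runif(20, -7, 1))
  expect_equal(potential_energy(p2, pts), potential_energy(p1, pts),
               tolerance = 1e-12)

  tr <- propagate_langevin(c(5.5, 0), p1,
                           langevin_settings(n_steps = 50, seed = 2))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(tr, tf)
  tr2 <- read_trajectory(tf)
  expect_identical(dim(tr2), dim(tr))
  expect_identical(as.numeric(tr2), as.numeric(tr))  # lossless round-trip
})
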