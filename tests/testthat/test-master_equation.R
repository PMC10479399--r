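# Master-equation evolution of the clutch state probabilities and its
# observables.

test_that("per-step event probabilities follow 1 - exp(-k dt)", {
  expect_equal(step_probabilities(0, 1), 0)
  expect_equal(step_probabilities(0.17, 1), 1 - exp(-0.17))
  expect_equal(step_probabilities(0.17, 1), 0.1563, tolerance = 1e-3)
  expect_equal(step_probabilities(1e6, 1), 1)
})

test_that("unfolding redistribution rows are binomial pmfs", {
  expect_equal(unfold_transition_row(3, 1, 0), c(0, 1, 0, 0))
  expect_equal(unfold_transition_row(2, 0, 0.1), c(0.81, 0.18, 0.01))
  set.seed(1)
  for (rep in 1:20) {
    M <- sample(1:12, 1); i <- sample(0:M, 1); p <- runif(1)
    row <- unfold_transition_row(M, i, p)
    expect_equal(sum(row), 1, tolerance = 1e-12)
    if (i > 0) expect_true(all(row[1:i] == 0))
  }
})

test_that("constant-rate limit reproduces the exponential lifetime", {
  cfg <- chain_config(12, 0, 45, 0)
  res <- master_equation(cfg, t_max = 120, p_terminate = 0.9999)
  expect_equal(res$observables$mean_clutch_duration, 1 / 0.17,
               tolerance = 2e-3)
  expect_equal(res$P_unbound, 1 - exp(-0.17 * res$time), tolerance = 1e-6)
})

test_that("probability is conserved to 1e-9 at every step", {
  res <- master_equation(chain_config(8, 4, 45, 20), t_max = 60)
  tot <- colSums(res$P[, -1, drop = FALSE]) + res$P_unbound
  expect_lt(max(abs(tot - 1)), 1e-9)
  expect_true(all(res$P >= -1e-12))
  expect_true(all(diff(res$P_unbound) >= 0))
})

test_that("observables are internally consistent", {
  cfg <- chain_config(8, 4, 45, 20)
  res <- master_equation(cfg, t_max = 60)
  obs <- res$observables
  # displacement identity x = v t
  expect_equal(obs$mean_unbind_displacement,
               cfg$v_retro * obs$mean_clutch_duration)
  # unbinding-displacement density integrates to terminal P_unbound
  expect_equal(sum(obs$unbind_displacement_density) * cfg$v_retro * res$dt,
               obs$terminal_P_unbound, tolerance = 1e-6)
  # maximum-force histogram holds the same mass
  expect_equal(sum(obs$fmax_hist$mass), obs$terminal_P_unbound,
               tolerance = 1e-9)
  # no flow, no work
  res0 <- master_equation(chain_config(4, 0, 45, 0), t_max = 30,
                          p_terminate = 0.99)
  expect_equal(res0$observables$mean_work, 0)
})

test_that("halving dt changes the mean clutch duration by < 0.5%", {
  cfg <- chain_config(8, 4, 45, 20)
  d1 <- master_equation(cfg, dt = 1e-3, t_max = 60)$observables$mean_clutch_duration
  d2 <- master_equation(cfg, dt = 5e-4, t_max = 60)$observables$mean_clutch_duration
  expect_lt(abs(d2 - d1) / d1, 0.005)
})

test_that("heterogeneous solver matches the homogeneous one for identical subdomains", {
  cfg <- chain_config(4, 3, 45, 20)
  sdm <- subdomain_spec(rep(1e-4, 4), rep(4, 4),
                        unfoldable = c(TRUE, TRUE, TRUE, FALSE))
  het <- suppressWarnings(
    master_equation_het(cfg, subdomains = sdm, dt = 5e-3, t_max = 3,
                        p_terminate = 1))
  hom <- suppressWarnings(
    master_equation(cfg, dt = 5e-3, t_max = 3, p_terminate = 1))
  expect_lt(max(abs(het$P - hom$P)), 1e-8)
  expect_lt(max(abs(het$P_unbound - hom$P_unbound)), 1e-8)
  # conservation over the full state space
  tot <- colSums(het$P_state[, -1, drop = FALSE]) + het$P_unbound
  expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("heterogeneous subdomains unfold in order of mechanical weakness", {
  cfg <- chain_config(3, 3, 45, 30)
  # subdomain 1 much weaker than 2 and 3
  sdm <- subdomain_spec(k0 = c(1e-2, 1e-5, 1e-5), dx = c(5, 2, 2))
  het <- suppressWarnings(
    master_equation_het(cfg, subdomains = sdm, dt = 2e-3, t_max = 4,
                        p_terminate = 1))
  # P(only subdomain 1 unfolded) dominates the single-unfold states at the
  # time when single-unfold probability peaks
  singles <- c(2, 3, 5)                 # bitmasks 1, 2, 4
  at <- which.max(colSums(het$P_state[singles, , drop = FALSE]))
  expect_gt(het$P_state[2, at], het$P_state[3, at])
  expect_gt(het$P_state[2, at], het$P_state[5, at])
})

test_that("solver guards reject invalid requests", {
  cfg <- chain_config(4, 3, 45, 20)
  sdm <- subdomain_spec(rep(1e-4, 4), rep(4, 4),
                        unfoldable = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(master_equation_het(cfg, subdomains = sdm, max_M = 2),
               "state space")
  sdm_bad <- subdomain_spec(rep(1e-4, 4), rep(4, 4))
  expect_error(master_equation_het(cfg, subdomains = sdm_bad), "unfoldable")
})

test_that("a sweep over one grid point equals the direct observables call", {
  sw <- me_sweep(list(n_unfoldable = 2), config = chain_config(4, 2, 45, 20),
                 t_max = 30)
  direct <- master_equation(chain_config(4, 2, 45, 20), t_max = 30)$observables
  expect_equal(sw$mean_clutch_duration, direct$mean_clutch_duration)
  expect_equal(sw$mean_work, direct$mean_work)
  expect_error(me_sweep(list(bogus = 1:2)), "vary must")
})

test_that("larger unbinding barrier distance shortens the mean displacement", {
  cfg <- chain_config(6, 3, 45, 30)
  d <- vapply(c(0.3, 0.51, 0.8), function(dx)
    master_equation(cfg, unbind = bell_params(0.17, dx),
                    t_max = 60)$observables$mean_unbind_displacement,
    numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("calibration on a single-value grid returns that value", {
  cfg <- chain_config(4, 2, 45, 30)
  res <- master_equation(cfg, unbind = bell_params(0.17, 0.5), t_max = 40)
  x <- cfg$v_retro * res$time
  dP <- colSums(res$unbind_mass)
  breaks <- seq(0, 100, by = 10)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= 10
  counts <- vapply(1:10, function(b) round(500 * sum(dP[ok][bin[ok] == b])),
                   numeric(1))
  out <- calibrate_dx_unbind(list(breaks = breaks, counts = counts),
                             grid = 0.4, config = cfg, t_max = 40)
  expect_equal(as.numeric(out), 0.4)
})
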