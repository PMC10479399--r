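# Synthetic SiMS track generation and the end-to-end recovery loop.

test_that("generation is reproducible and honours the imaging window", {
  tr1 <- generate_tracks(n = 20, seed = 5)
  tr2 <- generate_tracks(n = 20, seed = 5)
  expect_identical(tr1$tracks, tr2$tracks)
  expect_true(all(tr1$tracks$t_s <= imaging_model()$window))
  expect_true(all(table(tr1$tracks$track_id) >= 1))
})

test_that("tag geometry gives snap-backs for actin-end and jumps for integrin-end tags", {
  # noiseless kinematics straight from the state path renderer
  path <- data.frame(state = c("stationary", "clutch", "stationary"),
                     t_start = c(0, 1, 2.5), t_end = c(1, 2.5, 4))
  tf <- seq(0, 4, by = 0.1)
  xc <- talinclutch:::.tag_positions(path, "C_tag", 30, tf)
  # excursion toward 30 nm/s x 1.5 s = 45 nm (last pre-release frame at
  # t = 2.4 s reads 42 nm), then snap back to the origin
  expect_equal(max(xc), 42, tolerance = 1e-9)
  expect_equal(xc[tf >= 2.5], rep(0, sum(tf >= 2.5)))
  xn <- talinclutch:::.tag_positions(path, "N_tag", 30, tf)
  expect_equal(xn, rep(0, length(tf)))  # integrin end never moves via S-C-S
  path2 <- data.frame(state = c("stationary", "clutch", "flowing"),
                      t_start = c(0, 1, 2.5), t_end = c(1, 2.5, 4))
  xn2 <- talinclutch:::.tag_positions(path2, "N_tag", 30, tf)
  # forward jump by the accumulated stretch at clutch release
  expect_equal(xn2[tf == 2.5], 45)
  expect_equal(max(xn2), 45 + 30 * 1.5)
  xc2 <- talinclutch:::.tag_positions(path2, "C_tag", 30, tf)
  expect_equal(max(abs(xc2 - pmax(tf - 1, 0) * 30)), 0, tolerance = 1e-9)
})

test_that("noise-free ensembles separate the two tag phenotypes exactly", {
  im_c <- imaging_model("fast_100ms", localization_sd = 0, tag = "C_tag")
  im_n <- imaging_model("fast_100ms", localization_sd = 0, tag = "N_tag")
  gc <- generate_tracks(imaging = im_c, n = 150, seed = 8,
                        init_state = "stationary")
  gn <- generate_tracks(imaging = im_n, n = 150, seed = 8,
                        init_state = "stationary")
  step_min <- function(g) min(unlist(tapply(g$tracks$x_nm, g$tracks$track_id,
                                            function(x) if (length(x) > 1) diff(x) else 0)))
  step_max <- function(g) max(unlist(tapply(g$tracks$x_nm, g$tracks$track_id,
                                            function(x) if (length(x) > 1) diff(x) else 0)))
  # C-tag: snap-backs produce negative steps; N-tag never moves backwards
  expect_lt(step_min(gc), -10)
  expect_gte(step_min(gn), 0)
  # N-tag: release jumps far exceed the per-frame flow advance of 3 nm
  expect_gt(step_max(gn), 10)
})

test_that("immobile fixture reproduces the requested localization scatter", {
  im0 <- generate_immobile_fixture(12, sd = 0, seed = 2)
  expect_equal(diff(range(im0$x_nm)), 0)
  im <- generate_immobile_fixture(10000, sd = 18.6, seed = 2)
  se_sd <- 18.6 / sqrt(2 * 10000)
  expect_lt(abs(sd(im$x_nm) - 18.6), 3 * se_sd)
  expect_lt(abs(sd(im$y_nm) - 18.6), 3 * se_sd)
})

test_that("state occupancy matches the balance-equation oracle", {
  truth <- kinetic_ground_truth()
  gen <- generate_tracks(truth, imaging_model(), n = 2000, seed = 13)
  occ <- c(stationary = 0, clutch = 0, flowing = 0)
  for (p in gen$paths) {
    d <- tapply(p$t_end - p$t_start, p$state, sum)
    occ[names(d)] <- occ[names(d)] + d
  }
  occ <- occ / sum(occ)
  # independent oracle: integrate the sub-generator from the appearance split
  Q <- matrix(c(-(truth$k1 + truth$k_a), truth$k_a, 0,
                truth$k_b, -(truth$k_b + truth$k_c), truth$k_c,
                0, truth$k_d, -(truth$k3 + truth$k_d)), 3, 3, byrow = TRUE)
  pi0 <- c(truth$appearance_split, 0, 1 - truth$appearance_split)
  expected <- solve(t(Q), -pi0)
  expected <- expected / sum(expected)
  expect_equal(as.numeric(occ), as.numeric(expected), tolerance = 0.05)
  # by construction of the appearance split this matches the measured 57/4.1/39
  expect_equal(100 * expected[1], 57, tolerance = 0.2)
  expect_equal(100 * expected[2], 4.15, tolerance = 0.05)
})

test_that("apparent coarse rates agree with direct first-passage simulation", {
  truth <- kinetic_ground_truth()
  eff <- effective_coarse_rates(truth)
  # simulate stationary-appearing sojourns of the S<->C alternation
  set.seed(99)
  nrep <- 20000
  dur <- numeric(nrep); to_flow <- logical(nrep)
  for (i in seq_len(nrep)) {
    t <- 0; state <- "S"
    repeat {
      if (state == "S") {
        t <- t + rexp(1, truth$k1 + truth$k_a)
        if (runif(1) < truth$k1 / (truth$k1 + truth$k_a)) { out <- FALSE; break }
        state <- "C"
      } else {
        t <- t + rexp(1, truth$k_b + truth$k_c)
        if (runif(1) < truth$k_c / (truth$k_b + truth$k_c)) { out <- TRUE; break }
        state <- "S"
      }
    }
    dur[i] <- t; to_flow[i] <- out
  }
  lam <- 1 / mean(dur)
  q <- mean(to_flow)
  expect_equal(q * lam, as.numeric(eff["k2"]), tolerance = 0.03)
  expect_equal((1 - q) * lam, as.numeric(eff["k1"]), tolerance = 0.03)
})

test_that("the recovery experiment returns a complete comparison table", {
  rec <- recovery_experiment(n = 150, seed = 3, n_fast = 80)
  expect_setequal(rec$rates$parameter, c("k1", "k2", "k3", "k4"))
  expect_true(all(is.finite(rec$rates$recovered)))
  expect_true(all(is.finite(rec$rates$true)))
  expect_gt(rec$n_detected, 0)
  expect_true(rec$occupancy["S_percent"] > 40 &&
                rec$occupancy["S_percent"] < 80)
})
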