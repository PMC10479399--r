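# Speckle-track classification, flow-onset detection, survival-rate
# estimation, flux balance and force bookkeeping.

test_that("flux balance reproduces the measured clutch proportions", {
  rates <- list(k_a = 0.0548, k_b = 0.374, k_c = 0.680, k_d = 0.0315,
                k_2 = 0.0324, k_4 = 0.00694)
  sol <- clutch_flux_balance(57, rates)
  expect_equal(sol$C, 4.15146, tolerance = 1e-5)
  expect_equal(sol$F, 39.74726, tolerance = 1e-5)
  expect_equal(sol$X, 1.570954, tolerance = 1e-5)
  expect_lt(max(abs(sol$residuals)), 1e-9)
})

test_that("flux balance handles degenerate and invalid rate sets", {
  sol0 <- clutch_flux_balance(57, list(k_a = 0, k_b = 0.374, k_c = 0.680,
                                       k_d = 0, k_2 = 0, k_4 = 0))
  expect_equal(sol0$C, 0)
  expect_equal(sol0$F, 0)
  expect_equal(sol0$X, 0)
  expect_error(clutch_flux_balance(57, list(k_a = 0.05, k_b = 0, k_c = 0,
                                            k_d = 0, k_2 = 0, k_4 = 0)),
               "singular|residuals")
  expect_error(clutch_flux_balance(57, list(k_a = 1)), "must contain")
})

test_that("clutch rate constants derive from displacement statistics", {
  expect_equal(derive_rate_constants(1.47)$k_c, 0.680, tolerance = 5e-4)
  expect_equal(derive_rate_constants(2)$k_c, 0.5)
  rc <- derive_rate_constants(1.47, n_back_and_forth = 55,
                              n_switch_to_flow = 100)
  expect_equal(rc$k_b, 0.374, tolerance = 1e-3)
  expect_error(derive_rate_constants(1.47, 5, 0), "undefined")
})

test_that("force bookkeeping propagates the whole-cell arithmetic", {
  bk <- force_bookkeeping(concentration_uM = 3)
  expect_equal(bk$molecules_per_cell[1], 1.2285e6, tolerance = 1e-4)
  expect_equal(bk$total_force_pN[1], 4500)
  bk2 <- force_bookkeeping(concentration_uM = c(3, 5))
  expect_equal(bk2$molecules_per_cell, c(1.2285e6, 2.0475e6), tolerance = 1e-4)
  # region speckles ~5000 at the high end; per-speckle and per-clutch shares
  expect_equal(bk2$force_per_speckle_pN, c(0.5497, 0.9157), tolerance = 1e-3)
  expect_equal(bk2$force_per_clutch_pN, c(13.41, 22.34), tolerance = 1e-3)
  expect_error(force_bookkeeping(concentration_uM = 0), "positive")
})

test_that("Kaplan-Meier exponential rate is consistent and bleach-corrected", {
  set.seed(101)
  d <- rexp(10000, 0.17)
  est <- km_exponential_rate(d)
  expect_lt(abs(est$rate - 0.17) / 0.17, 0.03)
  expect_equal(est$n_events, 10000L)
  # independent censoring leaves the estimate unbiased
  cens_t <- rexp(10000, 0.05)
  obs <- pmin(d, cens_t)
  est_c <- km_exponential_rate(obs, censored = cens_t < d)
  expect_lt(abs(est_c$rate - 0.17) / 0.17, 0.05)
  expect_lt(abs(est_c$rate_mle - 0.17) / 0.17, 0.05)
  # photobleaching correction subtracts the per-second bleach rate
  est_b <- km_exponential_rate(d, bleach_per_frame = 0.0071,
                               frame_interval = 2)
  expect_equal(est_b$rate, est$rate - 0.00355)
  expect_true(est_b$bleach_corrected)
  expect_error(km_exponential_rate(c(1, 2), censored = c(TRUE, TRUE)),
               "censored")
  # degenerate single event still yields a finite rate
  one <- km_exponential_rate(c(5, 5, 5), censored = c(FALSE, TRUE, TRUE))
  expect_equal(one$rate, 1 / 15)
})

test_that("noiseless single-mode fixtures are classified exactly", {
  cats_coarse <- c("flowing", "stationary", "switching")
  cats_fast <- c("flowing", "stationary", "switching", "back_and_forth")
  set.seed(7)
  n_checked <- 0
  for (rep in 1:7) {
    for (cc in cats_coarse) {
      tr <- make_category_fixture(cc, "coarse_2s", id = 1L)
      out <- classify_tracks(tr, "coarse_2s", localization_sd = 5)
      expect_equal(out$category, cc, info = paste("coarse", cc, rep))
      n_checked <- n_checked + 1
    }
    for (cc in cats_fast) {
      tr <- make_category_fixture(cc, "fast_100ms", id = 1L)
      out <- classify_tracks(tr, "fast_100ms", localization_sd = 1)
      expect_equal(out$category, cc, info = paste("fast", cc, rep))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 49)
})

test_that("tracks below the minimum lifetime are excluded with a reason", {
  short <- make_track(rep(0, 1), 2)   # 2 frames, 2 s lifetime < 4 s
  out <- classify_tracks(short, "coarse_2s")
  expect_equal(out$category, "excluded")
  expect_match(out$reason, "lifetime")
  expect_error(classify_tracks(make_track(rep(0, 8), 1), "coarse_2s"),
               "frame interval")
})

test_that("flow-onset detection finds a constructed jump and ignores noise", {
  set.seed(11)
  sigma <- 5
  stat <- rnorm(30, 0, sigma)
  flow <- 100 + cumsum(rep(3, 30)) + rnorm(30, 0, sigma)
  tr <- data.frame(track_id = 1, frame = 1:60, t_s = (0:59) * 0.1,
                   x_nm = c(stat, flow), y_nm = rnorm(60, 0, sigma))
  ons <- detect_flow_onset(tr)
  expect_true(ons$applicable)
  expect_equal(ons$t_detect, 3.0, tolerance = 0.11)
  expect_equal(ons$delta_x, 103, tolerance = 3 * sigma)
  expect_equal(ons$flow_speed, 30, tolerance = 3)
  # immobile fixture (no run of 3 consecutive super-SD frames): no detection
  im <- generate_immobile_fixture(60, sd = 18.6, seed = 1)
  ons0 <- detect_flow_onset(im)
  expect_true(ons0$applicable)
  expect_true(is.na(ons0$t_detect))
  # too short for the stationary window
  expect_false(detect_flow_onset(im[1:9, ])$applicable)
})
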