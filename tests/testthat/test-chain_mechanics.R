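# Force laws, chain geometry and the uniform-tension solve.
# Expected values for the inverse Langevin function were frozen from an
# independent bisection oracle on coth(y) - 1/y = x.

test_that("inverse Langevin matches the bisection oracle and its domain", {
  expect_equal(inverse_langevin(0), 0)
  expect_equal(inverse_langevin(0.01), 0.0300018, tolerance = 1e-6)
  expect_equal(inverse_langevin(0.5), 1.796756, tolerance = 1e-6)
  expect_error(inverse_langevin(1), "0, 1")
  expect_error(inverse_langevin(-0.1), "0, 1")
  # round trip L(Linv(x)) = x across the working range
  x <- seq(0.02, 0.98, by = 0.02)
  y <- inverse_langevin(x)
  expect_equal(1 / tanh(y) - 1 / y, x, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("folded segments are tensile-only Hookean springs", {
  expect_equal(folded_force(2), 0)
  expect_equal(folded_force(3), 10)   # 1e4 pN/um x 1e-3 um
  expect_equal(folded_force(1), 0)    # slack convention
})

test_that("unfolded segments follow the FJC force-extension law", {
  mp <- mechanical_params()
  expect_equal(unfolded_force(0), 0)
  expect_equal(unfolded_force(27.55), 19.5844, tolerance = 1e-4)
  expect_equal(unfolded_force(5.51), 3.28977, tolerance = 1e-4)
  expect_error(unfolded_force(mp$l_contour), "contour")
  # strictly increasing
  l <- seq(0, 50, by = 0.5)
  expect_true(all(diff(unfolded_force(l)) > 0))
})

test_that("FJC extension-at-force inverts unfolded_force on 0.1-50 pN", {
  mp <- mechanical_params()
  F <- seq(0.1, 50, length.out = 40)
  y <- F * mp$kuhn_b / mp$kT
  l <- mp$l_contour * (1 / tanh(y) - 1 / y)
  expect_equal(unfolded_force(l), F, tolerance = 1e-6)
})

test_that("total chain length under retrograde loading follows the geometry", {
  cfg <- chain_config(12, 12, 90, 20)
  expect_equal(total_length(0, cfg), 28)
  expect_equal(total_length(1, cfg), sqrt(784 + 400))
  # collinear limit theta -> 0
  cfg0 <- chain_config(12, 12, theta0 = 1e-7, v_retro = 20)
  expect_equal(total_length(5, cfg0), 28 + 100, tolerance = 1e-6)
  tt <- seq(0, 30, by = 0.5)
  expect_true(all(diff(total_length(tt, cfg)) >= 0))
})

test_that("flow-direction cosine interpolates from cos(theta0) to 1", {
  cfg <- chain_config(12, 12, 90, 20)
  expect_equal(flow_direction_cosine(0, cfg), cos(pi / 2))
  expect_equal(flow_direction_cosine(1, cfg), 20 / sqrt(784 + 400),
               tolerance = 1e-9)
  expect_equal(flow_direction_cosine(1e5, cfg), 1, tolerance = 1e-3)
  cfg45 <- chain_config(12, 12, 45, 20)
  expect_equal(flow_direction_cosine(0, cfg45), cos(pi / 4))
})

test_that("uniform-tension solve satisfies both force laws and conservation", {
  cfg <- chain_config(12, 12, 45, 20)
  # slack chain
  expect_equal(solve_tension(28, 0, cfg)$tension, 0)
  # pure Hookean: each of 14 segments stretched 0.01 nm
  st <- solve_tension(28.14, 0, cfg)
  expect_equal(st$tension, 0.1, tolerance = 1e-9)
  # closed Hookean form across a grid of lengths, i = 0
  for (L in c(30, 40, 55)) {
    st <- solve_tension(L, 0, cfg)
    expect_equal(st$tension, 1e1 * (L / 14 - 2), tolerance = 1e-9)
  }
  # mixed chain: re-substitution of returned lengths into both force laws
  st <- solve_tension(150, 5, cfg)
  expect_equal(folded_force(st$l_folded), st$tension, tolerance = 1e-6)
  expect_equal(unfolded_force(st$l_unfolded), st$tension, tolerance = 1e-6)
  expect_equal(5 * st$l_unfolded + 9 * st$l_folded, 150, tolerance = 1e-6)
})

test_that("tension solve converges over a wide load/composition grid", {
  cfg <- chain_config(12, 12, 45, 20)
  for (i in c(0, 1, 6, 12)) {
    for (L in seq(20, 20 + i * 50 + 60, length.out = 8)) {
      st <- solve_tension(L, i, cfg)
      expect_gte(st$tension, 0)
      nf <- 14 - i
      expect_equal(i * st$l_unfolded + nf * st$l_folded, L,
                   tolerance = max(1e-6, 1e-9 * L))
    }
  }
})
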