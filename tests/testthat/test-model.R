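test_that("the regulation-expression function has its sigmoid properties", {
  expect_equal(phi(0), 0.5)
  expect_equal(phi(1), 0.8535533906, tolerance = 1e-10)
  u <- seq(-50, 50, length.out = 1001)
  expect_equal(phi(u) + phi(-u), rep(1, 1001), tolerance = 1e-12)
  expect_true(all(diff(phi(u)) > 0))
  expect_true(all(phi(u) > 0 & phi(u) < 1))
  expect_error(phi(Inf), "finite")
})

test_that("regulatory inputs sum weights, signals and thresholds", {
  p0 <- grn_params()
  expect_equal(regulatory_input(c(0.3, 0.1, 0.9), c(1, 1),
                                grn_params(R = p0$R, lam = p0$lam)),
               c(0, 0, 0))
  ph <- grn_params(h = c(1, -2, 3))
  expect_equal(regulatory_input(c(0, 0, 0), c(0, 0), ph), c(1, -2, 3))
  pw <- grn_params(W = matrix(1, 3, 3))
  expect_equal(regulatory_input(c(0.1, 0.2, 0.3), c(0, 0), pw),
               rep(0.6, 3))
  expect_error(regulatory_input(c(1, 2), c(0, 0), p0), "schema")
})

test_that("the right-hand side matches production minus decay", {
  p <- grn_params(R = c(0, 0, 0), lam = c(1, 2, 3))
  g <- c(0.5, 0.5, 0.5)
  expect_equal(grn_rhs(g, c(0, 0), p), -p$lam * g)
  p2 <- grn_params(R = c(1, 1, 1), lam = c(1, 1, 1))
  expect_equal(grn_rhs(c(0, 0, 0), c(0, 0), p2), rep(0.5, 3))
  # fixed point: dg/dt = 0 at g* = R phi(u*) / lambda with constant input
  p3 <- random_params(5, scale = 1)
  s <- c(0.3, 0.8)
  g <- p3$R / p3$lam * 0.5
  for (i in 1:5000)  # damped fixed-point iteration
    g <- g + 0.5 * (p3$R * phi(regulatory_input(g, s, p3)) / p3$lam - g)
  expect_equal(grn_rhs(g, s, p3), rep(0, 3), tolerance = 1e-10)
})

test_that("cell simulation reproduces closed-form decay and equilibria", {
  grid <- time_grid(61)
  aget <- matrix(0, 61, 5)
  aget[1, 1:3] <- 1
  p <- grn_params(R = rep(0, 3), lam = rep(1, 3))
  sim <- simulate_cell(aget, p, grid)
  expect_equal(unname(sim[61, ]), rep(exp(-1), 3), tolerance = 1e-6)
  expect_equal(unname(sim[31, ]), rep(exp(-grid$times[31]), 3),
               tolerance = 1e-6)
  # fixed-point initialization stays put under constant signals
  p2 <- random_params(6, scale = 1)
  s <- c(0.6, 0.2)
  g <- p2$R / p2$lam * 0.5
  for (i in 1:5000)
    g <- g + 0.5 * (p2$R * phi(regulatory_input(g, s, p2)) / p2$lam - g)
  aget2 <- cbind(matrix(g, 61, 3, byrow = TRUE),
                 matrix(s, 61, 2, byrow = TRUE))
  sim2 <- simulate_cell(aget2, p2, grid)
  expect_lt(max(abs(sweep(sim2, 2, g))), 1e-6)
})

test_that("the integrator is converged in its sub-step size", {
  fx <- tiny_agets(seed = 71, n_tracks = 3, n_frames = 31)
  p <- random_params(7, scale = 2)
  aget <- fx$agets$values[1, , ]
  s10 <- simulate_cell(aget, p, time_grid(31, substeps = 10))
  s20 <- simulate_cell(aget, p, time_grid(31, substeps = 20))
  expect_lt(max(abs(s10[31, ] - s20[31, ])), 1e-6)
})

test_that("frame-sampled solutions match a fine-step explicit-Euler oracle", {
  fx <- tiny_agets(seed = 81, n_tracks = 2, n_frames = 21)
  grid <- time_grid(21)
  for (seed in 1:20) {
    p <- random_params(seed)
    aget <- fx$agets$values[1 + seed %% 2, , ]
    sim <- simulate_cell(aget, p, grid)
    oracle <- euler_cell(aget[1, 1:3], aget[, 4:5], p, grid$dt_frame, 1000)
    expect_lt(max(abs(sim - oracle)), 1e-4)
  }
})

test_that("trajectories stay within the production/decay bounds", {
  fx <- tiny_agets(seed = 91, n_tracks = 5, n_frames = 21)
  grid <- time_grid(21)
  for (seed in 1:10) {
    p <- random_params(seed + 100, scale = 5)
    sim <- live_model(fx$agets, p, grid, clip = FALSE)
    for (a in 1:3) {
      g <- sim$values[, , a]
      g0 <- fx$agets$values[, 1, a]
      hi <- pmax(g0, p$R[a] / p$lam[a]) + 1e-9
      expect_true(all(g >= -1e-9 & g <= hi))
    }
  }
})

test_that("live-modelling equals per-cell simulation and is deterministic", {
  fx <- tiny_agets(seed = 101, n_tracks = 6, n_frames = 21)
  grid <- time_grid(21)
  p <- random_params(11, scale = 2)
  lm1 <- live_model(fx$agets, p, grid)
  single <- simulate_cell(fx$agets$values[4, , ], p, grid)
  expect_equal(unname(lm1$values[4, , 1:3]),
               unname(pmin(pmax(single, 0), 1)), tolerance = 1e-12)
  expect_identical(lm1$values, live_model(fx$agets, p, grid)$values)
  # cells with identical AGETs give identical trajectories
  dup <- fx$agets
  dup$values[2, , ] <- dup$values[1, , ]
  lm2 <- live_model(dup, p, grid)
  expect_identical(lm2$values[1, , ], lm2$values[2, , ])
  # live-modelling the generator truth reproduces forward-simulated targets
  lm3 <- live_model(fx$agets, tiny_truth()$params, grid)
  for (a in 1:3)
    expect_lt(sqrt(mean((lm3$values[, , a] - fx$agets$values[, , a])^2)),
              1e-4)
})

test_that("signal clamps replace exactly one channel", {
  fx <- tiny_agets(seed = 111, n_tracks = 4, n_frames = 11)
  wnt_up <- perturb_signals(fx$agets, perturbation_spec("wnt", 1.5))
  expect_true(all(wnt_up$values[, , "wnt"] == 1.5))
  expect_identical(wnt_up$values[, , c(1:3, 5)],
                   fx$agets$values[, , c(1:3, 5)])
  fgf_low <- perturb_signals(fx$agets, perturbation_spec("fgf", 0.01))
  expect_true(all(fgf_low$values[, , "fgf"] == 0.01))
  expect_error(perturbation_spec("tbxta", 1), "unknown signal")
  expect_error(perturbation_spec("wnt", -1), ">= 0")
  # clamping to the already-constant value changes nothing downstream
  const <- fx$agets
  const$values[, , "wnt"] <- 0.7
  clamped <- perturb_signals(const, perturbation_spec("wnt", 0.7))
  p <- random_params(13, scale = 1)
  grid <- time_grid(11)
  expect_identical(live_model(const, p, grid)$values,
                   live_model(clamped, p, grid)$values)
})

test_that("a single positive signal weight responds monotonically to clamps", {
  # tbx16 driven only by Wnt: raising the clamp never lowers g_tbx16(end)
  E <- matrix(0, 2, 3); E[1, 2] <- 4
  p <- grn_params(E = E, R = c(1, 1, 1), lam = c(1, 1, 1),
                  h = c(0, 0, 0))
  fx <- tiny_agets(seed = 121, n_tracks = 5, n_frames = 21)
  grid <- time_grid(21)
  ends <- vapply(c(0.2, 0.6, 1.0, 1.5), function(clamp) {
    sim <- live_model(
      perturb_signals(fx$agets, perturbation_spec("wnt", clamp)),
      p, grid, clip = FALSE)
    mean(sim$values[, 21, "tbx16"])
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
})
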