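test_that("log-likelihood is zero at a perfect fit and matches unit residuals", {
  fx <- tiny_agets(seed = 1, n_tracks = 4, n_frames = 11)
  grid <- time_grid(11)
  expect_equal(log_likelihood(tiny_truth()$params, fx$agets, grid = grid), 0,
               tolerance = 1e-9)
  # one gene, one cell, one frame residual of exactly sigma_a contributes -0.5
  spec <- likelihood_spec()
  base <- subset_agets(fx$agets, aget_cells(fx$agets)[1])
  shifted <- base
  # shift the *target* at the final frame only; simulation is unchanged
  shifted$values[1, 11, "tbx6"] <-
    shifted$values[1, 11, "tbx6"] + spec$sigmas["tbx6"]
  ll <- log_likelihood(tiny_truth()$params, shifted, spec, grid)
  expect_equal(ll, -0.5, tolerance = 1e-6)
})

test_that("log-likelihood equals an independent triple-loop oracle", {
  spec <- likelihood_spec()
  for (seed in 1:5) {
    fx <- tiny_agets(seed = seed + 200, n_tracks = 2, n_frames = 3)
    grid <- time_grid(3)
    p <- random_params(seed, scale = 2)
    ll <- log_likelihood(p, fx$agets, spec, grid)
    # brute force: per cell, simulate, then triple loop over genes/cells/frames
    total <- 0
    genes <- channel_schema()$genes
    for (cell in aget_cells(fx$agets)) {
      aget <- fx$agets$values[cell, , ]
      sim <- simulate_cell(aget, p, grid)
      for (a in seq_along(genes))
        for (t in 1:3)
          total <- total - 0.5 * (aget[t, a] - sim[t, a])^2 /
            spec$sigmas[[genes[a]]]^2
    }
    expect_equal(ll, unname(total), tolerance = 1e-9)
    expect_lte(ll, 0)
  }
  # non-simulable parameters give -Inf
  bad <- as.numeric(random_params(9)); bad[19] <- -1
  fx <- tiny_agets(seed = 300, n_tracks = 2, n_frames = 3)
  expect_identical(log_likelihood(bad, fx$agets, spec, time_grid(3)), -Inf)
})

test_that("the uniform prior is flat inside and impassable outside", {
  prior <- prior_spec()
  p0 <- rep(0, 24); p0[16:21] <- 1
  expect_identical(log_prior(p0, prior), 0)
  hi <- p0; hi[3] <- 250
  expect_identical(log_prior(hi, prior), -Inf)
  neg <- p0; neg[17] <- -0.1  # restricted production rate
  expect_identical(log_prior(neg, prior), -Inf)
  negw <- p0; negw[3] <- -150  # unrestricted weight may be negative
  expect_identical(log_prior(negw, prior), 0)
})

test_that("fitting-AGET selection respects the anterior bound and the seed", {
  fx <- tiny_agets(seed = 2, n_tracks = 40, n_frames = 11)
  all_sel <- select_fitting_agets(fx$agets, fx$tracks,
                                  n = length(aget_cells(fx$agets)),
                                  anterior_exclusion = 1.0)
  expect_setequal(aget_cells(all_sel), aget_cells(fx$agets))
  s1 <- select_fitting_agets(fx$agets, fx$tracks, 10, 0.9, seed = 3)
  s2 <- select_fitting_agets(fx$agets, fx$tracks, 10, 0.9, seed = 3)
  expect_identical(aget_cells(s1), aget_cells(s2))
  f1 <- fx$tracks[fx$tracks$frame == 1, ]
  ap <- f1$x[match(aget_cells(s1), f1$track_id)] / max(f1$x)
  expect_true(all(ap <= 0.9))
  expect_error(select_fitting_agets(fx$agets, fx$tracks, 1000), "only")
})

test_that("the stretch-move sampler recovers a known Gaussian posterior", {
  # 2-d Gaussian likelihood with known optimum; flat beyond that
  mu <- c(3, -2); sdv <- c(0.5, 1.5)
  lp <- function(v) sum(dnorm(v, mu, sdv, log = TRUE))
  set.seed(99)
  init <- matrix(rnorm(40, 0, 0.1), 20, 2)
  out <- ensemble_sample(lp, init, 3000)
  keep <- 1001:3000
  for (j in 1:2) {
    draws <- as.vector(out$samples[, keep, j])
    walker_means <- rowMeans(out$samples[, keep, j])
    se <- sd(walker_means) / sqrt(length(walker_means))
    expect_lt(abs(mean(draws) - mu[j]), 3 * se + 0.05 * sdv[j])
    expect_equal(sd(draws), sdv[j], tolerance = 0.2)
  }
})

test_that("sampling a flat target reproduces uniform-prior moments", {
  lo <- -50; hi <- 50
  lp <- function(v) if (all(v >= lo & v <= hi)) 0 else -Inf
  set.seed(5)
  init <- matrix(runif(60, -1, 1), 30, 2)
  out <- ensemble_sample(lp, init, 4000)
  keep <- 2001:4000
  for (j in 1:2) {
    draws <- as.vector(out$samples[, keep, j])
    walker_means <- rowMeans(out$samples[, keep, j])
    se <- sd(walker_means) / sqrt(length(walker_means))
    expect_lt(abs(mean(draws) - 0), 3 * se + 0.05 * (hi - lo))
    # spread should approach the uniform sd 100/sqrt(12)
    expect_gt(sd(draws), 0.6 * (hi - lo) / sqrt(12))
  }
})

test_that("identical seed and config give identical chains", {
  fx <- tiny_agets(seed = 3, n_tracks = 6, n_frames = 5)
  grid <- time_grid(5)
  mc <- mcmc_config(n_walkers = 52, n_steps = 40, max_extensions = 0,
                    seed = 7)
  e1 <- run_mcmc(fx$agets, config = mc, grid = grid)
  e2 <- run_mcmc(fx$agets, config = mc, grid = grid)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$log_prob, e2$log_prob)
  # stored samples always respect the prior
  prior <- prior_spec()
  flat <- flatten_samples(e1)
  expect_true(all(t(flat) >= prior$lower & t(flat) <= prior$upper))
})

test_that("walker-count guards reject degenerate ensembles", {
  expect_error(mcmc_config(n_walkers = 16), "even and >=")
  expect_error(mcmc_config(n_walkers = 51), "even and >=")
})

test_that("the K-S statistic equals a brute-force empirical-CDF oracle", {
  brute_ks <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
    Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
    max(abs(Fx - Fy))
  }
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(200 + i)
    y <- rnorm(300, mean = i / 10)
    expect_equal(ks_statistic(x, y), brute_ks(x, y), tolerance = 1e-12)
  }
})

test_that("K-S convergence accepts stable chains and flags drifting ones", {
  set.seed(10)
  stable <- posterior_ensemble(array(rnorm(8 * 400 * 24), c(8, 400, 24)))
  conv <- ks_convergence(stable)
  expect_true(conv)
  expect_length(attr(conv, "p_values"), 24)
  # identical windows always pass
  half <- array(rnorm(8 * 100 * 24), c(8, 100, 24))
  rep2 <- array(NA_real_, c(8, 200, 24))
  rep2[, 1:100, ] <- half
  rep2[, 101:200, ] <- half
  conv2 <- ks_convergence(posterior_ensemble(rep2), early_window = 1:100,
                          late_window = 101:200)
  expect_true(conv2)
  expect_true(all(attr(conv2, "statistics") == 0))  # all 24 stable
  # one wildly shifted parameter is tolerated (23 >= 20)...
  one_off <- array(rnorm(8 * 400 * 24), c(8, 400, 24))
  one_off[, 201:400, 5] <- one_off[, 201:400, 5] + 4000
  expect_true(ks_convergence(posterior_ensemble(one_off),
                             early_window = 1:80, late_window = 201:400))
  # ...but a shift in five parameters is not
  five_off <- one_off
  for (j in 1:5) five_off[, 201:400, j] <- five_off[, 201:400, j] + 4000
  expect_false(ks_convergence(posterior_ensemble(five_off),
                              early_window = 1:80, late_window = 201:400))
  expect_error(ks_convergence(stable, early_window = 1:100,
                              late_window = 50:200), "overlap")
})

test_that("overall-likelihood recomputation and MAP selection are consistent", {
  fx <- tiny_agets(seed = 4, n_tracks = 8, n_frames = 5)
  grid <- time_grid(5)
  mc <- mcmc_config(n_walkers = 52, n_steps = 30, max_extensions = 0,
                    seed = 9)
  ens <- run_mcmc(fx$agets, config = mc, grid = grid)
  # scoring on the same set it was fitted to equals the stored chain scores
  sc <- recompute_overall_likelihood(ens, fx$agets, grid = grid,
                                     n_final = 52 * 5)
  stored <- as.vector(ens$log_prob[, 26:30])
  expect_equal(sc$overall_log_likelihood, stored, tolerance = 1e-9)
  # permutation invariance in cell order
  perm <- rev(aget_cells(fx$agets))
  sc2 <- recompute_overall_likelihood(ens, subset_agets(fx$agets, perm),
                                      grid = grid, n_final = 20)
  expect_equal(sc2$overall_log_likelihood,
               tail(sc$overall_log_likelihood, 20), tolerance = 1e-9)
  map <- select_map(ens, sc)
  expect_gte(attr(map, "map_score"), max(sc$overall_log_likelihood) - 1e-12)
  map2 <- select_map(ens)
  expect_gte(attr(map2, "map_score"), max(ens$log_prob) - 1e-12)
  # truth outscores a sign-flipped variant on ground-truth targets
  vt <- as.numeric(tiny_truth()$params)
  flipped <- vt
  flipped[11] <- -flipped[11]  # Wnt -> tbx16 flipped to repression
  expect_gt(log_likelihood(vt, fx$agets, grid = grid),
            log_likelihood(flipped, fx$agets, grid = grid))
})
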