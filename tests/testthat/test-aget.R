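five_channels <- function(n, value = 0.5) {
  stats::setNames(lapply(1:5, function(i) rep(value, n)),
                  channel_schema()$channels)
}

test_that("single coincident neighbour passes its values through", {
  target <- expression_cloud(matrix(c(1, 2, 3), 1, 3))
  ch <- stats::setNames(as.list(seq(0.1, 0.5, 0.1)),
                        channel_schema()$channels)
  src <- expression_cloud(matrix(c(1, 2, 3), 1, 3), lapply(ch, identity))
  asg <- assign_frame_expression(target, list(src), n_neighbors = 1)
  expect_equal(asg$combined[1, ], unlist(ch))
})

test_that("median statistics follow their definitions at both levels", {
  # five source points at known distances with channel values 0.1..0.5
  target <- expression_cloud(matrix(0, 1, 3))
  pos <- cbind(x = 1:5, y = 0, z = 0)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  src <- expression_cloud(pos, stats::setNames(
    lapply(1:5, function(i) vals), channel_schema()$channels))
  asg <- assign_frame_expression(target, list(src), n_neighbors = 5)
  expect_equal(unname(asg$combined[1, "tbxta"]), 0.3)
  # median of per-source medians across three sources
  mk <- function(v) expression_cloud(pos, stats::setNames(
    lapply(1:5, function(i) rep(v, 5)), channel_schema()$channels))
  asg3 <- assign_frame_expression(
    target, list(mk(0.2), mk(0.6), mk(0.4)), n_neighbors = 3)
  expect_equal(unname(asg3$combined[1, "tbxta"]), 0.4)
})

test_that("neighbour sets match a brute-force all-pairs oracle, ties included", {
  set.seed(11)
  query <- matrix(runif(300), 100, 3)
  ref <- matrix(runif(600), 200, 3)
  nn <- agetr:::cpp_knn(query, ref, 5)
  expect_equal(nn$idx, brute_knn(query, ref, 5), ignore_attr = TRUE)
  # exact ties: grid positions where several reference points are equidistant
  reft <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0))
  qt <- cbind(1.5, 1.5, 0)  # 4 nearest at identical distance
  nnt <- agetr:::cpp_knn(qt, reft, 4)
  expect_equal(sort(as.vector(nnt$idx)), sort(brute_knn(qt, reft, 4)[1, ]))
  expect_equal(as.vector(nnt$idx), brute_knn(qt, reft, 4)[1, ])
})

test_that("assignments are invariant to source point order", {
  set.seed(12)
  target <- expression_cloud(matrix(runif(60), 20, 3))
  pos <- matrix(runif(300), 100, 3)
  ch <- stats::setNames(lapply(1:5, function(i) runif(100)),
                        channel_schema()$channels)
  src <- expression_cloud(pos, ch)
  perm <- sample(100)
  src_p <- expression_cloud(pos[perm, ], lapply(ch, function(v) v[perm]))
  a1 <- assign_frame_expression(target, list(src), 5)
  a2 <- assign_frame_expression(target, list(src_p), 5)
  expect_equal(a1$combined, a2$combined, tolerance = 1e-12)
})

test_that("a static tissue with one identical source yields constant AGETs", {
  cfg <- synthetic_config(n_tracks = 15, n_frames = 5, seed = 21,
                          motion_noise_sd_um = 0)
  tracks <- generate_tracks(cfg)
  tracks$x <- ave(tracks$x, tracks$track_id, FUN = function(v) v[1])
  tracks <- cell_tracks(as.data.frame(tracks))
  src <- expression_cloud(
    as.matrix(tracks[tracks$frame == 1, c("x", "y", "z")]),
    five_channels(15, 0.5))
  src$channels$tbxta <- runif(15)
  agets <- build_agets(tracks, list(src), alignments = NULL,
                       n_neighbors = 1, method = "nearest")
  for (f in 2:5)
    expect_equal(agets$values[, f, ], agets$values[, 1, ])
})

test_that("built AGET sets are complete and robust to neighbour settings", {
  cfg <- synthetic_config(n_cells_per_cloud = 400, n_tracks = 40,
                          n_frames = 8, seed = 31)
  tracks <- generate_tracks(cfg)
  sources <- generate_source_clouds(cfg, stage_jitter = 0.02)
  a5 <- build_agets(tracks, sources, n_neighbors = 5, method = "median")
  expect_identical(dim(a5$values), c(40L, 8L, 5L))
  expect_false(anyNA(a5$values))
  expect_true(all(a5$values >= 0 & a5$values <= 1))
  # per-cell robustness across neighbourhood configurations
  a1 <- build_agets(tracks, sources, n_neighbors = 1, method = "nearest")
  a10m <- build_agets(tracks, sources, n_neighbors = 10, method = "mean")
  for (other in list(a1, a10m)) {
    rms <- sqrt(apply((a5$values - other$values)^2, 3, mean))
    expect_true(all(rms < 0.1))
  }
})

test_that("tissue-level profiles of built AGETs recover the generator pattern", {
  cfg <- synthetic_config(n_cells_per_cloud = 600, n_tracks = 250,
                          n_frames = 3, seed = 41,
                          expression_noise_sd = 0.03)
  tracks <- generate_tracks(cfg)
  sources <- generate_source_clouds(cfg, stage_jitter = 0)
  a5 <- build_agets(tracks, sources, n_neighbors = 5, method = "median")
  prof <- tissue_pattern_profiles(a5, tracks, frame = 1)
  # compare against the generating logistic for tbxta; tracks cover only the
  # posterior part of the axis at frame 1, so rescale positions accordingly
  f1 <- tracks[tracks$frame == 1, ]
  scale_back <- max(f1$x) / cfg$psm_length_um
  truth <- logistic_profile(prof$tbxta$position * scale_back, 0.60, 10,
                            "posterior-high")
  expect_lt(sqrt(mean((prof$tbxta$value - truth)^2)), 0.1)
  # robustness of the tissue pattern to the neighbour count
  a10 <- build_agets(tracks, sources, n_neighbors = 10, method = "median")
  prof10 <- tissue_pattern_profiles(a10, tracks, frame = 1)
  expect_lt(sqrt(mean((prof$tbxta$value - prof10$tbxta$value)^2)), 0.05)
})

test_that("in-silico reporter export round-trips exactly", {
  fx <- tiny_agets(seed = 51, n_tracks = 8, n_frames = 6)
  dir <- withr::local_tempdir()
  paths <- export_insilico_reporter(fx$agets, fx$tracks, "tbx16", dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[3])
  expect_equal(back$value, unname(fx$agets$values[, 3, "tbx16"]))
  expect_true(all(back$value >= 0 & back$value <= 1))
})

test_that("AGET CSV round-trips and incomplete cells lose eligibility", {
  fx <- tiny_agets(seed = 61, n_tracks = 6, n_frames = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_agets(fx$agets, path)
  back <- read_agets(path)
  expect_equal(back$values, fx$agets$values, tolerance = 1e-15)
  # drop one frame of one cell
  df <- read.csv(path)
  df <- df[!(df$track_id == df$track_id[1] & df$frame == 3), ]
  write.csv(df, path, row.names = FALSE)
  expect_warning(back2 <- read_agets(path), "incomplete")
  expect_equal(dim(back2$values)[1], 5L)
})

test_that("frames without accepted alignments abort the build by name", {
  cfg <- synthetic_config(n_tracks = 10, n_frames = 3, seed = 71)
  tracks <- generate_tracks(cfg)
  src <- generate_source_cloud(cfg)
  rejected <- list(list(
    list(transform = diag(4), accepted = TRUE),
    list(transform = diag(4), accepted = FALSE),
    list(transform = diag(4), accepted = TRUE)))
  expect_error(
    build_agets(tracks, list(src), rejected, min_sources = 1),
    "frame 2")
})
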