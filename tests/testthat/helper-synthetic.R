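# Shared fixtures: small synthetic embryos and a sparse ground-truth network.

tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_cells_per_cloud = 200, n_source_clouds = 3,
                   n_tracks = 30, n_frames = 21, seed = seed, ...)
}

tiny_truth <- function() ground_truth_grn()

tiny_agets <- function(seed = 1, n_tracks = 30, n_frames = 21) {
  cfg <- synthetic_config(n_cells_per_cloud = 100, n_tracks = n_tracks,
                          n_frames = n_frames, seed = seed)
  tracks <- generate_tracks(cfg)
  list(tracks = tracks, cfg = cfg,
       agets = forward_simulate_agets(tracks, tiny_truth(),
                                      grid = time_grid(n_frames)))
}

# independent explicit-Euler oracle for one cell (fine steps per frame)
euler_cell <- function(g0, signals, params, dt_frame, steps_per_frame) {
  nf <- nrow(signals)
  out <- matrix(0, nf, 3)
  g <- g0
  out[1, ] <- g
  dt <- dt_frame / steps_per_frame
  for (f in seq_len(nf - 1)) {
    s0 <- signals[f, ]
    ds <- (signals[f + 1, ] - s0) / steps_per_frame
    for (m in seq_len(steps_per_frame)) {
      s <- s0 + ds * (m - 1)
      g <- g + dt * grn_rhs(g, s, params)
    }
    out[f + 1, ] <- g
  }
  out
}

# brute-force all-pairs k nearest neighbours (ties by lowest index)
brute_knn <- function(query, ref, k) {
  t(apply(query, 1, function(p) {
    d <- sqrt(colSums((t(ref) - p)^2))
    order(d)[seq_len(k)]  # order() breaks ties by index
  }))
}

random_params <- function(seed, scale = 3) {
  set.seed(seed)
  grn_params(W = matrix(rnorm(9, 0, scale), 3, 3),
             E = matrix(rnorm(6, 0, scale), 2, 3),
             R = runif(3, 0.5, 2), lam = runif(3, 0.5, 2),
             h = rnorm(3, 0, scale))
}
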