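#' Configuration for the synthetic PSM generator
#'
#' Describes an idealized presomitic mesoderm (PSM): a tapered-cylinder
#' tissue whose expression channels are smooth logistic functions of
#' normalized posterior-to-anterior (A-P) position plus noise, and a time
#' lapse of cells advecting anteriorly with extra positional mixing in the
#' posterior tailbud. Defaults emulate a 2 h lapse at 2-min intervals
#' (61 frames).
#'
#' @param n_cells_per_cloud points per source cloud.
#' @param n_source_clouds number of fixed-sample clouds to emulate.
#' @param n_tracks number of cell tracks in the synthetic lapse.
#' @param n_frames frames in the lapse (default 61).
#' @param frame_interval_min minutes between frames (default 2).
#' @param psm_length_um A-P length of the tissue in um.
#' @param psm_radius_um anterior radius of the tissue in um; the radius
#'   tapers ~30 percent toward the posterior tip.
#' @param channel_profile_params named list per channel with fields
#'   `midpoint` (in `[0, 1]`), `steepness`, and `orientation`
#'   (`"posterior-high"` or `"anterior-high"`).
#' @param expression_noise_sd Gaussian noise added to channel values.
#' @param motion_noise_sd_um per-frame positional noise, um.
#' @param mixing_zone_fraction posterior fraction of the A-P axis with
#'   elevated (3x) positional noise, emulating tailbud cell mixing.
#' @param seed integer; identical seed + config give bit-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_per_cloud = 500,
                             n_source_clouds = 10,
                             n_tracks = n_cells_per_cloud,
                             n_frames = 61,
                             frame_interval_min = 2,
                             psm_length_um = 200,
                             psm_radius_um = 40,
                             channel_profile_params = default_channel_profiles(),
                             expression_noise_sd = 0.05,
                             motion_noise_sd_um = 0.5,
                             mixing_zone_fraction = 0.3,
                             seed = 1L) {
  cfg <- list(n_cells_per_cloud = as.integer(n_cells_per_cloud),
              n_source_clouds = as.integer(n_source_clouds),
              n_tracks = as.integer(n_tracks),
              n_frames = as.integer(n_frames),
              frame_interval_min = frame_interval_min,
              psm_length_um = psm_length_um,
              psm_radius_um = psm_radius_um,
              channel_profile_params = channel_profile_params,
              expression_noise_sd = expression_noise_sd,
              motion_noise_sd_um = motion_noise_sd_um,
              mixing_zone_fraction = mixing_zone_fraction,
              seed = as.integer(seed))
  pos_fields <- c("n_cells_per_cloud", "n_source_clouds", "n_tracks",
                  "psm_length_um", "psm_radius_um", "frame_interval_min")
  for (f in pos_fields)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("invalid synthetic config: '", f, "' must be > 0")
  if (cfg$n_frames < 2) stop("invalid synthetic config: 'n_frames' must be >= 2")
  for (f in c("expression_noise_sd", "motion_noise_sd_um"))
    if (cfg[[f]] < 0) stop("invalid synthetic config: '", f, "' must be >= 0")
  if (cfg$mixing_zone_fraction < 0 || cfg$mixing_zone_fraction > 1)
    stop("invalid synthetic config: 'mixing_zone_fraction' must be in [0,1]")
  sch <- channel_schema()
  if (!all(sch$channels %in% names(cfg$channel_profile_params)))
    stop("invalid synthetic config: 'channel_profile_params' must cover ",
         paste(sch$channels, collapse = ","))
  for (nm in names(cfg$channel_profile_params)) {
    p <- cfg$channel_profile_params[[nm]]
    if (!p$orientation %in% c("posterior-high", "anterior-high"))
      stop("invalid synthetic config: orientation of '", nm, "'")
    if (p$midpoint < 0 || p$midpoint > 1)
      stop("invalid synthetic config: midpoint of '", nm, "' must be in [0,1]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Default logistic A-P profiles per channel
#'
#' tbxta, tbx16, Wnt and FGF are posterior-high with increasing midpoints;
#' tbx6 is anterior-high — the qualitative T-box / signalling pattern of the
#' zebrafish PSM.
#' @return Named list of per-channel profile parameters.
#' @export
default_channel_profiles <- function() {
  list(
    tbxta = list(midpoint = 0.60, steepness = 10, orientation = "posterior-high"),
    tbx16 = list(midpoint = 0.45, steepness = 10, orientation = "posterior-high"),
    tbx6  = list(midpoint = 0.55, steepness = 10, orientation = "anterior-high"),
    wnt   = list(midpoint = 0.35, steepness = 6,  orientation = "posterior-high"),
    fgf   = list(midpoint = 0.50, steepness = 6,  orientation = "posterior-high")
  )
}

#' Logistic expression profile along the normalized A-P axis
#'
#' `posterior-high` profiles equal 1 at the posterior tip (position 0) and
#' fall through 0.5 at the midpoint; `anterior-high` profiles rise instead.
#'
#' @param ap_frac normalized A-P positions in `[0, 1]` (0 = posterior tip).
#' @param midpoint profile midpoint in `[0, 1]`.
#' @param steepness logistic steepness (larger = sharper boundary).
#' @param orientation `"posterior-high"` or `"anterior-high"`.
#' @return Values in `(0, 1)`; exactly 0.5 at the midpoint.
#' @export
logistic_profile <- function(ap_frac, midpoint, steepness,
                             orientation = "posterior-high") {
  s <- switch(orientation, "posterior-high" = 1, "anterior-high" = -1,
              stop("unknown orientation '", orientation, "'"))
  1 / (1 + exp(s * steepness * (ap_frac - midpoint)))
}

psm_radius_at <- function(ap_frac, radius) radius * (0.7 + 0.3 * ap_frac)

#' Generate one synthetic fixed-sample expression cloud
#'
#' Points fill a tapered cylinder (posterior tip at the origin, radius
#' shrinking ~30 percent toward the tip) uniformly; each channel value is a
#' logistic function of normalized A-P position plus Gaussian noise, clipped
#' to `[0, 1]`. `stage_jitter` shifts the profile midpoints by a uniform
#' draw in `+-stage_jitter`, emulating the developmental spread of pooled
#' fixed samples.
#'
#' @param config a [synthetic_config()].
#' @param stage_jitter midpoint jitter amplitude (dimensionless).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An [expression_cloud()] with the five canonical channels.
#' @export
generate_source_cloud <- function(config, stage_jitter = 0,
                                  seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_cells_per_cloud
  L <- config$psm_length_um
  x <- runif(n, 0, L)
  rmax <- psm_radius_at(x / L, config$psm_radius_um)
  r <- rmax * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  pos <- cbind(x = x, y = r * cos(th), z = r * sin(th))
  channels <- list()
  for (nm in channel_schema()$channels) {
    p <- config$channel_profile_params[[nm]]
    mid <- p$midpoint + if (stage_jitter > 0) runif(1, -stage_jitter, stage_jitter) else 0
    v <- logistic_profile(x / L, mid, p$steepness, p$orientation)
    if (config$expression_noise_sd > 0)
      v <- v + rnorm(n, 0, config$expression_noise_sd)
    channels[[nm]] <- pmin(pmax(v, 0), 1)
  }
  expression_cloud(pos, channels,
                   metadata = list(synthetic = TRUE, seed = seed,
                                   stage_jitter = stage_jitter))
}

#' Generate a set of synthetic source clouds
#'
#' Seeds are derived deterministically from `config$seed`.
#'
#' @inheritParams generate_source_cloud
#' @return List of [expression_cloud()]s of length `config$n_source_clouds`.
#' @export
generate_source_clouds <- function(config, stage_jitter = 0.02) {
  lapply(seq_len(config$n_source_clouds), function(j) {
    generate_source_cloud(config, stage_jitter = stage_jitter,
                          seed = config$seed + 1000L * j)
  })
}

#' Generate synthetic cell tracks
#'
#' Cells advect posterior-to-anterior with per-cell speeds drawn uniformly
#' between 50 and 100 percent of the speed at which the fastest cell crosses
#' the whole PSM during the lapse; Gaussian positional noise is tripled
#' inside the posterior mixing zone. All positions are clamped to the tissue
#' volume, so with zero noise each cell's A-P coordinate is non-decreasing.
#'
#' @param config a [synthetic_config()].
#' @return A [cell_tracks()] object with `config$n_tracks` tracks of
#'   `config$n_frames` contiguous frames.
#' @export
generate_tracks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 777L)
  n <- config$n_tracks
  L <- config$psm_length_um
  nf <- config$n_frames
  dt <- config$frame_interval_min
  v_max <- L / ((nf - 1) * dt)            # fastest cell crosses the PSM
  speed <- runif(n, 0.5, 1) * v_max
  x <- runif(n, 0, 0.5 * L)               # start in the posterior half
  rmax0 <- psm_radius_at(x / L, config$psm_radius_um)
  rr <- rmax0 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  y <- rr * cos(th)
  z <- rr * sin(th)
  out <- vector("list", nf)
  clamp_radial <- function(x, y, z) {
    rmax <- psm_radius_at(x / L, config$psm_radius_um)
    r <- sqrt(y^2 + z^2)
    f <- ifelse(r > rmax, rmax / r, 1)
    list(y = y * f, z = z * f)
  }
  for (f in seq_len(nf)) {
    if (f > 1) {
      noise_sd <- config$motion_noise_sd_um *
        ifelse(x / L < config$mixing_zone_fraction, 3, 1)
      x <- x + speed * dt + rnorm(n, 0, noise_sd)
      y <- y + rnorm(n, 0, noise_sd)
      z <- z + rnorm(n, 0, noise_sd)
      x <- pmin(pmax(x, 0), L)
      yz <- clamp_radial(x, y, z)
      y <- yz$y; z <- yz$z
    }
    out[[f]] <- data.frame(track_id = sprintf("cell_%04d", seq_len(n)),
                           frame = f, x = x, y = y, z = z)
  }
  cell_tracks(do.call(rbind, out), frame_interval = dt)
}

#' Ground-truth GRN for parameter-recovery experiments
#'
#' Bundles a parameter set designated as generator truth with the rules that
#' supply each cell's signal inputs and initial gene levels as functions of
#' its normalized A-P position. The default network is sparse with four
#' strong interactions — Wnt and FGF activating tbx16, FGF repressing tbxta,
#' tbx16 activating tbx6 — so every strong sign is recoverable by fitting.
#'
#' @param params a [grn_params()] (decay rates must be > 0).
#' @param signal_fun function(ap_frac) -> matrix with columns wnt, fgf.
#' @param init_fun function(ap_frac) -> matrix with columns tbxta, tbx16,
#'   tbx6 giving initial gene levels.
#' @return An object of class `ground_truth_grn`.
#' @export
ground_truth_grn <- function(params = default_truth_params(),
                             signal_fun = default_signal_rule(),
                             init_fun = default_init_rule()) {
  validate_grn_params(params, for_simulation = TRUE)
  structure(list(params = params, signal_fun = signal_fun,
                 init_fun = init_fun), class = "ground_truth_grn")
}

#' @rdname ground_truth_grn
#' @export
default_truth_params <- function() {
  W <- matrix(0, 3, 3)
  E <- matrix(0, 2, 3)
  W[2, 3] <- 8    # tbx16 -> tbx6 activation
  E[1, 2] <- 8    # Wnt -> tbx16 activation
  E[2, 2] <- 8    # FGF -> tbx16 activation
  E[2, 1] <- -6   # FGF -> tbxta repression
  grn_params(W = W, E = E, R = c(2, 2, 2), lam = c(2, 2, 2),
             h = c(2, -6, -4))
}

#' @rdname ground_truth_grn
#' @export
default_signal_rule <- function() {
  prof <- default_channel_profiles()
  function(ap_frac) {
    cbind(wnt = logistic_profile(ap_frac, prof$wnt$midpoint,
                                 prof$wnt$steepness, prof$wnt$orientation),
          fgf = logistic_profile(ap_frac, prof$fgf$midpoint,
                                 prof$fgf$steepness, prof$fgf$orientation))
  }
}

#' @rdname ground_truth_grn
#' @export
default_init_rule <- function() {
  prof <- default_channel_profiles()
  function(ap_frac) {
    sapply(c("tbxta", "tbx16", "tbx6"), function(nm) {
      logistic_profile(ap_frac, prof[[nm]]$midpoint, prof[[nm]]$steepness,
                       prof[[nm]]$orientation)
    })
  }
}

#' Forward-simulate ground-truth AGETs on a track set
#'
#' Builds each cell's signal trajectory from its normalized A-P position over
#' time via the truth's signal rule, sets initial gene levels from the
#' truth's init rule, and integrates the GRN ODE exactly under the generator
#' parameters. The result is the ground-truth fitting target for
#' parameter-recovery experiments.
#'
#' @param tracks a [cell_tracks()] object (only fitting-eligible tracks are
#'   simulated).
#' @param truth a [ground_truth_grn()].
#' @param grid a [time_grid()]; defaults to the track's frame count.
#' @param ap_length A-P length used to normalize positions; defaults to the
#'   maximum x over all frames.
#' @return An [aget_set()] with simulated gene channels and rule-driven
#'   signal channels.
#' @export
forward_simulate_agets <- function(tracks, truth,
                                   grid = time_grid(attr(tracks, "n_frames")),
                                   ap_length = max(tracks$x)) {
  stopifnot(inherits(truth, "ground_truth_grn"))
  ids <- eligible_tracks(tracks)
  if (length(ids) == 0) stop("no fitting-eligible tracks to simulate")
  nf <- attr(tracks, "n_frames")
  if (grid$n_frames != nf)
    stop("time grid covers ", grid$n_frames, " frames but tracks have ", nf)
  sub <- tracks[tracks$track_id %in% ids, ]
  ord <- order(match(sub$track_id, ids), sub$frame)
  ap <- matrix(sub$x[ord] / ap_length, nrow = nf)  # frames x cells
  nc <- length(ids)
  signals <- array(0, dim = c(nf, 2, nc))
  s_flat <- truth$signal_fun(as.vector(ap))
  signals[, 1, ] <- matrix(s_flat[, "wnt"], nrow = nf)
  signals[, 2, ] <- matrix(s_flat[, "fgf"], nrow = nf)
  g0 <- t(truth$init_fun(ap[1, ]))                 # 3 x cells
  p <- truth$params
  sim <- cpp_simulate_cells(g0, signals, p$W, p$E, p$R, p$lam, p$h,
                            grid$dt_frame, grid$substeps)
  vals <- array(0, dim = c(nc, nf, 5),
                dimnames = list(ids, NULL, channel_schema()$channels))
  for (a in 1:3) vals[, , a] <- t(sim[, a, ])
  vals[, , 4] <- t(signals[, 1, ])
  vals[, , 5] <- t(signals[, 2, ])
  aget_set(vals, provenance = list(kind = "forward_simulation",
                                   truth = as.numeric(p)))
}
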