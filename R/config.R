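#' Default run configuration
#'
#' Nested per-stage settings with every default of the pipeline; the basis
#' for validating user configs. Sections: `synth`, `processing`, `align`,
#' `build`, `model`, `fit`, `cluster`, `perturb`, plus global `seed`,
#' `out_dir` and `log_level`.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    synth = list(n_cells_per_cloud = 500, n_source_clouds = 10,
                 n_tracks = 500, n_frames = 61, frame_interval_min = 2,
                 psm_length_um = 200, psm_radius_um = 40,
                 expression_noise_sd = 0.05, motion_noise_sd_um = 0.5,
                 mixing_zone_fraction = 0.3, stage_jitter = 0.02),
    processing = list(threshold_quantile = 20, window = 11, polyorder = 3,
                      n_bins = 50),
    align = list(max_iterations = 50, normal_k = 10,
                 rms_threshold_frac = 0.05, min_inlier_fraction = 0.5),
    build = list(n_neighbors = 5, method = "median", min_sources = 3),
    model = list(total_span = 1, substeps = 10),
    fit = list(n_walkers = 96, n_steps = 10000, extension_block = 10000,
               max_extensions = 1, n_fitting_agets = 200,
               anterior_exclusion = 0.85,
               sigmas = list(tbxta = 0.2, tbx16 = 0.2, tbx6 = 0.1),
               prior_lower = -200, prior_upper = 200,
               replicates = 1),
    cluster = list(k = "auto", k_range = 2:15,
                   min_overall_likelihood = -15000, max_abs_weight = 100,
                   min_cluster_fraction = 0.05),
    perturb = list(wnt_clamp = 1.5, fgf_clamp = 0.01)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown config key: '", here, "'")
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key '", here, "' must be a section")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read a run configuration (YAML or JSON)
#'
#' User files override the defaults of [default_run_config()]; unknown keys
#' are rejected with their full path.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file; `NULL` for pure defaults.
#' @return The fully resolved config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg, user)
}

#' Write the fully resolved config snapshot next to an output
#'
#' @param config resolved config list.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_config_snapshot <- function(config, path) {
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' One-line structured stage log
#'
#' @param stage pipeline stage name.
#' @param ... named fields appended as `key=value`.
#' @export
log_stage <- function(stage, ...) {
  fields <- list(...)
  msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", stage,
                if (length(fields))
                  paste0(" ", paste(names(fields), unlist(fields),
                                    sep = "=", collapse = " ")) else "")
  message(msg)
  invisible(msg)
}

#' Synthetic config from a run-config section
#' @param config resolved run config list.
#' @return A [synthetic_config()].
#' @export
synth_config_from_run <- function(config) {
  s <- config$synth
  synthetic_config(n_cells_per_cloud = s$n_cells_per_cloud,
                   n_source_clouds = s$n_source_clouds,
                   n_tracks = s$n_tracks, n_frames = s$n_frames,
                   frame_interval_min = s$frame_interval_min,
                   psm_length_um = s$psm_length_um,
                   psm_radius_um = s$psm_radius_um,
                   expression_noise_sd = s$expression_noise_sd,
                   motion_noise_sd_um = s$motion_noise_sd_um,
                   mixing_zone_fraction = s$mixing_zone_fraction,
                   seed = config$seed)
}
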