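#' Sigmoid regulation-expression function
#'
#' `phi(u) = 0.5 * (u / sqrt(u^2 + 1) + 1)`: the saturating, coarse-grained
#' transcription kinetics of the connectionist model. Strictly increasing,
#' range (0, 1), `phi(0) = 0.5`, and `phi(u) + phi(-u) = 1`.
#'
#' @param u regulatory input (dimensionless), any finite numeric vector.
#' @return Values in (0, 1).
#' @export
phi <- function(u) {
  if (any(!is.finite(u))) stop("phi: input must be finite")
  0.5 * (u / sqrt(u^2 + 1) + 1)
}

#' Total regulatory input per target gene
#'
#' `u_a = sum_b W[b,a] g_b + sum_s E[s,a] g_s + h_a`: the weighted sum of
#' gene regulators, signal inputs and the basal threshold.
#'
#' @param g length-3 gene levels (tbxta, tbx16, tbx6).
#' @param s length-2 signal levels (wnt, fgf).
#' @param params a [grn_params()].
#' @return Length-3 vector of inputs `u`.
#' @export
regulatory_input <- function(g, s, params) {
  if (length(g) != 3 || length(s) != 2)
    stop("regulatory_input: g must have 3 entries and s 2 (schema order)")
  as.vector(t(params$W) %*% g + t(params$E) %*% s + params$h)
}

#' Right-hand side of the GRN ODE
#'
#' `dg_a/dt = R_a * phi(u_a) - lambda_a * g_a` for each gene.
#'
#' @inheritParams regulatory_input
#' @return Length-3 vector `dg/dt`.
#' @export
grn_rhs <- function(g, s, params) {
  params$R * phi(regulatory_input(g, s, params)) - params$lam * g
}

#' Simulation time grid
#'
#' Model time is dimensionless: by convention the total span is the time the
#' fastest cell takes to travel the whole PSM, 1 by default, divided evenly
#' over the lapse. Integration uses `substeps` fixed RK4 sub-steps per frame
#' interval.
#'
#' @param n_frames number of frames (>= 2).
#' @param total_span model time covered by the lapse.
#' @param substeps RK4 sub-steps per frame interval.
#' @return A list of class `time_grid` with `n_frames`, `dt_frame`,
#'   `substeps` and the frame `times`.
#' @export
time_grid <- function(n_frames, total_span = 1, substeps = 10) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("time grid needs at least 2 frames")
  if (total_span <= 0 || substeps < 1) stop("invalid time grid")
  dt <- total_span / (n_frames - 1)
  structure(list(n_frames = n_frames, dt_frame = dt,
                 substeps = as.integer(substeps),
                 times = seq(0, total_span, length.out = n_frames)),
            class = "time_grid")
}

#' Simulate the GRN in one cell
#'
#' Integrates the three-gene ODE over the lapse with classical fixed-step
#' RK4. Initial gene levels are read from the first frame of the cell's
#' AGET; the time-varying Wnt/FGF inputs are linearly interpolated between
#' frame values (the system is non-autonomous).
#'
#' @param cell_aget numeric matrix (n_frames x 5) of one cell's AGET in
#'   canonical channel order, or an [aget_set()] with exactly one cell.
#' @param params a [grn_params()] with `lam > 0`.
#' @param grid a [time_grid()] matching the frame count.
#' @return Matrix (n_frames x 3) of simulated gene levels at frame times.
#' @export
simulate_cell <- function(cell_aget, params, grid) {
  if (inherits(cell_aget, "aget_set")) {
    if (dim(cell_aget$values)[1] != 1)
      stop("simulate_cell expects a single cell")
    cell_aget <- cell_aget$values[1, , ]
  }
  cell_aget <- as.matrix(cell_aget)
  if (ncol(cell_aget) != 5 || nrow(cell_aget) != grid$n_frames)
    stop("cell AGET must be n_frames x 5 and match the time grid")
  validate_grn_params(params, for_simulation = TRUE)
  signals <- array(0, dim = c(grid$n_frames, 2, 1))
  signals[, 1, 1] <- cell_aget[, 4]
  signals[, 2, 1] <- cell_aget[, 5]
  g0 <- matrix(cell_aget[1, 1:3], 3, 1)
  sim <- tryCatch(
    cpp_simulate_cells(g0, signals, params$W, params$E, params$R,
                       params$lam, params$h, grid$dt_frame, grid$substeps),
    error = function(e) stop("simulation failed: ", conditionMessage(e))
  )
  out <- sim[, , 1]
  colnames(out) <- channel_schema()$genes
  out
}

#' Live-model an AGET set: simulate the GRN in every cell
#'
#' Applies [simulate_cell()] independently to every cell (batched in C++),
#' returning an [aget_set()] whose gene channels are the simulated
#' trajectories and whose signal channels are copied from the input — ready
#' for likelihood computation or reporter export.
#'
#' @param agets an [aget_set()].
#' @param params a [grn_params()] with `lam > 0`.
#' @param grid a [time_grid()].
#' @param clip logical; clip simulated genes into `[0, 1]` for storage
#'   (values can exceed 1 transiently when `R > lambda`). Default `FALSE`
#'   keeps raw values and errors if outside `[0, 1]`.
#' @return An `aget_set` of simulated genes plus copied signals; the raw
#'   (unclipped) simulation array is attached as attribute `sim`.
#' @export
live_model <- function(agets, params, grid, clip = TRUE) {
  validate_grn_params(params, for_simulation = TRUE)
  arrs <- aget_arrays(agets)
  if (dim(arrs$targets)[1] != grid$n_frames)
    stop("AGET frame count does not match the time grid")
  nc <- dim(arrs$targets)[3]
  g0 <- matrix(arrs$targets[1, , ], nrow = 3)
  sim <- tryCatch(
    cpp_simulate_cells(g0, arrs$signals, params$W, params$E, params$R,
                       params$lam, params$h, grid$dt_frame, grid$substeps),
    error = function(e) stop("live-modelling failed: ", conditionMessage(e))
  )
  vals <- agets$values
  for (a in 1:3) vals[, , a] <- t(matrix(sim[, a, ], nrow = grid$n_frames))
  clipped <- vals
  for (a in 1:3) clipped[, , a] <- pmin(pmax(vals[, , a], 0), 1)
  out <- aget_set(pmin(pmax(clipped, 0), 1),
                  provenance = c(agets$provenance, list(simulated = TRUE)))
  if (!clip) out$values <- vals  # raw trajectories, may leave [0, 1]
  attr(out, "sim") <- sim
  out
}

#' Signal-clamp perturbation specification
#'
#' Describes an in-silico perturbation: one signal channel clamped to a
#' fixed value over an interval of frames (default: the whole simulation).
#' Clamping Wnt to 1.5 emulates Wnt over-expression; clamping FGF to 0.01
#' emulates FGF loss of function.
#'
#' @param signal `"wnt"` or `"fgf"`.
#' @param value clamp value (>= 0, dimensionless).
#' @param frames integer vector of frames to clamp (default: all).
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(signal, value, frames = NULL) {
  if (!signal %in% channel_schema()$signals)
    stop("unknown signal '", signal, "'; expected one of: ",
         paste(channel_schema()$signals, collapse = ", "))
  if (!is.finite(value) || value < 0) stop("clamp value must be >= 0")
  structure(list(signal = signal, value = value, frames = frames),
            class = "perturbation_spec")
}

#' Apply a signal clamp to an AGET set
#'
#' Replaces the clamped signal channel by the clamp value in every cell over
#' the active frames; all other channels are untouched. Note clamp values
#' may exceed 1 (over-expression), so the perturbed signal channel is stored
#' outside the usual `[0, 1]` range.
#'
#' @param agets an [aget_set()].
#' @param spec a [perturbation_spec()].
#' @return The perturbed `aget_set`.
#' @export
perturb_signals <- function(agets, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  frames <- if (is.null(spec$frames)) seq_len(aget_n_frames(agets)) else
    spec$frames
  vals <- agets$values
  vals[, frames, spec$signal] <- spec$value
  out <- agets
  out$values <- vals  # bypass [0,1] validation: clamps may exceed 1
  out$provenance <- c(out$provenance,
                      list(perturbation = list(signal = spec$signal,
                                               value = spec$value)))
  out
}
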