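#' Likelihood specification
#'
#' A Gaussian likelihood with a fixed standard deviation per gene models the
#' difference between target (AGET) and simulated expression:
#' `L = -0.5 * sum_a sum_c sum_t (T_atc - S_atc)^2 / sigma_a^2`.
#' Cells in the anterior-most PSM are excluded from fitting (regulators
#' outside the model dominate there).
#'
#' @param sigmas named length-3 vector of per-gene standard deviations;
#'   defaults `tbxta = 0.2, tbx16 = 0.2, tbx6 = 0.1`.
#' @param anterior_exclusion cells whose first-frame normalized A-P position
#'   exceeds this fraction are not fitted (default 0.85).
#' @return A list of class `likelihood_spec`.
#' @export
likelihood_spec <- function(sigmas = c(tbxta = 0.2, tbx16 = 0.2, tbx6 = 0.1),
                            anterior_exclusion = 0.85) {
  sigmas <- unlist(sigmas)[channel_schema()$genes]
  if (any(is.na(sigmas)) || any(sigmas <= 0))
    stop("likelihood sigmas must be positive and named per gene")
  if (anterior_exclusion <= 0 || anterior_exclusion > 1)
    stop("anterior_exclusion must be in (0, 1]")
  structure(list(sigmas = sigmas, anterior_exclusion = anterior_exclusion),
            class = "likelihood_spec")
}

#' Uniform prior specification
#'
#' Every parameter gets an independent uniform prior on
#' `[lower, upper]` (default -200 to 200); the parameters in the
#' positivity-restricted subset (by default the production rates R and decay
#' rates lambda) are restricted to `[0, upper]`.
#'
#' @param lower,upper global bounds.
#' @param positive indices (in canonical 24-vector order) restricted to
#'   non-negative values; default 16:21 (R then lambda).
#' @return A list of class `prior_spec` with length-24 `lower`/`upper`.
#' @export
prior_spec <- function(lower = -200, upper = 200, positive = 16:21) {
  if (lower >= upper) stop("prior requires lower < upper")
  lo <- rep(lower, N_PARAMS)
  up <- rep(upper, N_PARAMS)
  lo[positive] <- 0
  names(lo) <- names(up) <- grn_param_names()
  structure(list(lower = lo, upper = up, positive = positive),
            class = "prior_spec")
}

#' Ensemble MCMC configuration
#'
#' Reference-scale settings are 96 walkers and 10000 steps with 10000-step
#' extension blocks until convergence, fitting 200 randomly selected AGETs.
#' An affine-invariant ensemble in 24 dimensions needs more than twice as
#' many walkers as parameters (proposals live in the ensemble's affine
#' span), hence the `n_walkers >= 50` requirement.
#'
#' @param n_walkers even integer >= 50.
#' @param n_steps steps in the initial run.
#' @param extension_block steps added per extension when unconverged.
#' @param max_extensions extension cap (0 disables extensions).
#' @param n_fitting_agets cells to fit (see [select_fitting_agets()]).
#' @param seed RNG seed; identical seed + config give identical chains.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_walkers = 96, n_steps = 10000,
                        extension_block = 10000, max_extensions = 1,
                        n_fitting_agets = 200, seed = 1L) {
  n_walkers <- as.integer(n_walkers)
  if (n_walkers %% 2 != 0 || n_walkers < 2 * (N_PARAMS + 1))
    stop("n_walkers must be even and >= ", 2 * (N_PARAMS + 1))
  if (n_steps < 2) stop("n_steps must be >= 2")
  structure(list(n_walkers = n_walkers, n_steps = as.integer(n_steps),
                 extension_block = as.integer(extension_block),
                 max_extensions = as.integer(max_extensions),
                 n_fitting_agets = as.integer(n_fitting_agets),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gaussian log-likelihood of a parameter set against target AGETs
#'
#' Live-models every target cell under `params` (initial conditions and
#' signal inputs from the AGETs) and returns
#' `-0.5 * sum (T - S)^2 / sigma_a^2` over genes, cells and frames.
#' Always <= 0; exactly 0 iff the simulation reproduces the targets;
#' `-Inf` for non-simulable parameters (`lambda <= 0`) or failed
#' integrations.
#'
#' @param params a [grn_params()] or canonical 24-vector.
#' @param targets an [aget_set()] of target cells.
#' @param spec a [likelihood_spec()].
#' @param grid a [time_grid()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, targets, spec = likelihood_spec(),
                           grid = time_grid(aget_n_frames(targets))) {
  if (!inherits(params, "grn_params")) params <- grn_params_from_vector(params)
  arrs <- aget_arrays(targets)
  cpp_log_likelihood(arrs$targets, arrs$signals, params$W, params$E,
                     params$R, params$lam, params$h, spec$sigmas,
                     grid$dt_frame, grid$substeps)
}

#' Uniform log-prior: 0 inside the support, -Inf outside
#'
#' @param params a [grn_params()] or canonical 24-vector.
#' @param prior a [prior_spec()].
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  v <- if (inherits(params, "grn_params")) as.numeric(params) else
    as.numeric(params)
  if (length(v) != N_PARAMS) stop("expected 24 parameters")
  if (all(v >= prior$lower & v <= prior$upper)) 0 else -Inf
}

#' Randomly select AGETs for fitting
#'
#' Uniform sample without replacement from cells whose first-frame
#' normalized A-P position is at most the anterior-exclusion bound.
#'
#' @param agets an [aget_set()].
#' @param tracks the matching [cell_tracks()].
#' @param n number of cells to select.
#' @param anterior_exclusion max first-frame A-P fraction (0 = posterior
#'   tip, 1 = anterior end).
#' @param seed RNG seed.
#' @return The selected [aget_set()] subset; chosen ids in
#'   `provenance$selected_ids`.
#' @export
select_fitting_agets <- function(agets, tracks, n,
                                 anterior_exclusion = 0.85, seed = 1L) {
  ids <- aget_cells(agets)
  f1 <- tracks[tracks$frame == 1 & tracks$track_id %in% ids, ]
  ap <- f1$x / max(f1$x)
  eligible <- f1$track_id[ap <= anterior_exclusion]
  if (n > length(eligible))
    stop("requested ", n, " fitting AGETs but only ", length(eligible),
         " cells pass the anterior-exclusion bound")
  set.seed(seed)
  chosen <- sort(sample(eligible, n))
  out <- subset_agets(agets, chosen)
  out$provenance$selected_ids <- chosen
  out
}

#' Affine-invariant ensemble MCMC over the 24 GRN parameters
#'
#' Stretch-move ensemble sampler targeting `log_prior + log_likelihood`.
#' Walkers start in a small region of prior support (weights and thresholds
#' uniform in `[-1, 1]`, rates uniform in `[0.1, 2]`). After the initial
#' `n_steps`, the chain is extended by `extension_block` steps (up to
#' `max_extensions` times) until [ks_convergence()] passes.
#'
#' @param targets the [aget_set()] subset to fit.
#' @param spec a [likelihood_spec()].
#' @param prior a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param grid a [time_grid()].
#' @param stretch_a stretch-move scale parameter (default 2).
#' @param progress print a line every 500 steps.
#' @return A `posterior_ensemble`: list with `samples`
#'   (n_walkers x n_steps x 24), `log_prob` (n_walkers x n_steps),
#'   `acceptance` (per-walker fractions), `converged`, `config`.
#' @export
run_mcmc <- function(targets, spec = likelihood_spec(),
                     prior = prior_spec(), config = mcmc_config(),
                     grid = time_grid(aget_n_frames(targets)),
                     stretch_a = 2, progress = FALSE) {
  arrs <- aget_arrays(targets)
  sig <- spec$sigmas
  lp_fun <- function(v) {
    if (!all(v >= prior$lower & v <= prior$upper)) return(-Inf)
    cpp_log_likelihood(arrs$targets, arrs$signals,
                       matrix(v[1:9], 3, 3), matrix(v[10:15], 2, 3),
                       v[16:18], v[19:21], v[22:24], sig,
                       grid$dt_frame, grid$substeps)
  }
  set.seed(config$seed)
  K <- config$n_walkers
  # initial ensemble: small region of prior support
  X <- matrix(runif(K * N_PARAMS, -1, 1), K, N_PARAMS)
  X[, 16:21] <- matrix(runif(K * 6, 0.1, 2), K, 6)
  blk <- ensemble_sample(lp_fun, X, config$n_steps, stretch_a = stretch_a,
                         progress = progress)
  mk <- function(b, converged) {
    structure(list(samples = b$samples, log_prob = b$log_prob,
                   acceptance = b$acceptance, converged = converged,
                   config = config),
              class = "posterior_ensemble")
  }
  conv <- ks_convergence(mk(blk, NA))
  ext <- 0L
  while (!conv && ext < config$max_extensions) {
    more <- ensemble_sample(lp_fun, blk$state, config$extension_block,
                            stretch_a = stretch_a, lp0 = blk$lp,
                            progress = progress)
    blk <- list(
      samples = abind_steps(blk$samples, more$samples),
      log_prob = cbind(blk$log_prob, more$log_prob),
      acceptance = (blk$acceptance * dim(blk$log_prob)[2] +
                      more$acceptance * dim(more$log_prob)[2]) /
        (dim(blk$log_prob)[2] + dim(more$log_prob)[2]),
      state = more$state, lp = more$lp)
    ext <- ext + 1L
    conv <- ks_convergence(mk(blk, NA))
  }
  mk(blk, conv)
}

abind_steps <- function(a, b) {
  d <- dim(a)
  out <- array(NA_real_, dim = c(d[1], d[2] + dim(b)[2], d[3]))
  out[, seq_len(d[2]), ] <- a
  out[, d[2] + seq_len(dim(b)[2]), ] <- b
  out
}

#' Affine-invariant stretch-move ensemble sampler
#'
#' The Goodman-Weare stretch move: each walker proposes along the line to a
#' walker of the complementary half-ensemble, scaled by
#' `z ~ g(z) propto 1/sqrt(z)` on `[1/a, a]`, accepted with probability
#' `min(1, z^(d-1) * p(y)/p(x))`. Generic over the target density, so the
#' sampler can be validated on closed-form targets independently of the GRN
#' likelihood. Note the ensemble only explores the affine span of its
#' current states: use comfortably more than `2 * d` walkers.
#'
#' @param log_prob function(numeric vector) -> scalar log density.
#' @param init matrix (n_walkers x d) of starting positions; walker count
#'   must be even and at least 4.
#' @param n_steps steps to run.
#' @param stretch_a stretch scale `a > 1` (default 2).
#' @param lp0 optional vector of log densities of `init` (skips
#'   re-evaluation when continuing a chain).
#' @param progress print a line every 500 steps.
#' @return List with `samples` (n_walkers x n_steps x d), `log_prob`
#'   (n_walkers x n_steps), `acceptance` (per-walker fraction), `state`
#'   (final positions) and `lp` (their log densities). Errors if no
#'   proposal at all is accepted (ensemble stuck).
#' @export
ensemble_sample <- function(log_prob, init, n_steps, stretch_a = 2,
                            lp0 = NULL, progress = FALSE) {
  X <- as.matrix(init)
  K <- nrow(X)
  d <- ncol(X)
  if (K %% 2 != 0 || K < 4) stop("walker count must be even and >= 4")
  lp <- if (is.null(lp0)) apply(X, 1, log_prob) else lp0
  if (all(!is.finite(lp)))
    stop("no walker starts at finite log density")
  samples <- array(NA_real_, dim = c(K, n_steps, d))
  logp <- matrix(NA_real_, K, n_steps)
  n_accept <- rep(0, K)
  halves <- list(seq_len(K / 2), (K / 2 + 1):K)
  for (s in seq_len(n_steps)) {
    for (hi in 1:2) {
      move <- halves[[hi]]
      other <- halves[[3 - hi]]
      nh <- length(move)
      z <- ((stretch_a - 1) * runif(nh) + 1)^2 / stretch_a
      partner <- other[sample.int(length(other), nh, replace = TRUE)]
      u <- runif(nh)
      for (m in seq_len(nh)) {
        w <- move[m]
        y <- X[partner[m], ] + z[m] * (X[w, ] - X[partner[m], ])
        lpy <- log_prob(y)
        if (is.finite(lpy) &&
            log(u[m]) < (d - 1) * log(z[m]) + lpy - lp[w]) {
          X[w, ] <- y
          lp[w] <- lpy
          n_accept[w] <- n_accept[w] + 1
        }
      }
    }
    samples[, s, ] <- X
    logp[, s] <- lp
    if (progress && s %% 500 == 0)
      message("step ", s, " best logp ", round(max(lp), 2))
  }
  if (sum(n_accept) == 0)
    stop("ensemble stuck: no proposal accepted over a ", n_steps,
         "-step block; check the target and initialization")
  list(samples = samples, log_prob = logp, acceptance = n_accept / n_steps,
       state = X, lp = lp)
}

#' Assemble a posterior ensemble from raw pieces
#'
#' Mainly for constructing diagnostic fixtures; [run_mcmc()] returns this
#' class directly.
#'
#' @param samples array (n_walkers x n_steps x 24).
#' @param log_prob matrix (n_walkers x n_steps); default all 0.
#' @param acceptance per-walker acceptance fractions; default `NA`.
#' @param converged convergence flag.
#' @param config optional [mcmc_config()].
#' @return A `posterior_ensemble`.
#' @export
posterior_ensemble <- function(samples, log_prob = NULL, acceptance = NULL,
                               converged = NA, config = NULL) {
  d <- dim(samples)
  if (length(d) != 3 || d[3] != N_PARAMS)
    stop("samples must be an n_walkers x n_steps x 24 array")
  if (is.null(log_prob)) log_prob <- matrix(0, d[1], d[2])
  if (is.null(acceptance)) acceptance <- rep(NA_real_, d[1])
  structure(list(samples = samples, log_prob = log_prob,
                 acceptance = acceptance, converged = converged,
                 config = config),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  d <- dim(x$samples)
  cat("Posterior ensemble:", d[1], "walkers x", d[2], "steps x", d[3],
      "parameters; mean acceptance", round(mean(x$acceptance), 3),
      "; converged:", as.character(x$converged), "\n")
  invisible(x)
}

#' Flatten ensemble samples to a matrix
#'
#' Step-major flattening (all walkers of step 1, then step 2, ...) so "the
#' final n samples" means the most recent ones.
#'
#' @param ensemble a `posterior_ensemble`.
#' @param steps step indices to include (default: all).
#' @return Matrix ((steps * walkers) x 24) with parameter-name columns.
#' @export
flatten_samples <- function(ensemble, steps = NULL) {
  d <- dim(ensemble$samples)
  if (is.null(steps)) steps <- seq_len(d[2])
  # column-major reshape: walker varies fastest within each step
  out <- matrix(ensemble$samples[, steps, , drop = FALSE], ncol = d[3])
  dimnames(out) <- list(NULL, grn_param_names())
  out
}

#' Kolmogorov-Smirnov convergence check
#'
#' Compares, per parameter, the flattened samples of an early and a late
#' chain window with a two-sample K-S test; the chain is converged when the
#' two windows are statistically indistinguishable (p > alpha) for at least
#' `min_params` of the 24 parameters. Reference-scale windows are steps
#' (L-10000, L-8000] versus the final 5000; shorter chains fall back to the
#' first fifth versus the final half.
#'
#' @param ensemble a `posterior_ensemble`.
#' @param early_window,late_window integer step ranges; `NULL` for defaults.
#' @param alpha significance threshold (default 0.001).
#' @param min_params parameters that must be stable (default 20 of 24).
#' @return Logical flag, with attributes `p_values` and `statistics`.
#' @export
ks_convergence <- function(ensemble, early_window = NULL,
                           late_window = NULL, alpha = 0.001,
                           min_params = 20) {
  L <- dim(ensemble$samples)[2]
  if (is.null(early_window)) {
    early_window <- if (L >= 10000) (L - 9999):(L - 8000) else
      seq_len(max(2, floor(0.2 * L)))
  }
  if (is.null(late_window)) {
    late_window <- if (L >= 10000) (L - 4999):L else
      (floor(0.5 * L) + 1):L
  }
  if (length(intersect(early_window, late_window)) > 0)
    stop("K-S windows overlap; choose disjoint step ranges")
  early <- flatten_samples(ensemble, early_window)
  late <- flatten_samples(ensemble, late_window)
  pv <- numeric(N_PARAMS)
  st <- numeric(N_PARAMS)
  for (j in seq_len(N_PARAMS)) {
    kt <- suppressWarnings(ks.test(early[, j], late[, j]))
    pv[j] <- kt$p.value
    st[j] <- unname(kt$statistic)
  }
  names(pv) <- names(st) <- grn_param_names()
  out <- sum(pv > alpha) >= min_params
  attr(out, "p_values") <- pv
  attr(out, "statistics") <- st
  out
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs; thin wrapper
#' over [stats::ks.test()] exposed for diagnostics.
#'
#' @param x,y numeric samples.
#' @return The K-S statistic D.
#' @export
ks_statistic <- function(x, y) {
  unname(suppressWarnings(ks.test(x, y))$statistic)
}

#' Recompute the likelihood of retained samples on the full AGET set
#'
#' Evaluates [log_likelihood()] against all AGETs (not just the fitting
#' subset) for the final `n_final` flattened samples, making runs fitted to
#' different cell counts comparable.
#'
#' @param ensemble a `posterior_ensemble`.
#' @param all_agets the complete [aget_set()].
#' @param spec a [likelihood_spec()].
#' @param grid a [time_grid()].
#' @param n_final number of most recent flattened samples to score.
#' @return data.frame with `sample_index` (row in the flattened chain),
#'   the 24 parameters, and `overall_log_likelihood`.
#' @export
recompute_overall_likelihood <- function(ensemble, all_agets,
                                         spec = likelihood_spec(),
                                         grid = time_grid(aget_n_frames(all_agets)),
                                         n_final = 2000) {
  flat <- flatten_samples(ensemble)
  n <- nrow(flat)
  idx <- seq.int(max(1, n - n_final + 1), n)
  arrs <- aget_arrays(all_agets)
  sig <- spec$sigmas
  scores <- vapply(idx, function(i) {
    v <- flat[i, ]
    cpp_log_likelihood(arrs$targets, arrs$signals,
                       matrix(v[1:9], 3, 3), matrix(v[10:15], 2, 3),
                       v[16:18], v[19:21], v[22:24], sig,
                       grid$dt_frame, grid$substeps)
  }, numeric(1))
  out <- data.frame(sample_index = idx)
  out <- cbind(out, as.data.frame(flat[idx, , drop = FALSE]))
  out$overall_log_likelihood <- scores
  out
}

#' Maximum a posteriori (MAP) parameter set
#'
#' The retained sample with the highest score; ties break by earliest index.
#' With a `recompute_overall_likelihood()` data.frame the overall score is
#' used; with a bare ensemble, the stored log-probabilities.
#'
#' @param ensemble a `posterior_ensemble`.
#' @param overall_scores optional data.frame from
#'   [recompute_overall_likelihood()].
#' @return A [grn_params()] with attribute `map_score`.
#' @export
select_map <- function(ensemble, overall_scores = NULL) {
  if (!is.null(overall_scores)) {
    if (nrow(overall_scores) == 0) stop("no scored samples")
    best <- which.max(overall_scores$overall_log_likelihood)
    v <- as.numeric(overall_scores[best, grn_param_names()])
    score <- overall_scores$overall_log_likelihood[best]
  } else {
    flat <- flatten_samples(ensemble)
    if (nrow(flat) == 0) stop("empty ensemble")
    lp <- as.vector(ensemble$log_prob)
    best <- which.max(lp)
    v <- flat[best, ]
    score <- lp[best]
  }
  p <- grn_params_from_vector(v)
  attr(p, "map_score") <- score
  p
}
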