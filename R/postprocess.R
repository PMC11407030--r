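#' Filter posterior parameter sets
#'
#' Retains samples that (i) come from converged runs (when
#' `require_converged`), (ii) have every interaction weight (the 9 W and 6 E
#' entries) within `+-max_abs_weight`, and (iii) score at least
#' `min_overall_likelihood` on the full AGET set. Original row indices are
#' kept for provenance. Idempotent.
#'
#' @param samples numeric matrix (n x 24) of parameter vectors (canonical
#'   order), e.g. from [recompute_overall_likelihood()].
#' @param overall_scores numeric vector of length n.
#' @param min_overall_likelihood default -15000.
#' @param max_abs_weight default 100.
#' @param converged logical flag of the producing run(s); with
#'   `require_converged = TRUE`, `FALSE` empties the result.
#' @param require_converged default `TRUE`.
#' @return List with `samples` (retained rows), `scores`, and `indices`
#'   (original row numbers). Warns (not errors) when empty.
#' @export
filter_parameter_sets <- function(samples, overall_scores,
                                  min_overall_likelihood = -15000,
                                  max_abs_weight = 100,
                                  converged = TRUE,
                                  require_converged = TRUE) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(overall_scores))
    stop("scores are not aligned with samples")
  if (max_abs_weight <= 0) stop("max_abs_weight must be > 0")
  keep <- overall_scores >= min_overall_likelihood
  w <- abs(samples[, interaction_indices(), drop = FALSE])
  keep <- keep & (apply(w, 1, max) <= max_abs_weight)
  if (require_converged && !isTRUE(converged)) keep[] <- FALSE
  if (!any(keep)) warning("no parameter sets survive filtering")
  list(samples = samples[keep, , drop = FALSE],
       scores = overall_scores[keep],
       indices = which(keep))
}

#' Standardize and k-means-cluster parameter sets
#'
#' Per-parameter z-scaling (zero-variance parameters get scale 1) followed
#' by k-means with a fixed seed and multiple restarts. The scaling
#' statistics are stored so new samples can be assigned to the nearest
#' centroid.
#'
#' @param samples numeric matrix (n x 24) of retained parameter vectors.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return A `cluster_model`: list with `k`, `labels`, `centroids` (scaled
#'   space), `sizes`, `centers`/`scales` (the standardization), `totss`,
#'   `tot_withinss`, and `retained` (per-cluster logical mask, all `TRUE`
#'   until [prune_small_clusters()]).
#' @export
scale_and_cluster <- function(samples, k, seed = 1L, nstart = 10) {
  samples <- as.matrix(samples)
  if (nrow(samples) < k)
    stop("need at least k = ", k, " samples to cluster")
  centers <- colMeans(samples)
  scales <- apply(samples, 2, sd)
  degenerate <- !is.finite(scales) | scales == 0
  if (any(degenerate)) {
    message(sum(degenerate), " zero-variance parameter(s); scale set to 1")
    scales[degenerate] <- 1
  }
  z <- scale(samples, center = centers, scale = scales)
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  structure(list(k = k, labels = km$cluster, centroids = km$centers,
                 sizes = as.integer(km$size), centers = centers,
                 scales = scales, totss = km$totss,
                 tot_withinss = km$tot.withinss,
                 retained = rep(TRUE, k)),
            class = "cluster_model")
}

#' Within-cluster sum of squares across a range of k (elbow support)
#'
#' @param samples numeric matrix of parameter vectors.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed.
#' @return data.frame with `k` and `tot_withinss`.
#' @export
elbow_wss <- function(samples, k_range = 2:15, seed = 1L) {
  data.frame(k = k_range, tot_withinss = vapply(k_range, function(k) {
    scale_and_cluster(samples, k, seed = seed)$tot_withinss
  }, numeric(1)))
}

#' Pick k at the point of maximum curvature of the elbow curve
#'
#' @param wss data.frame from [elbow_wss()].
#' @return The chosen k.
#' @export
choose_k_elbow <- function(wss) {
  if (nrow(wss) < 3) return(wss$k[which.min(wss$tot_withinss)])
  y <- wss$tot_withinss
  curvature <- y[1:(length(y) - 2)] - 2 * y[2:(length(y) - 1)] +
    y[3:length(y)]
  wss$k[which.max(curvature) + 1]
}

#' Mask clusters holding less than a minimum fraction of all networks
#'
#' Clusters with `size / total < min_fraction` (default 5 percent) are
#' masked out; retained clusters and their member labels are untouched, so
#' masked plus retained counts always equal the original count.
#'
#' @param model a `cluster_model`.
#' @param min_fraction minimum cluster share (default 0.05).
#' @return The model with an updated `retained` mask.
#' @export
prune_small_clusters <- function(model, min_fraction = 0.05) {
  stopifnot(inherits(model, "cluster_model"))
  total <- sum(model$sizes)
  model$retained <- model$sizes / total >= min_fraction
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("k-means topology clustering: k =", x$k, "; sizes:",
      paste(x$sizes, collapse = ", "), "; retained:",
      sum(x$retained), "clusters\n")
  invisible(x)
}

#' Fraction of networks with a positive sign per interaction
#'
#' For each of the 15 interaction parameters (9 gene-gene and 6 signal-gene
#' weights), the fraction of samples in which the interaction is an
#' activation (value strictly > 0; exact zeros count as non-positive).
#'
#' @param samples numeric matrix (n x 24) of retained parameter vectors.
#' @return Named numeric vector of length 15 with values in `[0, 1]`.
#' @export
interaction_sign_consensus <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) stop("no samples")
  colMeans(samples[, interaction_indices(), drop = FALSE] > 0)
}

#' Summarize an in-silico perturbation experiment
#'
#' Per-cell, per-gene expression difference (perturbed minus unperturbed) at
#' the final frame, plus the per-gene mean over cells — the single-network
#' summary behind across-network perturbation histograms.
#'
#' @param sim_wt,sim_pert [aget_set()]s from [live_model()] runs on the
#'   unperturbed and perturbed inputs; must cover identical cells and
#'   frames.
#' @return A `perturbation_summary`: list with `per_cell` (cells x 3 matrix
#'   of deltas) and `mean_delta` (length-3 per-gene means).
#' @export
summarize_perturbation <- function(sim_wt, sim_pert) {
  if (!identical(aget_cells(sim_wt), aget_cells(sim_pert)) ||
      aget_n_frames(sim_wt) != aget_n_frames(sim_pert))
    stop("perturbed and unperturbed simulations cover different cells/frames")
  nf <- aget_n_frames(sim_wt)
  genes <- channel_schema()$genes
  per_cell <- sim_pert$values[, nf, genes, drop = TRUE] -
    sim_wt$values[, nf, genes, drop = TRUE]
  per_cell <- matrix(per_cell, ncol = 3,
                     dimnames = list(aget_cells(sim_wt), genes))
  structure(list(per_cell = per_cell, mean_delta = colMeans(per_cell)),
            class = "perturbation_summary")
}

#' Run one perturbation experiment end to end
#'
#' Live-models an AGET set with and without a signal clamp under one
#' network and summarizes the final-frame differences.
#'
#' @param agets an [aget_set()].
#' @param params a [grn_params()].
#' @param spec a [perturbation_spec()].
#' @param grid a [time_grid()].
#' @param clip passed to [live_model()].
#' @return A `perturbation_summary` (see [summarize_perturbation()]).
#' @export
run_perturbation <- function(agets, params, spec,
                             grid = time_grid(aget_n_frames(agets)),
                             clip = FALSE) {
  sim_wt <- live_model(agets, params, grid, clip = clip)
  sim_pert <- live_model(perturb_signals(agets, spec), params, grid,
                         clip = clip)
  summarize_perturbation(sim_wt, sim_pert)
}
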