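#' Background thresholding of expression channels
#'
#' Reduces background by zeroing every channel value strictly below that
#' channel's lower-bound threshold; values at or above the threshold pass
#' through unchanged. Idempotent and order-independent across channels.
#'
#' @param cloud an [expression_cloud()].
#' @param thresholds named numeric vector/list, channel -> lower bound (>= 0).
#' @return The thresholded cloud.
#' @export
apply_thresholds <- function(cloud, thresholds) {
  thresholds <- unlist(thresholds)
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  for (nm in names(thresholds)) {
    check_channel(cloud, nm)
    v <- cloud$channels[[nm]]
    v[v < thresholds[[nm]]] <- 0
    cloud$channels[[nm]] <- v
  }
  cloud$metadata$thresholds <- as.list(thresholds)
  cloud
}

#' Percentile-based automatic thresholds
#'
#' The reference analysis chose per-gene thresholds visually; as an objective
#' stand-in this heuristic sets each channel's threshold to its q-th
#' percentile (default 20). Always inspect the resulting spatial pattern.
#'
#' @param cloud an [expression_cloud()].
#' @param channels channels to threshold (default: all).
#' @param q percentile in `[0, 100]`.
#' @return Named numeric vector of thresholds.
#' @export
auto_thresholds <- function(cloud, channels = names(cloud$channels), q = 20) {
  vapply(channels, function(nm) {
    check_channel(cloud, nm)
    unname(quantile(cloud$channels[[nm]], q / 100, names = FALSE))
  }, numeric(1))
}

#' Normalize the A-P axis to the unit interval
#'
#' Divides every x position by the maximum x, so 0 is the posterior tip and
#' 1 the anterior end of the cloud. Idempotent.
#'
#' @param cloud an [expression_cloud()].
#' @return Cloud with `x` in `[0, 1]` and `ap_normalized = TRUE`.
#' @export
normalize_ap_axis <- function(cloud) {
  mx <- max(cloud$positions[, "x"])
  if (mx <= 0) stop("cannot A-P normalize: max x is ", mx)
  cloud$positions[, "x"] <- cloud$positions[, "x"] / mx
  cloud$ap_normalized <- TRUE
  cloud
}

#' Smoothed A-P expression profile of one channel
#'
#' Bins channel values by normalized A-P position into `n_bins` equal-width
#' bins, takes bin means, linearly interpolates isolated empty bins, and
#' smooths with a Savitzky-Golay filter. This is the tissue-level
#' quantification used both for per-experiment channel normalization and for
#' comparing reconstructed patterns with the originals.
#'
#' @param cloud an A-P-normalized [expression_cloud()].
#' @param channel channel name.
#' @param window odd Savitzky-Golay window length in bins (> `polyorder`).
#' @param polyorder polynomial order of the filter.
#' @param n_bins number of A-P bins (>= `window`).
#' @param max_empty_run largest run of consecutive empty bins tolerated
#'   (interpolated over); longer runs raise an error.
#' @return data.frame with columns `position` (bin centers) and `value`.
#' @export
ap_profile <- function(cloud, channel, window = 11, polyorder = 3,
                       n_bins = 50, max_empty_run = 5) {
  if (!cloud$ap_normalized)
    stop("cloud must be A-P normalized before profiling")
  check_channel(cloud, channel)
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (n_bins < window) stop("n_bins must be >= window")
  x <- cloud$positions[, "x"]
  v <- cloud$channels[[channel]]
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  means <- rep(NA_real_, n_bins)
  agg <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
  means[] <- as.numeric(agg)
  if (anyNA(means)) {
    runs <- rle(is.na(means))
    if (max(runs$lengths[runs$values]) > max_empty_run)
      stop("profile of '", channel, "' has a run of more than ",
           max_empty_run, " empty bins; increase points or reduce n_bins")
    means <- zoo::na.approx(means, na.rm = FALSE, rule = 2)
  }
  sm <- signal::sgolayfilt(means, p = polyorder, n = window)
  data.frame(position = (edges[-1] + edges[-(n_bins + 1)]) / 2, value = sm)
}

#' Per-experiment channel normalization by the smoothed maximum
#'
#' Each channel is divided by the maximum of its smoothed A-P profile so the
#' smoothed maximum is 1; raw points exceeding that maximum are capped at 1
#' to keep values in `[0, 1]`. Normalization is applied per source cloud,
#' never pooled across experiments. Idempotent and invariant to pre-scaling.
#'
#' @inheritParams ap_profile
#' @return The normalized cloud.
#' @export
normalize_channels <- function(cloud, window = 11, polyorder = 3,
                               n_bins = 50) {
  for (nm in names(cloud$channels)) {
    prof <- ap_profile(cloud, nm, window = window, polyorder = polyorder,
                       n_bins = n_bins)
    m <- max(prof$value)
    if (m <= 0)
      stop("channel '", nm, "' has non-positive smoothed maximum; ",
           "cannot normalize")
    # Raw points above the smoothed maximum are capped at 1, so the
    # recomputed smoothed maximum can sit marginally below 1 where noise
    # saturates the peak region.
    cloud$channels[[nm]] <- pmin(cloud$channels[[nm]] / m, 1)
  }
  cloud$metadata$channels_normalized <- TRUE
  cloud
}
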