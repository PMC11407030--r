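#' Rescale a source cloud to a target's A-P length
#'
#' Pre-processing for ICP: the source is scaled isotropically about its
#' centroid so its A-P (x) extent equals the target's; isotropic scaling
#' preserves nuclear-neighbourhood geometry. Idempotent.
#'
#' @param source,target [expression_cloud()]s, non-degenerate in x.
#' @return The rescaled source cloud.
#' @export
rescale_ap <- function(source, target) {
  ext_s <- diff(range(source$positions[, "x"]))
  ext_t <- diff(range(target$positions[, "x"]))
  if (ext_s <= 0 || ext_t <= 0)
    stop("cannot rescale: zero A-P extent (source ", ext_s,
         " um, target ", ext_t, " um)")
  f <- ext_t / ext_s
  ctr <- colMeans(source$positions)
  out <- source
  out$positions <- sweep(sweep(source$positions, 2, ctr, "-") * f,
                         2, ctr, "+")
  out$metadata$ap_rescale_factor <- f
  out
}

#' Per-point normals of a cloud by local plane fit
#'
#' Each point's normal is the smallest-eigenvalue eigenvector of the
#' covariance of its `k` nearest neighbours (the local plane normal).
#' Orientation is arbitrary (normals are used in squared point-to-plane
#' residuals only).
#'
#' @param cloud an [expression_cloud()].
#' @param k neighbours used for the plane fit.
#' @return Matrix (n x 3) of unit normals.
#' @export
estimate_normals <- function(cloud, k = 10) {
  p <- cloud$positions
  if (nrow(p) < k) stop("cloud has fewer than k = ", k, " points")
  nn <- cpp_knn(p, p, k)
  normals <- matrix(0, nrow(p), 3)
  for (i in seq_len(nrow(p))) {
    nb <- p[nn$idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    normals[i, ] <- ev$vectors[, 3]
  }
  normals
}

#' Initial alignment: centroid match + A-P axis co-orientation
#'
#' Translates the source centroid onto the target centroid and rotates the
#' source's first principal axis onto the target's (sign chosen so the A-P
#' directions co-orient), without introducing roll about that axis.
#'
#' @param source,target [expression_cloud()]s.
#' @return A 4x4 rigid transform.
#' @export
initial_alignment <- function(source, target) {
  ps <- source$positions; pt <- target$positions
  cs <- colMeans(ps); ct <- colMeans(pt)
  a <- eigen(stats::cov(ps), symmetric = TRUE)$vectors[, 1]
  b <- eigen(stats::cov(pt), symmetric = TRUE)$vectors[, 1]
  if (a[1] < 0) a <- -a  # co-orient with +x (posterior -> anterior)
  if (b[1] < 0) b <- -b
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  R <- diag(3)
  if (s > 1e-12) {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  R <- project_rotation(R)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

project_rotation <- function(R) {
  sv <- svd(R)
  out <- sv$u %*% t(sv$v)
  if (det(out) < 0) {
    u <- sv$u; u[, 3] <- -u[, 3]
    out <- u %*% t(sv$v)
  }
  out
}

#' Point-to-plane ICP registration
#'
#' Iterates closest-point correspondence and a linearized point-to-plane
#' least-squares transform update until the correspondence RMS stops
#' improving or `max_iterations` is reached. Target normals come from
#' [estimate_normals()]. Only residual-improving updates are accepted, so
#' the recorded RMS sequence is non-increasing.
#'
#' @param source,target [expression_cloud()]s (>= `normal_k` points each).
#' @param init initial 4x4 rigid transform (default:
#'   [initial_alignment()]).
#' @param max_iterations iteration cap (default 50).
#' @param max_correspondence_distance um; pairs farther apart are ignored
#'   (default: 10 percent of the target's A-P extent).
#' @param normal_k neighbours for normal estimation.
#' @return An `alignment_result`: list with `transform`, `rms_residual`
#'   (um, over final correspondences), `inlier_fraction`, `n_iterations`,
#'   `rms_history`, and `accepted` (`NA` until [alignment_qc()]).
#' @export
icp_point_to_plane <- function(source, target, init = NULL,
                               max_iterations = 50,
                               max_correspondence_distance = NULL,
                               normal_k = 10) {
  if (n_points(source) < normal_k || n_points(target) < normal_k)
    stop("registration needs at least normal_k = ", normal_k,
         " points in both clouds")
  if (is.null(max_correspondence_distance))
    max_correspondence_distance <-
      0.1 * diff(range(target$positions[, "x"]))
  tf <- if (is.null(init)) initial_alignment(source, target) else
    validate_rigid_transform(init)
  normals <- estimate_normals(target, k = normal_k)
  pt <- target$positions
  ps0 <- source$positions
  corr_rms <- function(tf) {
    p <- sweep(ps0 %*% t(tf[1:3, 1:3]), 2, tf[1:3, 4], "+")
    nn <- cpp_knn(p, pt, 1)
    keep <- nn$dist[, 1] <= max_correspondence_distance
    list(p = p, idx = nn$idx[, 1], dist = nn$dist[, 1], keep = keep,
         rms = if (any(keep)) sqrt(mean(nn$dist[keep, 1]^2)) else Inf)
  }
  cur <- corr_rms(tf)
  rms_hist <- cur$rms
  n_iter <- 0L
  for (it in seq_len(max_iterations)) {
    if (!any(cur$keep)) break
    p <- cur$p[cur$keep, , drop = FALSE]
    q <- pt[cur$idx[cur$keep], , drop = FALSE]
    nrm <- normals[cur$idx[cur$keep], , drop = FALSE]
    # linearized point-to-plane: minimize sum(((p - q) . n + (p x n) . r + n . t)^2)
    cxn <- cbind(p[, 2] * nrm[, 3] - p[, 3] * nrm[, 2],
                 p[, 3] * nrm[, 1] - p[, 1] * nrm[, 3],
                 p[, 1] * nrm[, 2] - p[, 2] * nrm[, 1])
    A <- cbind(cxn, nrm)
    b <- -rowSums((p - q) * nrm)
    x <- tryCatch(solve(crossprod(A) + 1e-12 * diag(6), crossprod(A, b)),
                  error = function(e) NULL)
    if (is.null(x)) break
    r <- x[1:3]; tr <- x[4:6]
    th <- sqrt(sum(r^2))
    Rd <- if (th < 1e-15) diag(3) else {
      k <- r / th
      kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx
    }
    delta <- diag(4); delta[1:3, 1:3] <- Rd; delta[1:3, 4] <- tr
    tf_new <- delta %*% tf
    tf_new[1:3, 1:3] <- project_rotation(tf_new[1:3, 1:3])
    cand <- corr_rms(tf_new)
    if (!is.finite(cand$rms) || cand$rms > cur$rms) break  # keep monotone
    tf <- tf_new
    improved <- cur$rms - cand$rms
    cur <- cand
    rms_hist <- c(rms_hist, cur$rms)
    n_iter <- it
    if (improved < 1e-10) break
  }
  structure(list(
    transform = validate_rigid_transform(tf),
    rms_residual = cur$rms,
    inlier_fraction = mean(cur$dist <= max_correspondence_distance),
    n_iterations = n_iter,
    rms_history = rms_hist,
    accepted = NA
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "ICP alignment: rms %.4g um, inliers %.2f, %d iterations, accepted: %s\n",
    x$rms_residual, x$inlier_fraction, x$n_iterations,
    as.character(x$accepted)))
  invisible(x)
}

#' Numeric alignment quality gate
#'
#' Replaces visual inspection with an objective rule: an alignment is
#' accepted when its RMS residual is at most `rms_threshold` and its inlier
#' fraction at least `min_inlier_fraction`. Rejected alignments are excluded
#' from AGET construction.
#'
#' @param result an `alignment_result` from [icp_point_to_plane()].
#' @param rms_threshold um; a practical default is 5 percent of the target's
#'   A-P extent.
#' @param min_inlier_fraction minimum fraction of source points with a
#'   target correspondence within the distance gate.
#' @return The result with `accepted` set.
#' @export
alignment_qc <- function(result, rms_threshold,
                         min_inlier_fraction = 0.5) {
  stopifnot(inherits(result, "alignment_result"))
  result$accepted <- is.finite(result$rms_residual) &&
    result$rms_residual <= rms_threshold &&
    result$inlier_fraction >= min_inlier_fraction
  result
}

#' Align every source cloud to every frame of a track set
#'
#' Runs [rescale_ap()] + [icp_point_to_plane()] + [alignment_qc()] for each
#' (source, frame) pair, as AGET construction requires.
#'
#' @param sources list of source [expression_cloud()]s.
#' @param tracks a [cell_tracks()] object.
#' @param frames frames to align (default: all).
#' @param rms_threshold_frac QC threshold as a fraction of each target
#'   frame's A-P extent.
#' @param min_inlier_fraction see [alignment_qc()].
#' @param ... passed to [icp_point_to_plane()].
#' @return Nested list `result[[j]][[i]]` of `alignment_result`s.
#' @export
align_sources_to_tracks <- function(sources, tracks, frames = NULL,
                                    rms_threshold_frac = 0.05,
                                    min_inlier_fraction = 0.5, ...) {
  nf <- attr(tracks, "n_frames")
  if (is.null(frames)) frames <- seq_len(nf)
  lapply(sources, function(src) {
    out <- vector("list", nf)
    for (f in frames) {
      target <- frame_cloud(tracks, f)
      scaled <- rescale_ap(src, target)
      res <- icp_point_to_plane(scaled, target, ...)
      thr <- rms_threshold_frac * diff(range(target$positions[, "x"]))
      res$rescale_factor <- scaled$metadata$ap_rescale_factor
      res$rescale_center <- colMeans(src$positions)
      out[[f]] <- alignment_qc(res, thr, min_inlier_fraction)
    }
    out
  })
}

#' Serialize / deserialize a rigid transform as JSON (row-major 4x4)
#' @param transform 4x4 rigid transform.
#' @param path JSON file path.
#' @return `write_transform` returns `path` invisibly; `read_transform` the
#'   4x4 matrix.
#' @export
write_transform <- function(transform, path) {
  transform <- validate_rigid_transform(transform)
  jsonlite::write_json(
    list(rows = unname(apply(transform, 1, function(r) r, simplify = FALSE))),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_rigid_transform(
    do.call(rbind, lapply(obj$rows, function(r) as.numeric(unlist(r)))))
}
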