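#' AGET set: approximated gene expression trajectories
#'
#' Per tracked cell and per frame, approximated values for the three T-box
#' genes and the two signal inputs, all in `[0, 1]`. This is both the
#' fitting target of the GRN model and the store of its initial and signal
#' boundary conditions.
#'
#' @param values numeric array (n_cells x n_frames x 5) with cell ids as the
#'   first dimnames and the canonical channels (`tbxta,tbx16,tbx6,wnt,fgf`)
#'   as the third.
#' @param provenance free-form list (neighbour count, averaging method,
#'   source ids...).
#' @return An object of class `aget_set`.
#' @export
aget_set <- function(values, provenance = list()) {
  sch <- channel_schema()
  if (length(dim(values)) != 3 || dim(values)[3] != 5)
    stop("AGET values must be an n_cells x n_frames x 5 array")
  if (is.null(dimnames(values)[[1]]))
    stop("AGET values need cell ids as first dimnames")
  dimnames(values)[[3]] <- sch$channels
  if (anyNA(values) || any(!is.finite(values)))
    stop("AGET values must be complete and finite")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop("AGET values must lie in [0, 1]")
  values[] <- pmin(pmax(values, 0), 1)
  structure(list(values = values, provenance = provenance),
            class = "aget_set")
}

#' @export
print.aget_set <- function(x, ...) {
  d <- dim(x$values)
  cat("AGET set:", d[1], "cells x", d[2], "frames x 5 channels\n")
  invisible(x)
}

#' Cell ids and frame count of an AGET set
#' @param agets an [aget_set()].
#' @return `aget_cells`: character vector of cell (track) ids;
#'   `aget_n_frames`: integer frame count.
#' @export
aget_cells <- function(agets) dimnames(agets$values)[[1]]

#' @rdname aget_cells
#' @export
aget_n_frames <- function(agets) dim(agets$values)[2]

#' Extract gene-target and signal-input arrays for simulation
#'
#' @param agets an [aget_set()].
#' @return List with `targets` (n_frames x 3 x n_cells) and `signals`
#'   (n_frames x 2 x n_cells) arrays in canonical channel order.
#' @export
aget_arrays <- function(agets) {
  v <- agets$values
  nc <- dim(v)[1]; nf <- dim(v)[2]
  targets <- array(0, dim = c(nf, 3, nc))
  signals <- array(0, dim = c(nf, 2, nc))
  for (a in 1:3) targets[, a, ] <- t(v[, , a])
  for (s in 1:2) signals[, s, ] <- t(v[, , 3 + s])
  list(targets = targets, signals = signals)
}

#' Subset an AGET set by cell ids
#' @param agets an [aget_set()].
#' @param ids cell ids to keep (ordering preserved as given).
#' @return The subset `aget_set`.
#' @export
subset_agets <- function(agets, ids) {
  missing <- setdiff(ids, aget_cells(agets))
  if (length(missing))
    stop("unknown cell ids: ", paste(utils::head(missing, 5), collapse = ", "))
  aget_set(agets$values[ids, , , drop = FALSE], agets$provenance)
}

#' Assign expression to the cells of one frame from aligned source clouds
#'
#' For every cell, finds its `n_neighbors` closest points (Euclidean
#' distance, in the target frame's coordinate system) in each aligned source
#' cloud and computes a per-channel statistic over them; the per-source
#' statistics are then combined across sources with the same statistic
#' family (median of medians by default). Distance ties at the n-th
#' neighbour break by lowest source-point index.
#'
#' @param target_frame an [expression_cloud()] of cell positions.
#' @param aligned_sources list of source [expression_cloud()]s already
#'   transformed into the target frame's coordinates.
#' @param n_neighbors neighbours per source (>= 1).
#' @param method `"median"`, `"mean"` or `"nearest"` (single closest point).
#' @param channels channels to assign (default: canonical five).
#' @return List with `per_source` (list over sources of cells x channels
#'   matrices `M_ijk`) and `combined` (cells x channels matrix `M_ik`).
#' @export
assign_frame_expression <- function(target_frame, aligned_sources,
                                    n_neighbors = 5,
                                    method = c("median", "mean", "nearest"),
                                    channels = channel_schema()$channels) {
  method <- match.arg(method)
  if (length(aligned_sources) == 0)
    stop("no aligned source clouds supplied")
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  k <- if (method == "nearest") 1L else as.integer(n_neighbors)
  q <- target_frame$positions
  per_source <- lapply(aligned_sources, function(src) {
    if (n_points(src) < k)
      stop("source cloud has ", n_points(src), " points; ", k, " required")
    for (nm in channels) check_channel(src, nm)
    nn <- cpp_knn(q, src$positions, k)
    m <- matrix(0, nrow(q), length(channels),
                dimnames = list(NULL, channels))
    for (ci in seq_along(channels)) {
      vals <- matrix(src$channels[[channels[ci]]][nn$idx],
                     nrow = nrow(q))
      m[, ci] <- if (k == 1) vals[, 1] else
        apply(vals, 1, if (method == "mean") mean else median)
    }
    m
  })
  combine <- if (method == "mean") mean else median
  combined <- per_source[[1]]
  if (length(per_source) > 1) {
    arr <- simplify2array(per_source)  # cells x channels x sources
    combined <- apply(arr, c(1, 2), combine)
  }
  list(per_source = per_source, combined = combined)
}

#' Build AGETs for a whole time lapse
#'
#' For every frame, re-transforms each QC-accepted source cloud with that
#' frame's alignment, assigns per-cell expression with
#' [assign_frame_expression()], and assembles per-cell trajectories for all
#' fitting-eligible tracks.
#'
#' @param tracks a [cell_tracks()] object.
#' @param sources list of processed source [expression_cloud()]s (values in
#'   `[0, 1]`).
#' @param alignments nested list `alignments[[j]][[i]]`: the
#'   [alignment_qc()]-annotated result of aligning source j to frame i. If
#'   `NULL`, sources are used untransformed (static-tissue shortcut).
#' @param n_neighbors neighbours per source.
#' @param method averaging statistic (see [assign_frame_expression()]).
#' @param min_sources minimum accepted sources a frame needs (default 3; a
#'   frame below the minimum aborts the build, naming the frame).
#' @return An [aget_set()] covering every fitting-eligible track.
#' @export
build_agets <- function(tracks, sources, alignments = NULL, n_neighbors = 5,
                        method = "median", min_sources = 3) {
  ids <- eligible_tracks(tracks)
  if (length(ids) == 0) stop("no fitting-eligible tracks")
  nf <- attr(tracks, "n_frames")
  sch <- channel_schema()
  vals <- array(NA_real_, dim = c(length(ids), nf, 5),
                dimnames = list(ids, NULL, sch$channels))
  min_needed <- if (is.null(alignments)) 1 else min(min_sources, length(sources))
  for (f in seq_len(nf)) {
    target <- frame_cloud(tracks, f, ids)
    if (is.null(alignments)) {
      aligned <- sources
    } else {
      keep <- vapply(seq_along(sources), function(j) {
        isTRUE(alignments[[j]][[f]]$accepted)
      }, logical(1))
      if (sum(keep) < min_needed)
        stop("frame ", f, " has ", sum(keep),
             " accepted source alignments; ", min_needed, " required")
      aligned <- lapply(which(keep), function(j) {
        al <- alignments[[j]][[f]]
        s <- sources[[j]]
        if (!is.null(al$rescale_factor)) {  # replay the A-P pre-rescaling
          ctr <- al$rescale_center
          s$positions <- sweep(sweep(s$positions, 2, ctr, "-") *
                                 al$rescale_factor, 2, ctr, "+")
        }
        apply_rigid_transform(s, al$transform)
      })
    }
    asg <- assign_frame_expression(target, aligned, n_neighbors, method)
    vals[, f, ] <- asg$combined
  }
  aget_set(vals, provenance = list(
    kind = "neighbor_assignment", n_neighbors = n_neighbors,
    method = method, n_sources = length(sources)
  ))
}

#' Tissue-level A-P expression profiles of an AGET frame
#'
#' Places each cell at its normalized A-P position in the chosen frame and
#' computes a smoothed per-channel profile via [ap_profile()] — the
#' projection used to compare reconstructed tissue patterns with the
#' originals.
#'
#' @param agets an [aget_set()].
#' @param tracks the [cell_tracks()] the AGETs were built on.
#' @param frame frame index.
#' @inheritParams ap_profile
#' @param channels channels to profile.
#' @return Named list of profile data.frames (see [ap_profile()]).
#' @export
tissue_pattern_profiles <- function(agets, tracks, frame, window = 11,
                                    polyorder = 3, n_bins = 50,
                                    channels = channel_schema()$channels) {
  ids <- aget_cells(agets)
  target <- frame_cloud(tracks, frame, ids)
  ch <- lapply(channels, function(nm) agets$values[, frame, nm])
  names(ch) <- channels
  cloud <- expression_cloud(target$positions, ch)
  cloud <- normalize_ap_axis(cloud)
  out <- lapply(channels, function(nm)
    ap_profile(cloud, nm, window = window, polyorder = polyorder,
               n_bins = n_bins))
  names(out) <- channels
  out
}

#' Export an in-silico reporter as per-frame CSVs
#'
#' Writes one `x,y,z,value` CSV per frame for the chosen channel, painting
#' AGET values onto the moving cell positions — the file series behind
#' reporter-style animations.
#'
#' @param agets an [aget_set()].
#' @param tracks the matching [cell_tracks()].
#' @param channel channel to export.
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Character vector of the written file paths, invisibly.
#' @export
export_insilico_reporter <- function(agets, tracks, channel, out_dir,
                                     prefix = paste0("reporter_", channel)) {
  if (!channel %in% channel_schema()$channels)
    stop("unknown channel '", channel, "'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- aget_cells(agets)
  nf <- aget_n_frames(agets)
  paths <- character(nf)
  for (f in seq_len(nf)) {
    target <- frame_cloud(tracks, f, ids)
    df <- data.frame(target$positions, value = agets$values[, f, channel])
    paths[f] <- file.path(out_dir, sprintf("%s_frame%03d.csv", prefix, f))
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              paths[f], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read / write AGET sets as CSV
#'
#' Dialect: `track_id,frame,tbxta,tbx16,tbx6,wnt,fgf`, one row per cell per
#' frame. On read, cells missing any frame of the lapse are dropped with a
#' warning (their fitting eligibility is void) and recorded in
#' `provenance$dropped_cells`.
#'
#' @param agets an [aget_set()].
#' @param path CSV path.
#' @return `write_agets` returns `path` invisibly; `read_agets` an
#'   [aget_set()].
#' @export
write_agets <- function(agets, path) {
  ids <- aget_cells(agets)
  nf <- aget_n_frames(agets)
  df <- data.frame(track_id = rep(ids, each = nf),
                   frame = rep(seq_len(nf), length(ids)))
  for (nm in channel_schema()$channels)
    df[[nm]] <- as.vector(t(agets$values[, , nm]))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_agets
#' @export
read_agets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  sch <- channel_schema()
  need <- c("track_id", "frame", sch$channels)
  if (!all(need %in% names(df)))
    stop("AGET CSV must have columns ", paste(need, collapse = ","))
  nf <- max(df$frame)
  counts <- table(df$track_id)
  complete <- names(counts)[counts == nf]
  dropped <- setdiff(names(counts), complete)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " cell(s) with incomplete frame coverage (not fitting-eligible): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  df <- df[df$track_id %in% complete, ]
  df <- df[order(match(df$track_id, complete), df$frame), ]
  vals <- array(NA_real_, dim = c(length(complete), nf, 5),
                dimnames = list(complete, NULL, sch$channels))
  for (nm in sch$channels)
    vals[, , nm] <- matrix(df[[nm]], nrow = length(complete), byrow = TRUE)
  aget_set(vals, provenance = list(source_file = path,
                                   dropped_cells = dropped))
}
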