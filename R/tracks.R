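#' Cell track set
#'
#' Per-track ordered nuclear positions across time-lapse frames — the spatial
#' skeleton AGETs are painted onto. Frames are 1-based. A track is
#' "fitting-eligible" only if it spans every frame of the lapse with no gaps,
#' mirroring the rule that only cells tracked consecutively through the whole
#' time lapse are fitted.
#'
#' @param df data.frame with columns `track_id`, `frame`, `x`, `y`, `z`
#'   (positions in um).
#' @param frame_interval minutes between consecutive frames.
#' @return An object of class `cell_tracks`: the (sorted) data.frame with
#'   attributes `frame_interval`, `n_frames` (the lapse length, max frame)
#'   and `eligible` (named logical per track).
#' @export
cell_tracks <- function(df, frame_interval = 2) {
  need <- c("track_id", "frame", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("tracks need columns ", paste(need, collapse = ","), "; got: ",
         paste(names(df), collapse = ","))
  for (nm in c("frame", "x", "y", "z"))
    if (!is.numeric(df[[nm]])) stop("column '", nm, "' must be numeric")
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("track positions must be finite")
  df <- df[order(df$track_id, df$frame), need]
  rownames(df) <- NULL
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup)) {
    bad <- df[dup, ][1, ]
    stop("duplicate (track, frame) pair: track ", bad$track_id,
         ", frame ", bad$frame)
  }
  n_frames <- max(df$frame)
  by_track <- split(df$frame, df$track_id)
  eligible <- vapply(by_track, function(f) {
    length(f) == n_frames && identical(as.integer(f), seq_len(n_frames))
  }, logical(1))
  structure(df, class = c("cell_tracks", "data.frame"),
            frame_interval = frame_interval, n_frames = n_frames,
            eligible = eligible)
}

#' @export
print.cell_tracks <- function(x, ...) {
  el <- attr(x, "eligible")
  cat("Cell track set:", length(el), "tracks,", attr(x, "n_frames"),
      "frames,", sum(el), "fitting-eligible\n")
  invisible(x)
}

#' Track ids eligible for model fitting (full, gap-free coverage)
#' @param tracks a `cell_tracks` object.
#' @return Character vector of track ids.
#' @export
eligible_tracks <- function(tracks) {
  el <- attr(tracks, "eligible")
  names(el)[el]
}

#' Positions of all cells present at one frame
#' @param tracks a `cell_tracks` object.
#' @param frame frame index (1-based).
#' @param track_ids optional subset/ordering of track ids.
#' @return An [expression_cloud()] of the cell positions (no channels), with
#'   the track ids in `metadata$track_ids`.
#' @export
frame_cloud <- function(tracks, frame, track_ids = NULL) {
  sub <- tracks[tracks$frame == frame, , drop = FALSE]
  if (!is.null(track_ids)) {
    sub <- sub[match(track_ids, sub$track_id), , drop = FALSE]
    if (anyNA(sub$track_id))
      stop("frame ", frame, " is missing requested tracks")
  }
  if (nrow(sub) == 0) stop("no cells at frame ", frame)
  expression_cloud(as.matrix(sub[, c("x", "y", "z")]),
                   metadata = list(frame = frame, track_ids = sub$track_id))
}

#' Read / write cell tracks CSV
#'
#' Dialect: header `track_id,frame,x,y,z`, frames 1-based, positions in um —
#' the shape exported by common tracking software. Non-contiguous tracks are
#' loaded but flagged ineligible for fitting.
#'
#' @param path CSV file path.
#' @param frame_interval minutes between frames (stored, not read from file).
#' @return `read_tracks` returns a `cell_tracks`; `write_tracks` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path, frame_interval = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  for (nm in c("frame", "x", "y", "z")) {
    if (!nm %in% names(df)) next
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop("non-numeric '", nm, "' at data line ", bad, " of ", path)
    }
  }
  cell_tracks(df, frame_interval = frame_interval)
}

#' @rdname read_tracks
#' @param tracks a `cell_tracks` object.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  df$frame <- as.integer(df$frame)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
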