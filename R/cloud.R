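#' Expression point cloud
#'
#' One fixed sample (a "source") or one time-lapse frame (a "target"):
#' nuclear centroid positions in micrometres plus per-nucleus channel values.
#' The x axis is the posterior-to-anterior (A-P) axis with the posterior tip
#' at the origin.
#'
#' @param positions numeric matrix (n x 3) of x, y, z positions in um.
#' @param channels named list of numeric vectors, one value per point.
#'   May be empty (pure target clouds from tracking data carry no channels).
#' @param ap_normalized logical; `TRUE` once x has been rescaled to `[0, 1]`.
#' @param metadata free-form list (sample id, stage label, provenance).
#' @return An object of class `expression_cloud`.
#' @export
expression_cloud <- function(positions, channels = list(),
                             ap_normalized = FALSE, metadata = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  if (any(!is.finite(positions))) stop("positions must be finite")
  n <- nrow(positions)
  channels <- lapply(channels, as.numeric)
  for (nm in names(channels)) {
    if (length(channels[[nm]]) != n)
      stop("channel '", nm, "' has length ", length(channels[[nm]]),
           " but cloud has ", n, " points")
  }
  structure(list(positions = positions, channels = channels,
                 ap_normalized = isTRUE(ap_normalized), metadata = metadata),
            class = "expression_cloud")
}

#' @export
print.expression_cloud <- function(x, ...) {
  cat("Expression point cloud:", nrow(x$positions), "points,",
      length(x$channels), "channels",
      if (x$ap_normalized) "(A-P normalized)" else "", "\n")
  if (length(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$positions)

check_channel <- function(cloud, channel) {
  if (!channel %in% names(cloud$channels))
    stop("unknown channel '", channel, "'; cloud has: ",
         paste(names(cloud$channels), collapse = ", "))
  invisible(channel)
}

#' Rigid transform helpers
#'
#' A rigid transform is a 4x4 homogeneous matrix whose rotation block is
#' orthonormal with determinant +1 (tolerance 1e-6); translations are in um.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in um.
#' @return 4x4 homogeneous transform matrix.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  tf <- diag(4)
  tf[1:3, 1:3] <- rotation
  tf[1:3, 4] <- translation
  validate_rigid_transform(tf)
}

#' @rdname rigid_transform
#' @param tf a 4x4 matrix to validate.
#' @export
validate_rigid_transform <- function(tf) {
  tf <- as.matrix(tf)
  if (!all(dim(tf) == c(4, 4))) stop("transform must be a 4x4 matrix")
  R <- tf[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rotation block is not a proper rotation (orthonormal, det +1)")
  if (max(abs(tf[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of a homogeneous transform must be (0, 0, 0, 1)")
  tf
}

#' Rotation about the z axis by `theta` radians, as a rigid transform.
#' @param theta angle in radians.
#' @param translation optional translation in um.
#' @export
rotation_z <- function(theta, translation = c(0, 0, 0)) {
  rigid_transform(matrix(c(cos(theta), sin(theta), 0,
                           -sin(theta), cos(theta), 0,
                           0, 0, 1), 3, 3), translation)
}

#' Apply a rigid transform to a point cloud
#'
#' Positions are mapped through the homogeneous transform; channel values and
#' flags are untouched. Used both by the registration pipeline (to move
#' aligned sources into a target frame's coordinates) and as the test harness
#' for known-transform recovery.
#'
#' @param cloud an `expression_cloud`.
#' @param transform 4x4 rigid transform matrix.
#' @return The transformed cloud.
#' @export
apply_rigid_transform <- function(cloud, transform) {
  transform <- validate_rigid_transform(transform)
  p <- cloud$positions %*% t(transform[1:3, 1:3])
  p <- sweep(p, 2, transform[1:3, 4], "+")
  colnames(p) <- c("x", "y", "z")
  out <- cloud
  out$positions <- p
  out
}

#' Read and write expression point clouds
#'
#' CSV dialect: header `x,y,z` followed by one column per channel (canonical
#' order `tbxta,tbx16,tbx6,wnt,fgf` when all five are present); positions in
#' um. An ASCII PLY dialect with the same scalar properties is also
#' supported for interoperability with mesh viewers.
#'
#' @param cloud an `expression_cloud`.
#' @param path file path; `.ply` extension selects the PLY dialect.
#' @return `write_cloud` returns `path` invisibly; `read_cloud` an
#'   `expression_cloud`.
#' @export
write_cloud <- function(cloud, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE))
    return(write_cloud_ply(cloud, path))
  df <- data.frame(cloud$positions)
  for (nm in names(cloud$channels)) df[[nm]] <- cloud$channels[[nm]]
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE))
    return(read_cloud_ply(path))
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("cloud CSV must have columns x,y,z; got: ",
         paste(names(df), collapse = ","))
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]))
      stop("non-numeric values in column '", nm, "' of ", path)
  }
  ch <- setdiff(names(df), need)
  expression_cloud(as.matrix(df[, need]),
                   channels = as.list(df[, ch, drop = FALSE]),
                   metadata = list(source_file = path))
}

write_cloud_ply <- function(cloud, path) {
  ch <- names(cloud$channels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", n_points(cloud)),
    "property double x", "property double y", "property double z",
    paste("property double", ch),
    "end_header"
  ), con)
  m <- cbind(cloud$positions, do.call(cbind, cloud$channels))
  write.table(format(as.data.frame(m), digits = 17, trim = TRUE,
                     scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_cloud_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("not an ASCII PLY file: ", path)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY header not terminated in ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", hdr, value = TRUE))
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nv, byrow = TRUE)
  colnames(m) <- props
  ch <- setdiff(props, c("x", "y", "z"))
  expression_cloud(m[, c("x", "y", "z"), drop = FALSE],
                   channels = as.list(as.data.frame(m[, ch, drop = FALSE])),
                   metadata = list(source_file = path))
}
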