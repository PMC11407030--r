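#' Channel schema for the T-box model family
#'
#' Fixed ordering of the modelled genes and the external signal inputs,
#' shared by every module: three T-box genes (tbxta, tbx16, tbx6) whose
#' mRNA levels are the state variables, and two signalling inputs
#' (Wnt, FGF) that drive the network but are not themselves modelled.
#'
#' @return A list with components `genes`, `signals` and `channels`
#'   (genes then signals).
#' @export
channel_schema <- function() {
  list(
    genes = c("tbxta", "tbx16", "tbx6"),
    signals = c("wnt", "fgf"),
    channels = c("tbxta", "tbx16", "tbx6", "wnt", "fgf")
  )
}

N_GENES <- 3L
N_SIGNALS <- 2L
N_PARAMS <- 24L

#' GRN parameter set
#'
#' The 24 fitted quantities of the connectionist model: the gene-gene
#' interconnectivity matrix W (entry `W[b, a]` is the effect of regulator
#' gene b on target gene a), the signal-gene matrix E (entry `E[s, a]` is
#' the effect of signal s on gene a), per-gene production rates R, decay
#' rates lambda and basal-activity thresholds h. Positive weights are
#' activations, negative weights repressions.
#'
#' @param W 3x3 numeric matrix, regulator rows, target columns.
#' @param E 2x3 numeric matrix, signal rows (wnt, fgf), target columns.
#' @param R numeric length-3, production rates (must be >= 0 to simulate).
#' @param lam numeric length-3, decay rates (must be > 0 to simulate).
#' @param h numeric length-3, basal thresholds.
#' @return An object of class `grn_params`.
#' @export
grn_params <- function(W = matrix(0, 3, 3), E = matrix(0, 2, 3),
                       R = rep(1, 3), lam = rep(1, 3), h = rep(0, 3)) {
  sch <- channel_schema()
  W <- matrix(as.numeric(W), 3, 3, dimnames = list(sch$genes, sch$genes))
  E <- matrix(as.numeric(E), 2, 3, dimnames = list(sch$signals, sch$genes))
  stopifnot(length(R) == 3, length(lam) == 3, length(h) == 3)
  p <- structure(
    list(W = W, E = E, R = as.numeric(R), lam = as.numeric(lam),
         h = as.numeric(h)),
    class = "grn_params"
  )
  validate_grn_params(p)
  p
}

validate_grn_params <- function(p, for_simulation = FALSE) {
  vals <- as.numeric(p)
  if (length(vals) != N_PARAMS)
    stop("grn_params must contain exactly 24 scalars, got ", length(vals))
  if (any(!is.finite(vals))) stop("grn_params contains non-finite values")
  if (for_simulation) {
    if (any(p$lam <= 0)) stop("decay rates lambda must be > 0 for simulation")
    if (any(p$R < 0)) stop("production rates R must be >= 0 for simulation")
  }
  invisible(p)
}

#' Flatten a parameter set to the canonical 24-vector
#'
#' Ordering: the 9 entries of W column-major (all regulators of tbxta, then
#' of tbx16, then of tbx6), the 6 entries of E column-major, then R, lambda
#' and h (each in gene order). This ordering defines the parameter axis of
#' posterior ensembles and the JSON serialization. (`as.numeric` dispatches
#' here too.)
#'
#' @param x a `grn_params` object.
#' @param ... unused.
#' @return Named numeric vector of length 24.
#' @export
as.double.grn_params <- function(x, ...) {
  sch <- channel_schema()
  wn <- as.vector(outer(sch$genes, sch$genes,
                        function(b, a) paste0("W_", b, "_", a)))
  en <- as.vector(outer(sch$signals, sch$genes,
                        function(s, a) paste0("E_", s, "_", a)))
  out <- c(as.vector(x$W), as.vector(x$E), x$R, x$lam, x$h)
  names(out) <- c(wn, en, paste0("R_", sch$genes),
                  paste0("lam_", sch$genes), paste0("h_", sch$genes))
  out
}

#' Names of the 24 parameters in canonical order
#' @return Character vector of length 24.
#' @export
grn_param_names <- function() names(as.double.grn_params(grn_params()))

#' Rebuild a parameter set from its canonical 24-vector
#'
#' Inverse of the canonical flattening ([as.double.grn_params()]).
#'
#' @param v numeric vector of length 24 in canonical order.
#' @return A `grn_params` object.
#' @export
grn_params_from_vector <- function(v) {
  if (length(v) != N_PARAMS)
    stop("parameter vector must have exactly 24 entries, got ", length(v))
  v <- as.numeric(v)
  grn_params(W = matrix(v[1:9], 3, 3), E = matrix(v[10:15], 2, 3),
             R = v[16:18], lam = v[19:21], h = v[22:24])
}

#' Indices of the 15 interaction parameters (9 W + 6 E) in the 24-vector
#' @return Integer vector of length 15.
#' @export
interaction_indices <- function() 1:15

#' @export
print.grn_params <- function(x, ...) {
  cat("GRN parameter set (24 parameters)\n")
  cat("W (gene -> gene, regulator rows):\n")
  print(round(x$W, 4))
  cat("E (signal -> gene):\n")
  print(round(x$E, 4))
  cat("R:  ", paste(round(x$R, 4), collapse = " "), "\n")
  cat("lam:", paste(round(x$lam, 4), collapse = " "), "\n")
  cat("h:  ", paste(round(x$h, 4), collapse = " "), "\n")
  invisible(x)
}

#' Write / read GRN parameters as JSON
#'
#' The JSON carries named blocks `W` (3x3, regulator-major), `E` (2x3),
#' `R`, `lam`, `h`, plus a `schema` block documenting the gene/signal
#' ordering. Round-trips preserve values to full double precision.
#'
#' @param params a `grn_params` object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `grn_params` object.
#' @export
write_params <- function(params, path) {
  validate_grn_params(params)
  sch <- channel_schema()
  obj <- list(
    schema = list(genes = sch$genes, signals = sch$signals,
                  note = "W[b][a]: regulator gene b -> target gene a; E[s][a]: signal s -> gene a"),
    W = unname(apply(params$W, 1, function(r) r, simplify = FALSE)),
    E = unname(apply(params$E, 1, function(r) r, simplify = FALSE)),
    R = params$R, lam = params$lam, h = params$h
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("W", "E", "R", "lam", "h"))
    if (is.null(obj[[f]])) stop("params JSON missing block '", f, "'")
  W <- do.call(rbind, lapply(obj$W, function(r) as.numeric(unlist(r))))
  E <- do.call(rbind, lapply(obj$E, function(r) as.numeric(unlist(r))))
  if (!all(dim(W) == c(3, 3)) || !all(dim(E) == c(2, 3)))
    stop("params JSON has wrong W/E dimensions; 24 scalars required")
  R <- as.numeric(unlist(obj$R)); lam <- as.numeric(unlist(obj$lam))
  h <- as.numeric(unlist(obj$h))
  n <- length(W) + length(E) + length(R) + length(lam) + length(h)
  if (n != N_PARAMS) stop("params JSON holds ", n, " scalars; 24 required")
  grn_params(W = W, E = E, R = R, lam = lam, h = h)
}
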