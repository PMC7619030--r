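#' Fit an affine calibration from digitized control points
#'
#' Least-squares affine map from digitizer pixel coordinates to a calibrated
#' frame, from at least three non-collinear control points. With exactly
#' three non-collinear controls the map interpolates them exactly. Because
#' digitizer exports use image coordinates (pixel y grows downward), a
#' y-flip is absorbed by the fitted linear part whenever the targets are
#' given "north up".
#'
#' @param pixel Two-column matrix/data frame of pixel `(x, y)`.
#' @param target Two-column matrix/data frame of calibrated `(u, v)`.
#' @return An `affine_transform`: list with `linear` (2x2) and `offset`
#'   (length-2), mapping `p` to `linear %*% p + offset`.
#' @export
fit_affine <- function(pixel, target) {
  pixel <- as.matrix(pixel)
  target <- as.matrix(target)
  stopifnot(ncol(pixel) == 2L, ncol(target) == 2L,
            nrow(pixel) == nrow(target))
  if (nrow(pixel) < 3L) {
    stop("affine calibration needs at least 3 control points", call. = FALSE)
  }
  X <- cbind(1, pixel)
  if (qr(X)$rank < 3L) {
    stop("control points are collinear; calibration is degenerate", call. = FALSE)
  }
  coefs <- qr.coef(qr(X), target)   # 3 x 2: intercept row, then x, y rows
  linear <- t(coefs[2:3, , drop = FALSE])
  if (abs(det(linear)) < .Machine$double.eps^0.5) {
    stop("fitted linear part is singular; calibration is degenerate", call. = FALSE)
  }
  structure(list(linear = linear, offset = as.numeric(coefs[1L, ])),
            class = "affine_transform")
}

#' Apply an affine transform to points
#'
#' @param transform An `affine_transform`.
#' @param points Two-column matrix/data frame of `(x, y)` points.
#' @return Matrix of transformed points (columns `u`, `v`).
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine_transform"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  out <- points %*% t(transform$linear)
  out[, 1L] <- out[, 1L] + transform$offset[1L]
  out[, 2L] <- out[, 2L] + transform$offset[2L]
  colnames(out) <- c("u", "v")
  out
}

#' Distance between calibrated map points
#'
#' `mode = "planar"` (default) is the Euclidean distance in the calibrated
#' frame — the defensible metric for a schematic image. `mode =
#' "lonlat-compat"` feeds `(y, x)` into the great-circle routine as
#' `(lat, lon)`, replicating analyses that run geographic distance code
#' directly on map X/Y; its output is only meaningful up to a monotone
#' scale, so use it for standardized or correlational quantities.
#'
#' @param p,q Length-2 points `(x, y)` or two-column matrices of points.
#' @param mode `"planar"` or `"lonlat-compat"`.
#' @param radius_km Sphere radius for the compat mode.
#' @return Non-negative distance(s).
#' @export
map_distance <- function(p, q, mode = c("planar", "lonlat-compat"),
                         radius_km = 6371.0088) {
  mode <- match.arg(mode)
  p <- if (is.null(dim(p))) matrix(p, ncol = 2L) else as.matrix(p)
  q <- if (is.null(dim(q))) matrix(q, ncol = 2L) else as.matrix(q)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L, nrow(p) == nrow(q))
  if (mode == "planar") {
    d <- sqrt((p[, 1L] - q[, 1L])^2 + (p[, 2L] - q[, 2L])^2)
  } else {
    d <- haversine_km(p[, 2L], p[, 1L], q[, 2L], q[, 1L], radius_km = radius_km)
  }
  as.numeric(d)
}

#' Pearson correlation with input validation
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Read digitized points (WebPlotDigitizer-style CSV)
#'
#' @param path CSV with header `label,x,y`.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
read_digitized_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  miss <- setdiff(c("label", "x", "y"), names(df))
  if (length(miss)) {
    stop("digitized CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[, c("label", "x", "y")]
}
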