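#' Well geometry
#'
#' Describes the imaged field: a pixel grid with physical calibration and a
#' boolean mask of valid (in-well) pixels. Physical coordinates are in
#' micrometres with the origin at the top-left corner of the pixel grid; the
#' centre of pixel (row i, column j) lies at
#' \eqn{x = (j - 1/2)\,s, \; y = (i - 1/2)\,s} for pixel size \eqn{s}.
#'
#' @param height_px,width_px Integer pixel counts.
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param mask Optional logical matrix (`height_px` x `width_px`) of valid
#'   pixels. Defaults to the full rectangle.
#' @param shape Convenience mask shapes: `"rect"` (all pixels valid) or
#'   `"disk"` (largest inscribed disk).
#' @return A `well_geometry` object.
#' @export
well_geometry <- function(height_px, width_px, pixel_size_um,
                          mask = NULL, shape = c("rect", "disk")) {
  shape <- match.arg(shape)
  stopifnot(height_px >= 1, width_px >= 1, pixel_size_um > 0)
  if (is.null(mask)) {
    if (shape == "rect") {
      mask <- matrix(TRUE, height_px, width_px)
    } else {
      cy <- height_px / 2; cx <- width_px / 2
      r <- min(cy, cx)
      rr <- row(matrix(0, height_px, width_px)) - 0.5
      cc <- col(matrix(0, height_px, width_px)) - 0.5
      mask <- (rr - cy)^2 + (cc - cx)^2 <= r^2
    }
  }
  stopifnot(is.logical(mask), nrow(mask) == height_px, ncol(mask) == width_px)
  if (!any(mask)) stop("well mask is empty")
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         pixel_size_um = pixel_size_um, mask = mask),
    class = "well_geometry"
  )
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("<well_geometry> %d x %d px @ %.3g um/px (%.2f x %.2f mm), %d valid px\n",
              x$height_px, x$width_px, x$pixel_size_um,
              x$width_px * x$pixel_size_um / 1000,
              x$height_px * x$pixel_size_um / 1000, sum(x$mask)))
  invisible(x)
}

# pixel-centre coordinates (um) for all pixels, as h x w matrices
pixel_coords_um <- function(geometry) {
  h <- geometry$height_px; w <- geometry$width_px; s <- geometry$pixel_size_um
  list(x = matrix(rep((seq_len(w) - 0.5) * s, each = h), h, w),
       y = matrix(rep((seq_len(h) - 0.5) * s, w), h, w))
}

# convert physical (x, y) um to nearest pixel (row, col); clamped to grid
um_to_pixel <- function(geometry, x_um, y_um) {
  s <- geometry$pixel_size_um
  col <- pmin(pmax(ceiling(x_um / s), 1L), geometry$width_px)
  row <- pmin(pmax(ceiling(y_um / s), 1L), geometry$height_px)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Distance to the well boundary
#'
#' Euclidean distance (um) from each valid pixel to the nearest pixel outside
#' the mask (or to the image border), used to define "edge-associated"
#' sources.
#'
#' @param geometry A [well_geometry()].
#' @return Matrix (um); `NA` outside the mask.
#' @export
boundary_distance_um <- function(geometry) {
  m <- geometry$mask
  # pad so that the image border counts as boundary
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1
  d <- EBImage::distmap(pad)
  d <- d[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  d <- d * geometry$pixel_size_um
  d[!m] <- NA_real_
  d
}

# TRUE if mask is (approximately) convex: every row and column run is
# contiguous and the convex hull of pixel centres has nearly the mask area.
is_convex_mask <- function(geometry, tol = 0.03) {
  m <- geometry$mask
  contig <- function(v) {
    idx <- which(v)
    length(idx) == 0L || all(diff(idx) == 1L)
  }
  if (!all(apply(m, 1, contig)) || !all(apply(m, 2, contig))) return(FALSE)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 4) return(TRUE)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  xs <- idx[hull, 2]; ys <- idx[hull, 1]
  n <- length(xs)
  area <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  # hull of centres underestimates the rasterized area by ~ perimeter / 2
  area + 2 * (sum(abs(diff(range(idx[, 1])))) + sum(abs(diff(range(idx[, 2]))))) >=
    (1 - tol) * sum(m)
}
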