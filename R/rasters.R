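#' @useDynLib plotsieve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Class codebook used throughout: 0 = NoData, 1 = LC (the target crop),
# 2 = forest, 3 = other plants, 4 = bare land, 5 = construction land.
CLASS_CODES <- 1:5
CLASS_NAMES <- c("LC", "forest", "other plants", "bare land", "construction land")

#' Default projected CRS (WGS 84 / UTM zone 48N)
#' @keywords internal
DEFAULT_CRS <- "EPSG:32648"

new_grid_geometry <- function(width, height, pixel_size, origin = c(0, 0),
                              crs = DEFAULT_CRS) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 # world coordinates of the top-left corner of pixel (1,1)
                 origin = as.numeric(origin), crs = crs),
            class = "grid_geometry")
}

geom_equal <- function(a, b, tol = 1e-9) {
  a$width == b$width && a$height == b$height &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    all(abs(a$origin - b$origin) < tol) && identical(a$crs, b$crs)
}

#' World coordinates of pixel centers
#'
#' Row 1 is the top of the raster; y decreases with increasing row.
#' @keywords internal
xy_from_rowcol <- function(geom, row, col) {
  cbind(x = geom$origin[1] + (col - 0.5) * geom$pixel_size,
        y = geom$origin[2] - (row - 0.5) * geom$pixel_size)
}

rowcol_from_xy <- function(geom, x, y) {
  col <- floor((x - geom$origin[1]) / geom$pixel_size) + 1L
  row <- floor((geom$origin[2] - y) / geom$pixel_size) + 1L
  cbind(row = as.integer(row), col = as.integer(col))
}

in_extent <- function(geom, row, col) {
  row >= 1L & row <= geom$height & col >= 1L & col <= geom$width
}

#' RGB orthomosaic container
#'
#' A three-band 8-bit raster with a validity mask and grid geometry. Values
#' are stored as an `height x width x 3` integer array in `[0, 255]`.
#'
#' @param values numeric array `h x w x 3` of digital numbers in `[0, 255]`.
#' @param geom a grid geometry created by the scene generator or raster reader.
#' @param mask logical matrix, `TRUE` where pixels are valid.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(values, geom, mask = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 3)
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  stopifnot(all(dim(mask) == dim(values)[1:2]))
  v <- values[is.finite(values)]
  if (length(v) && (min(v) < 0 || max(v) > 255))
    stop("rgb_image values must lie in [0, 255]")
  structure(list(values = values, mask = mask, geom = geom),
            class = c("rgb_image", "ps_raster"))
}

#' Digital elevation model container
#'
#' @param values numeric matrix of elevations in metres.
#' @inheritParams rgb_image
#' @return an object of class `elevation_model`.
#' @export
elevation_model <- function(values, geom, mask = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  structure(list(values = values, mask = mask, geom = geom),
            class = c("elevation_model", "ps_raster"))
}

#' Thematic label raster
#'
#' Integer raster over the five-class codebook; 0 encodes NoData.
#'
#' @param values integer matrix with codes in `{0, 1, ..., 5}`.
#' @inheritParams rgb_image
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(values, geom) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(as.vector(values)), c(0L, CLASS_CODES))
  if (length(bad)) stop("label codes outside 0..5: ", paste(bad, collapse = ", "))
  structure(list(values = values, mask = values != 0L, geom = geom),
            class = c("label_raster", "ps_raster"))
}

#' @export
print.ps_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px @ %.3g m/px, origin (%.1f, %.1f), %s\n",
              class(x)[1], x$geom$height, x$geom$width, x$geom$pixel_size,
              x$geom$origin[1], x$geom$origin[2], x$geom$crs))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.ps_raster <- function(x) c(x$geom$height, x$geom$width)

band <- function(rgb, i)
  matrix(rgb$values[, , i], dim(rgb$values)[1], dim(rgb$values)[2])
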