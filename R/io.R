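# Raster and sample-point I/O.
#
# Rasters are stored as TIFF with two sidecar files providing the
# georeferencing that a full GeoTIFF would carry inline:
#   <file>.tfw       ESRI world file (pixel size, rotation, center of pixel 1,1)
#   <file>.aux.json  CRS, raster kind, NoData handling, band names and the
#                    affine offset/scale used to pack float layers into the
#                    TIFF's [0,1] sample range.
# 8-bit bands (RGB, labels) round-trip exactly; float layers round-trip to the
# 32-bit quantisation of their packed range.

world_file_path <- function(path) sub("\\.tif{1,2}$", ".tfw", path, ignore.case = TRUE)
sidecar_path <- function(path) paste0(path, ".aux.json")

write_world_file <- function(geom, path) {
  px <- geom$pixel_size
  lines <- c(px, 0, 0, -px, geom$origin[1] + px / 2, geom$origin[2] - px / 2)
  writeLines(format(lines, digits = 15, scientific = FALSE, trim = TRUE),
             world_file_path(path))
}

read_world_file <- function(path, width, height, crs) {
  v <- as.numeric(readLines(world_file_path(path)))
  new_grid_geometry(width, height, v[1], c(v[5] - v[1] / 2, v[6] + v[1] / 2), crs)
}

#' Save a raster to TIFF with georeferencing sidecars
#'
#' @param x an [rgb_image()], [elevation_model()] or [label_raster()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_raster <- function(x, path) {
  stopifnot(inherits(x, "ps_raster"))
  kind <- class(x)[1]
  aux <- list(kind = kind, crs = x$geom$crs, nodata = 0)
  if (kind == "rgb_image") {
    tiff::writeTIFF(x$values / 255, path, bits.per.sample = 8L,
                    compression = "none")
    aux$bands <- c("R", "G", "B")
  } else if (kind == "label_raster") {
    tiff::writeTIFF(x$values / 255, path, bits.per.sample = 8L,
                    compression = "none")
    aux$codes <- stats::setNames(as.list(CLASS_NAMES), CLASS_CODES)
  } else {
    rng <- range(x$values[x$mask], finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    scale <- max(rng[2] - rng[1], 1e-12)
    v <- (x$values - rng[1]) / scale
    v[!x$mask] <- 0
    tiff::writeTIFF(v, path, bits.per.sample = 32L, compression = "none")
    aux$offset <- rng[1]; aux$scale <- scale
    aux$mask_packed <- !all(x$mask)
    if (aux$mask_packed) aux$mask_rle <- pack_mask(x$mask)
  }
  jsonlite::write_json(aux, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  write_world_file(x$geom, path)
  invisible(path)
}

pack_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = r$lengths, values = r$values, dim = dim(mask))
}

unpack_mask <- function(p) {
  matrix(inverse.rle(list(lengths = p$lengths, values = as.logical(p$values))),
         p$dim[1], p$dim[2])
}

#' Load a raster written by [save_raster()]
#'
#' The band count dispatches the returned type: 3 bands give an
#' [rgb_image()]; a single band is a [label_raster()] or [elevation_model()]
#' according to the sidecar.
#'
#' @param path a `.tif` path with its `.tfw`/`.aux.json` sidecars.
#' @return a `ps_raster` object.
#' @export
load_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster: ", path)
  aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  dims <- dim(img)
  geom <- read_world_file(path, dims[2], dims[1], aux$crs)
  if (length(dims) == 3 && dims[3] == 3) {
    rgb_image(round(img * 255), geom)
  } else if (identical(aux$kind, "label_raster")) {
    label_raster(matrix(as.integer(round(img * 255)), dims[1], dims[2]), geom)
  } else {
    v <- img * aux$scale + aux$offset
    mask <- if (isTRUE(aux$mask_packed)) unpack_mask(aux$mask_rle) else NULL
    if (!is.null(mask)) v[!mask] <- NA_real_
    elevation_model(v, geom, mask)
  }
}

#' Save sample points to CSV
#'
#' Columns: `id`, `x`, `y`, `class_code`, `split`, `fold`, `radius_m`.
#' @param samples a sample set data frame.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
save_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Load sample points from CSV
#'
#' Class codes are validated against the five-class codebook. If the `fold`
#' column is absent, stratified folds are assigned to training points with the
#' given seed (and a message is emitted).
#'
#' @param path a `.csv` path.
#' @param folds,seed fold count and seed used only when folds must be assigned.
#' @return a `sample_set` data frame.
#' @export
load_samples <- function(path, folds = 5L, seed = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "class_code", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample file lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$class_code), CLASS_CODES)
  if (length(bad)) stop("unknown class codes: ", paste(sort(bad), collapse = ", "))
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  if (is.null(df$radius_m)) df$radius_m <- 0.2
  if (is.null(df$fold) || all(is.na(df$fold))) {
    message("no fold column; assigning ", folds, " stratified folds (seed ", seed, ")")
    set.seed(seed)
    df$fold <- NA_integer_
    for (code in unique(df$class_code)) {
      it <- which(df$split == "train" & df$class_code == code)
      df$fold[it] <- sample(rep_len(seq_len(folds), length(it)))
    }
  }
  df <- df[, c("id", "x", "y", "class_code", "split", "fold", "radius_m")]
  class(df) <- c("sample_set", "data.frame")
  df
}
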