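#' Construct a feature stack
#'
#' A named, aligned collection of float feature layers sharing one grid
#' geometry. Per-layer NoData is encoded as `NA`; the stack's combined
#' validity mask is the conjunction of all per-layer masks and the source
#' mask.
#'
#' @param layers named list of numeric matrices (all the same shape).
#' @param category named character vector, one of `"CI"`, `"GLCM"`, `"CS"`,
#'   `"DEM"`, `"BAND"`, aligned with `layers`.
#' @param geom grid geometry shared by all layers.
#' @param mask logical matrix of source validity.
#' @return an object of class `feature_stack`.
#' @export
feature_stack <- function(layers, category, geom, mask = NULL) {
  stopifnot(length(layers) == length(category), !is.null(names(layers)))
  if (anyDuplicated(names(layers)))
    stop("duplicate layer name: ",
         paste(unique(names(layers)[duplicated(names(layers))]), collapse = ", "))
  dims <- c(geom$height, geom$width)
  for (nm in names(layers))
    if (!all(dim(layers[[nm]]) == dims))
      stop("layer ", nm, " does not match the stack geometry")
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  for (l in layers) mask <- mask & !is.na(l)
  structure(list(layers = layers,
                 category = stats::setNames(as.character(category), names(layers)),
                 geom = geom, mask = mask),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d layers, %d x %d px, %d valid px\n",
              length(x$layers), x$geom$height, x$geom$width, sum(x$mask)))
  tab <- table(x$category)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of layers and their names
#' @param x a [feature_stack()].
#' @export
stack_names <- function(x) names(x$layers)

#' Extract one layer matrix
#' @param x a [feature_stack()].
#' @param name layer name.
#' @export
get_layer <- function(x, name) {
  if (!name %in% names(x$layers)) stop("no such layer: ", name)
  x$layers[[name]]
}

#' Subset a stack by layer names (order preserved as given)
#' @param x a [feature_stack()].
#' @param names layer names to keep.
#' @export
subset_stack <- function(x, names) {
  missing <- setdiff(names, stack_names(x))
  if (length(missing)) stop("missing layer(s): ", paste(missing, collapse = ", "))
  feature_stack(x$layers[names], x$category[names], x$geom, x$mask)
}

#' Assemble feature stacks (and optionally a DEM) into one
#'
#' @param ... feature stacks sharing one grid geometry.
#' @param dem optional [elevation_model()]; appended as a layer named `"DEM"`.
#' @return a combined [feature_stack()] whose validity mask is the
#'   conjunction of all inputs' masks.
#' @export
assemble_stack <- function(..., dem = NULL) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  geom <- parts[[1]]$geom
  layers <- list(); category <- character(); mask <- parts[[1]]$mask
  for (p in parts) {
    if (!geom_equal(p$geom, geom))
      stop("geometry mismatch at layer(s): ", paste(stack_names(p), collapse = ", "))
    dup <- intersect(names(p$layers), names(layers))
    if (length(dup)) stop("duplicate layer name: ", paste(dup, collapse = ", "))
    layers <- c(layers, p$layers)
    category <- c(category, p$category)
    mask <- mask & p$mask
  }
  if (!is.null(dem)) {
    if (!geom_equal(dem$geom, geom)) stop("geometry mismatch at layer(s): DEM")
    if ("DEM" %in% names(layers)) stop("duplicate layer name: DEM")
    layers$DEM <- dem$values
    category <- c(category, DEM = "DEM")
    mask <- mask & dem$mask
  }
  feature_stack(layers, category, geom, mask)
}

#' Raw R, G, B bands as a feature stack (the RGB baseline)
#' @param rgb an [rgb_image()].
#' @export
band_stack <- function(rgb) {
  feature_stack(list(R = band(rgb, 1), G = band(rgb, 2), B = band(rgb, 3)),
                c(R = "BAND", G = "BAND", B = "BAND"), rgb$geom, rgb$mask)
}

#' Write a feature stack as a multi-page float TIFF with a layer manifest
#'
#' Each layer becomes one 32-bit page; layer names, categories and the
#' per-layer packing range go to the JSON sidecar, and a `*_manifest.csv`
#' records name and category.
#'
#' @param x a [feature_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(x, path) {
  pages <- list(); packing <- list()
  for (nm in stack_names(x)) {
    v <- x$layers[[nm]]
    rng <- range(v[x$mask], finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    scale <- max(rng[2] - rng[1], 1e-12)
    p <- (v - rng[1]) / scale
    p[is.na(p) | !x$mask] <- 0
    pages[[nm]] <- p
    packing[[nm]] <- list(offset = rng[1], scale = scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  aux <- list(kind = "feature_stack", crs = x$geom$crs,
              bands = stack_names(x), category = as.list(x$category),
              packing = packing, mask_rle = pack_mask(x$mask))
  jsonlite::write_json(aux, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  write_world_file(x$geom, path)
  utils::write.csv(data.frame(name = stack_names(x),
                              category = unname(x$category)),
                   sub("\\.tif{1,2}$", "_manifest.csv", path), row.names = FALSE)
  invisible(path)
}

#' Load a feature stack written by [save_stack()]
#' @param path a `.tif` path.
#' @export
load_stack <- function(path) {
  aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- dim(pages[[1]])
  geom <- read_world_file(path, dims[2], dims[1], aux$crs)
  mask <- unpack_mask(list(lengths = unlist(aux$mask_rle$lengths),
                           values = unlist(aux$mask_rle$values),
                           dim = unlist(aux$mask_rle$dim)))
  bands <- unlist(aux$bands)
  layers <- list()
  for (i in seq_along(bands)) {
    nm <- bands[i]
    pk <- aux$packing[[nm]]
    v <- pages[[i]] * pk$scale + pk$offset
    v[!mask] <- NA_real_
    layers[[nm]] <- v
  }
  feature_stack(layers, stats::setNames(unlist(aux$category), bands), geom, mask)
}
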