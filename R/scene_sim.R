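#' Default class signatures: the "metameric stress" preset
#'
#' LC plots and forest share nearly identical RGB means (both are dense green
#' canopies from nadir) but differ strongly in texture roughness (manicured LC
#' beds are smooth, forest canopy is rough) and in elevation (forest canopy sits
#' ~10 m above ground, LC ~1 m). RGB-only classifiers therefore confuse the two,
#' while texture and elevation layers separate them — the situation the whole
#' workflow exists to resolve.
#'
#' @return named list of per-class signature records.
#' @export
default_class_signatures <- function() {
  sig <- function(mean_rgb, rgb_spread, texture_scale, elevation_offset_m,
                  elevation_roughness_m) {
    list(mean_rgb = mean_rgb, rgb_spread = rgb_spread,
         texture_scale = texture_scale,
         elevation_offset_m = elevation_offset_m,
         elevation_roughness_m = elevation_roughness_m)
  }
  list(
    `1` = sig(c(70, 120, 60),   c(10, 10, 10), 4.0, 1.0, 0.3),  # LC
    `2` = sig(c(66, 114, 58),   c(16, 16, 16), 1.0, 10.0, 3.0), # forest
    `3` = sig(c(88, 126, 74),   c(12, 12, 12), 1.8, 0.6, 0.5),  # other plants
    `4` = sig(c(150, 132, 110), c(9, 9, 9),    2.5, 0.0, 0.2),  # bare land
    `5` = sig(c(178, 178, 184), c(7, 7, 7),    5.0, 3.0, 1.5)   # construction
  )
}

#' Synthetic scene configuration
#'
#' Describes a landscape of rectangular crop plots over a mosaic background,
#' with per-class spectral means, texture correlation lengths and elevation
#' offsets. Exactly five classes (codes 1-5) must be configured; code 0 is
#' reserved for NoData.
#'
#' @param width,height scene size in pixels.
#' @param pixel_size ground sampling distance in metres per pixel.
#' @param class_signatures per-class records as in [default_class_signatures()].
#' @param plot_geometry list with `n_plots`, `plot_size_range_m` (min/max side
#'   length of the rectangular plots, metres) and `fragmentation` (fraction of
#'   the scene kept as background mosaic).
#' @param base_elevation_m valley-floor elevation added to all classes.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width = 256, height = 256, pixel_size = 0.10,
                         class_signatures = default_class_signatures(),
                         plot_geometry = list(n_plots = 8,
                                              plot_size_range_m = NULL,
                                              fragmentation = 0.6),
                         base_elevation_m = 600, seed = 1L) {
  stopifnot(width > 0, height > 0, pixel_size > 0)
  if (length(class_signatures) != 5 ||
      !identical(sort(as.integer(names(class_signatures))), 1:5))
    stop("exactly five classes (codes 1-5) must be configured")
  for (s in class_signatures) {
    if (any(s$mean_rgb < 0 | s$mean_rgb > 255))
      stop("mean_rgb components must lie in [0, 255]")
  }
  if (is.null(plot_geometry$plot_size_range_m)) {
    ext <- min(width, height) * pixel_size
    plot_geometry$plot_size_range_m <- c(0.12, 0.3) * ext
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, class_signatures = class_signatures,
                 plot_geometry = plot_geometry,
                 base_elevation_m = base_elevation_m, seed = as.integer(seed)),
            class = "scene_config")
}

# Separable Gaussian smoothing with reflected edges; sigma in pixels.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) { # filter the columns of x
    n <- nrow(x)
    if (n == 1L) return(x)
    rr <- min(r, n - 1L)
    kk <- if (rr < r) { k2 <- exp(-((-rr:rr)^2) / (2 * sigma^2)); k2 / sum(k2) } else k
    ridx <- c((rr + 1):2, 1:n, (n - 1):(n - rr)) # reflect-101 padding
    xp <- x[ridx, , drop = FALSE]
    f <- stats::filter(xp, kk, sides = 2)
    f[(rr + 1):(rr + n), , drop = FALSE]
  }
  t(smooth1(t(smooth1(m))))
}

# Place n axis-aligned, non-overlapping rectangles (in pixels); error if they
# cannot be fitted after a bounded number of attempts.
place_plots <- function(width, height, n_plots, size_range_px, gap_px = 2L) {
  if (n_plots == 0) return(matrix(numeric(0), 0, 4))
  if (min(size_range_px) > min(width, height))
    stop("impossible geometry: plots larger than the scene")
  rects <- matrix(0L, 0, 4, dimnames = list(NULL, c("r1", "r2", "c1", "c2")))
  attempts <- 0L
  while (nrow(rects) < n_plots) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_plots)
      stop("impossible geometry: could not place ", n_plots,
           " non-overlapping plots of the requested size")
    h <- as.integer(round(stats::runif(1, size_range_px[1], size_range_px[2])))
    w <- as.integer(round(stats::runif(1, size_range_px[1], size_range_px[2])))
    h <- min(h, height); w <- min(w, width)
    r1 <- sample.int(height - h + 1L, 1L); c1 <- sample.int(width - w + 1L, 1L)
    cand <- c(r1, r1 + h - 1L, c1, c1 + w - 1L)
    ok <- TRUE
    if (nrow(rects)) {
      overlap <- rects[, 1] <= cand[2] + gap_px & rects[, 2] >= cand[1] - gap_px &
        rects[, 3] <= cand[4] + gap_px & rects[, 4] >= cand[3] - gap_px
      ok <- !any(overlap)
    }
    if (ok) rects <- rbind(rects, cand)
  }
  rects
}

#' Generate a synthetic orthomosaic, DEM and ground-truth labels
#'
#' Rectangular LC plots are placed without overlap; the remaining background is
#' a Voronoi mosaic of the other four classes, reproducing the scattered and
#' fragmented plot structure of smallholder cultivation. Per-class pixels are
#' drawn as `mean + spread * z` where `z` is white noise smoothed with a
#' Gaussian kernel of width `texture_scale` and re-standardised within the
#' class, so class sample means and spreads match the configuration exactly up
#' to 8-bit rounding. Elevation is `base + offset + roughness * z`.
#'
#' @param config a [scene_config()].
#' @return list with elements `rgb` ([rgb_image()]), `dem`
#'   ([elevation_model()]) and `labels` ([label_raster()]).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width
  geom <- new_grid_geometry(w, h, config$pixel_size)

  pg <- config$plot_geometry
  size_px <- pg$plot_size_range_m / config$pixel_size
  labels <- matrix(0L, h, w)
  rects <- place_plots(w, h, pg$n_plots, size_px)
  for (i in seq_len(nrow(rects)))
    labels[rects[i, 1]:rects[i, 2], rects[i, 3]:rects[i, 4]] <- 1L

  # Background: Voronoi tessellation of classes 2-5 over the remaining pixels.
  bg_classes <- 2:5
  n_seeds <- max(length(bg_classes), as.integer(round(12 * (1 - pg$fragmentation))) + 8L)
  sr <- stats::runif(n_seeds, 1, h); sc <- stats::runif(n_seeds, 1, w)
  scls <- rep(bg_classes, length.out = n_seeds)[sample.int(n_seeds)]
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- matrix(Inf, h, w); bg <- matrix(bg_classes[1], h, w)
  for (k in seq_len(n_seeds)) {
    d2 <- (rows - sr[k])^2 + (cols - sc[k])^2
    take <- d2 < best
    bg[take] <- scls[k]; best[take] <- d2[take]
  }
  labels[labels == 0L] <- bg[labels == 0L]

  rgbv <- array(0, dim = c(h, w, 3))
  dem <- matrix(config$base_elevation_m, h, w)
  for (code in CLASS_CODES) {
    s <- config$class_signatures[[as.character(code)]]
    msk <- labels == code
    n <- sum(msk)
    if (n == 0L) next
    for (b in 1:3) {
      z <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), s$texture_scale)
      zc <- z[msk]
      if (n > 1L && stats::sd(zc) > 0) zc <- (zc - mean(zc)) / stats::sd(zc)
      rgbv[, , b][msk] <- s$mean_rgb[b] + s$rgb_spread[b] * zc
    }
    z <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), max(s$texture_scale, 1))
    zc <- z[msk]
    if (n > 1L && stats::sd(zc) > 0) zc <- (zc - mean(zc)) / stats::sd(zc)
    dem[msk] <- config$base_elevation_m + s$elevation_offset_m +
      s$elevation_roughness_m * zc
  }
  rgbv <- round(pmin(pmax(rgbv, 0), 255))

  list(rgb = rgb_image(rgbv, geom),
       dem = elevation_model(dem, geom),
       labels = label_raster(labels, geom))
}

#' Draw labelled sample points with a minimum-spacing rule
#'
#' Emulates stratified random point sampling with a spatial separation
#' criterion: points sit at pixel centers of their class, and any two points
#' (across all classes) are farther apart than `min_spacing_m`. Training points
#' are assigned to 5 stratified cross-validation folds.
#'
#' @param labels a [label_raster()].
#' @param counts data frame or list with per-class `train` and `validation`
#'   counts; either length-5 vectors (classes 1-5) or single values recycled.
#' @param min_spacing_m minimum pairwise point distance in metres (default 3).
#' @param radius_m nominal point radius, metadata only (default 0.2).
#' @param folds number of cross-validation folds for training points.
#' @param seed integer seed.
#' @return data frame of class `sample_set` with columns `id`, `x`, `y`,
#'   `class_code`, `split`, `fold`, `radius_m`.
#' @export
generate_samples <- function(labels, counts, min_spacing_m = 3, radius_m = 0.2,
                             folds = 5L, seed = 1L) {
  stopifnot(inherits(labels, "label_raster"))
  set.seed(seed)
  geom <- labels$geom
  tr <- rep_len(as.integer(counts$train), 5L)
  va <- rep_len(as.integer(counts$validation), 5L)
  total <- tr + va
  diag_m <- sqrt((geom$width^2 + geom$height^2)) * geom$pixel_size
  if (sum(total) >= 2 && min_spacing_m > diag_m)
    stop("infeasible spacing: min_spacing_m (", min_spacing_m,
         " m) exceeds the scene diagonal (", round(diag_m, 2), " m)")

  cell <- max(min_spacing_m, 1e-9)
  occ <- list() # spatial hash: cell key -> matrix of accepted xy
  key <- function(cx, cy) paste(cx, cy, sep = ",")
  too_close <- function(x, y) {
    cx <- floor(x / cell); cy <- floor(y / cell)
    for (dx in -1:1) for (dy in -1:1) {
      pts <- occ[[key(cx + dx, cy + dy)]]
      if (!is.null(pts) &&
          any((pts[, 1] - x)^2 + (pts[, 2] - y)^2 <= min_spacing_m^2))
        return(TRUE)
    }
    FALSE
  }
  push <- function(x, y) {
    k <- key(floor(x / cell), floor(y / cell))
    occ[[k]] <<- rbind(occ[[k]], c(x, y))
  }

  out <- vector("list", 5L)
  for (code in CLASS_CODES) {
    need <- total[code]
    if (need == 0L) { out[[code]] <- NULL; next }
    idx <- which(labels$values == code)
    if (length(idx) < need)
      stop("infeasible counts for class ", code, " (", CLASS_NAMES[code],
           "): ", need, " points requested, ", length(idx), " pixels available")
    idx <- idx[sample.int(length(idx))]
    rc <- cbind(row = (idx - 1L) %% geom$height + 1L,
                col = (idx - 1L) %/% geom$height + 1L)
    xy <- xy_from_rowcol(geom, rc[, 1], rc[, 2])
    got <- matrix(numeric(0), 0, 2)
    for (i in seq_along(idx)) {
      if (nrow(got) == need) break
      if (!too_close(xy[i, 1], xy[i, 2])) {
        push(xy[i, 1], xy[i, 2])
        got <- rbind(got, xy[i, ])
      }
    }
    if (nrow(got) < need)
      stop("infeasible counts/spacing for class ", code, " (",
           CLASS_NAMES[code], "): placed ", nrow(got), " of ", need,
           " points at ", min_spacing_m, " m spacing")
    split <- sample(rep(c("train", "validation"), c(tr[code], va[code])))
    fold <- rep(NA_integer_, need)
    it <- which(split == "train")
    fold[it] <- sample(rep_len(seq_len(folds), length(it)))
    out[[code]] <- data.frame(x = got[, 1], y = got[, 2], class_code = code,
                              split = split, fold = fold)
  }
  res <- do.call(rbind, out)
  res <- data.frame(id = seq_len(nrow(res)), res, radius_m = radius_m)
  class(res) <- c("sample_set", "data.frame")
  res
}

#' Write a synthetic scene to disk
#'
#' Rasters go to TIFF files with world-file georeferencing and JSON sidecars;
#' sample points to CSV. Reading the files back reproduces the grids exactly
#' (8-bit bands and labels) or to 32-bit float precision (DEM).
#'
#' @param scene list as returned by [generate_scene()].
#' @param samples a sample set from [generate_samples()], or `NULL`.
#' @param directory output directory, created if missing.
#' @return named character vector of file paths.
#' @export
write_scene <- function(scene, samples = NULL, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rgb = file.path(directory, "ortho.tif"),
             dem = file.path(directory, "dem.tif"),
             labels = file.path(directory, "labels.tif"))
  save_raster(scene$rgb, paths[["rgb"]])
  save_raster(scene$dem, paths[["dem"]])
  save_raster(scene$labels, paths[["labels"]])
  if (!is.null(samples)) {
    paths <- c(paths, samples = file.path(directory, "samples.csv"))
    save_samples(samples, paths[["samples"]])
  }
  paths
}
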