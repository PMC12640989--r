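#' Multiresolution segmentation parameters
#'
#' @param scale stopping threshold parameter; merges proceed while the
#'   heterogeneity increase stays below `scale^2`. Scale values are not
#'   transferable across segmentation implementations; 300 is the default
#'   label, not a calibrated equivalence to any other software.
#' @param shape weight of shape vs color heterogeneity, in `[0, 1]`.
#' @param compactness weight of compactness vs smoothness within the shape
#'   term, in `[0, 1]`.
#' @param layer_weights per-layer positive weights (default all 1).
#' @export
segmentation_params <- function(scale = 300, shape = 0.3, compactness = 0.5,
                                layer_weights = NULL) {
  stopifnot(scale > 0, shape >= 0, shape <= 1,
            compactness >= 0, compactness <= 1)
  structure(list(scale = scale, shape = shape, compactness = compactness,
                 layer_weights = layer_weights),
            class = "segmentation_params")
}

#' Segment an image by bottom-up region merging
#'
#' Single-pixel regions are merged pairwise, most-similar mutually-best-
#' fitting neighbours first, while the fusion cost
#' `(1 - shape) * dh_color + shape * dh_shape` stays below `scale^2`.
#' `dh_color` is the weighted increase in pixel-count-scaled standard
#' deviation over the layers; `dh_shape` mixes perimeter-based compactness
#' and smoothness. Deterministic for a fixed input.
#'
#' @param x an [rgb_image()] (segmented on its three bands, the default
#'   practice) or a [feature_stack()].
#' @param params a [segmentation_params()].
#' @return object of class `segment_map`: `object_ids` (integer matrix,
#'   labels >= 1, NoData 0), `objects` (per-object statistics table), `geom`.
#' @export
segment <- function(x, params = segmentation_params()) {
  if (inherits(x, "rgb_image")) x <- band_stack(x)
  stopifnot(inherits(x, "feature_stack"))
  geom <- x$geom
  if (sum(x$mask) == 0) stop("empty raster: no valid pixels to segment")
  L <- length(x$layers)
  X <- vapply(x$layers, as.vector, numeric(geom$height * geom$width))
  X[is.na(X)] <- 0
  wts <- params$layer_weights
  if (is.null(wts)) wts <- rep(1, L)
  stopifnot(length(wts) == L, all(wts > 0))
  ids <- segment_cpp(X, as.vector(x$mask), geom$height, geom$width,
                     as.numeric(wts), params$scale, params$shape,
                     params$compactness)
  ids <- matrix(ids, geom$height, geom$width)
  segment_map(ids, x)
}

# Build the object table by direct aggregation over the id raster.
segment_map <- function(ids, stack) {
  valid <- ids > 0L
  f <- factor(ids[valid])
  n <- as.integer(table(f))
  obj <- data.frame(id = as.integer(levels(f)), n_pixels = n)
  h <- nrow(ids); w <- ncol(ids)
  pad <- cbind(0L, rbind(0L, ids, 0L), 0L)
  edges <- (pad[2:(h + 1), 2:(w + 1)] != pad[1:h, 2:(w + 1)]) +
    (pad[2:(h + 1), 2:(w + 1)] != pad[3:(h + 2), 2:(w + 1)]) +
    (pad[2:(h + 1), 2:(w + 1)] != pad[2:(h + 1), 1:w]) +
    (pad[2:(h + 1), 2:(w + 1)] != pad[2:(h + 1), 3:(w + 2)])
  obj$perimeter <- as.vector(rowsum(as.numeric(edges[valid]), f))
  rr <- row(ids)[valid]; cc <- col(ids)[valid]
  obj$bbox_h <- as.vector(tapply(rr, f, max) - tapply(rr, f, min) + 1L)
  obj$bbox_w <- as.vector(tapply(cc, f, max) - tapply(cc, f, min) + 1L)
  for (nm in stack_names(stack)) {
    v <- stack$layers[[nm]][valid]
    s <- as.vector(rowsum(v, f))
    s2 <- as.vector(rowsum(v^2, f))
    obj[[paste0("mean.", nm)]] <- s / n
    obj[[paste0("sd.", nm)]] <- sqrt(pmax(s2 / n - (s / n)^2, 0))
  }
  structure(list(object_ids = ids, objects = obj, geom = stack$geom,
                 layer_names = stack_names(stack)),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d objects over %d x %d px (min size %d, median %.0f)\n",
              nrow(x$objects), x$geom$height, x$geom$width,
              min(x$objects$n_pixels), stats::median(x$objects$n_pixels)))
  invisible(x)
}

#' Aggregate a feature stack over segmentation objects
#'
#' Per-object means of arbitrary stack layers (which may differ from the
#' layers used for segmentation), for use as object classification features.
#'
#' @param segments a `segment_map`.
#' @param stack a [feature_stack()] on the same grid.
#' @param layers layer names to aggregate (default all).
#' @return data frame `id` + one `mean.<layer>` column per layer.
#' @export
object_features <- function(segments, stack, layers = stack_names(stack)) {
  stopifnot(geom_equal(segments$geom, stack$geom))
  valid <- segments$object_ids > 0L
  f <- factor(segments$object_ids[valid])
  n <- as.integer(table(f))
  out <- data.frame(id = as.integer(levels(f)))
  for (nm in layers) {
    v <- stack$layers[[nm]][valid]
    out[[paste0("mean.", nm)]] <- as.vector(rowsum(v, f, na.rm = TRUE)) / n
  }
  out
}

#' Transfer training-point labels onto segmentation objects
#'
#' An object containing at least one training point takes that label;
#' objects hit by points of conflicting classes are dropped with a warning.
#'
#' @param segments a `segment_map`.
#' @param samples a sample set (training split is used).
#' @return data frame `id`, `class_code` of labelled objects; attributes
#'   `conflicts` (dropped object count) and `untouched` (objects with no
#'   training point).
#' @export
assign_training_objects <- function(segments, samples) {
  tr <- samples[samples$split == "train", , drop = FALSE]
  geom <- segments$geom
  rc <- rowcol_from_xy(geom, tr$x, tr$y)
  inside <- in_extent(geom, rc[, 1], rc[, 2])
  if (!all(inside))
    stop("training point(s) outside extent: ", paste(tr$id[!inside], collapse = ", "))
  oid <- segments$object_ids[cbind(rc[, 1], rc[, 2])]
  keep <- oid > 0L
  agg <- tapply(tr$class_code[keep], oid[keep], function(cc) {
    u <- unique(cc)
    if (length(u) == 1L) u else NA_integer_
  })
  labelled <- data.frame(id = as.integer(names(agg)),
                         class_code = as.integer(agg))
  conflicts <- sum(is.na(labelled$class_code))
  if (conflicts > 0)
    warning(conflicts, " object(s) hit by conflicting training classes were dropped")
  labelled <- labelled[!is.na(labelled$class_code), , drop = FALSE]
  if (nrow(labelled) == 0) stop("no labelled objects")
  attr(labelled, "conflicts") <- conflicts
  attr(labelled, "untouched") <- nrow(segments$objects) - conflicts - nrow(labelled)
  labelled
}

object_feature_matrix <- function(features, layers) {
  cols <- paste0("mean.", layers)
  missing <- setdiff(cols, names(features))
  if (length(missing)) stop("missing object feature(s): ",
                            paste(missing, collapse = ", "))
  as.matrix(features[, cols, drop = FALSE])
}

#' K-nearest-neighbour classification of objects
#'
#' Each object is assigned the majority class of its `k` nearest labelled
#' objects in standardised Euclidean feature space (standardisation from the
#' labelled objects). Ties break by the nearest single neighbour, then the
#' lowest class code. `k = 1` reproduces the plain nearest-neighbour object
#' classifier.
#'
#' @param segments a `segment_map`.
#' @param features object feature table from [object_features()].
#' @param labelled labelled objects from [assign_training_objects()].
#' @param layers layer names used as features.
#' @param k neighbourhood size (default 1).
#' @return a `classification_result` rasterised via the object ids.
#' @export
classify_objects_knn <- function(segments, features, labelled, layers, k = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(labelled)) stop("k exceeds the number of labelled objects")
  X <- object_feature_matrix(features, layers)
  tr_idx <- match(labelled$id, features$id)
  Xtr <- X[tr_idx, , drop = FALSE]
  center <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  Xtrs <- Xs[tr_idx, , drop = FALSE]
  # squared Euclidean distances all objects x labelled objects
  d2 <- outer(rowSums(Xs^2), rep(1, nrow(Xtrs))) +
    outer(rep(1, nrow(Xs)), rowSums(Xtrs^2)) - 2 * Xs %*% t(Xtrs)
  pred <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[i, ], labelled$class_code) # stable: nearer, then lower code
    nn <- ord[seq_len(k)]
    votes <- table(labelled$class_code[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) pred[i] <- top
    else {
      nearest_in_tie <- nn[labelled$class_code[nn] %in% top][1]
      pred[i] <- labelled$class_code[nearest_in_tie]
    }
  }
  rasterize_objects(segments, features$id, pred, classifier = "KNN")
}

#' SVM classification of objects
#'
#' As the pixel SVM ([fit_predict_svm()]) but over object mean-feature
#' vectors.
#'
#' @inheritParams classify_objects_knn
#' @param cost,gamma SVM hyperparameters (defaults 1 and `1/d`).
#' @return a `classification_result`.
#' @export
classify_objects_svm <- function(segments, features, labelled, layers,
                                 cost = 1, gamma = NULL) {
  if (length(unique(labelled$class_code)) < 2)
    stop("SVM training requires at least 2 labelled classes")
  X <- object_feature_matrix(features, layers)
  tr_idx <- match(labelled$id, features$id)
  Xtr <- X[tr_idx, , drop = FALSE]
  center <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl == 0] <- 1
  Xtrs <- sweep(sweep(Xtr, 2, center), 2, scl, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xtrs)
  fit <- e1071::svm(Xtrs, factor(labelled$class_code), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  pred <- as.integer(as.character(stats::predict(fit, Xs)))
  rasterize_objects(segments, features$id, pred, classifier = "SVM")
}

rasterize_objects <- function(segments, ids, pred, classifier) {
  lut <- integer(max(segments$object_ids))
  lut[ids] <- pred
  v <- segments$object_ids
  v[v > 0L] <- lut[v[v > 0L]]
  classification_result(label_raster(v, segments$geom), classifier = classifier)
}

#' Dissolve object boundaries into a thematic raster
#'
#' Drops the object partition, keeping classes only: adjacent objects of one
#' class render as a single connected region.
#'
#' @param result a `classification_result` from an object classifier.
#' @return a [label_raster()].
#' @export
dissolve_boundaries <- function(result) {
  if (inherits(result, "classification_result")) return(result$labels)
  result
}

#' Connected components of a label raster (4-connectivity, per class)
#'
#' @param labels a [label_raster()].
#' @return list with `ids` (integer matrix of component ids, 0 = NoData) and
#'   `sizes` (pixel count per component).
#' @export
connected_components <- function(labels) {
  if (inherits(labels, "classification_result")) labels <- labels$labels
  ids <- cc_label_cpp(as.vector(labels$values), labels$geom$height,
                      labels$geom$width)
  ids <- matrix(ids, labels$geom$height, labels$geom$width)
  list(ids = ids, sizes = tabulate(ids[ids > 0L]))
}

#' Local-variance diagnostic for choosing a segmentation scale
#'
#' A heuristic aid (not an estimator): mean within-object standard deviation
#' of the first layer across a ladder of scales, to eyeball where additional
#' merging stops adding heterogeneity.
#'
#' @param x input image or stack as for [segment()].
#' @param scales numeric vector of scale values to profile.
#' @param params base [segmentation_params()]; `scale` is overridden.
#' @return data frame `scale`, `n_objects`, `mean_sd`.
#' @export
scale_profile <- function(x, scales, params = segmentation_params()) {
  do.call(rbind, lapply(scales, function(s) {
    params$scale <- s
    sm <- segment(x, params)
    sdcol <- grep("^sd\\.", names(sm$objects), value = TRUE)[1]
    data.frame(scale = s, n_objects = nrow(sm$objects),
               mean_sd = stats::weighted.mean(sm$objects[[sdcol]],
                                              sm$objects$n_pixels))
  }))
}
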