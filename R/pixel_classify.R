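#' Fit a Gaussian maximum-likelihood classifier
#'
#' Class-conditional multivariate Gaussians with sample means and covariances
#' estimated from training rows; equal priors by default. Ill-conditioned
#' covariances are ridge-regularised by adding `eps * trace/d` to the
#' diagonal until the Cholesky factorisation succeeds.
#'
#' @param table a sample table (training rows are used).
#' @param layers character vector of feature columns.
#' @param priors optional named numeric priors (must sum to 1); default equal.
#' @return an object of class `ml_model`.
#' @export
fit_ml <- function(table, layers, priors = NULL) {
  tr <- table[table$split == "train", , drop = FALSE]
  classes <- sort(unique(tr$class_code))
  d <- length(layers)
  models <- list()
  for (k in classes) {
    X <- as.matrix(tr[tr$class_code == k, layers, drop = FALSE])
    if (nrow(X) < 2) stop("class ", k, " has fewer than 2 training rows")
    mu <- colMeans(X)
    S <- stats::cov(X)
    eps <- 0
    repeat {
      Sr <- S + diag(eps * max(sum(diag(S)), 1e-12) / d, d)
      ch <- tryCatch(chol(Sr), error = function(e) NULL)
      if (!is.null(ch) && all(diag(ch) > 1e-10)) break
      eps <- if (eps == 0) 1e-8 else eps * 10
      if (eps > 1) stop("covariance for class ", k, " cannot be regularised")
    }
    models[[as.character(k)]] <- list(mean = mu, cov = Sr, chol = ch,
                                      logdet = 2 * sum(log(diag(ch))))
  }
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  stopifnot(abs(sum(priors) - 1) < 1e-9)
  structure(list(classes = classes, models = models,
                 priors = stats::setNames(priors, classes),
                 layer_names = layers),
            class = "ml_model")
}

# Discriminant scores (n x classes): log prior - 1/2 log|S| - 1/2 Mahalanobis^2
ml_scores <- function(model, X) {
  out <- matrix(NA_real_, nrow(X), length(model$classes))
  for (i in seq_along(model$classes)) {
    m <- model$models[[as.character(model$classes[i])]]
    Z <- forwardsolve(t(m$chol), t(X) - m$mean)
    out[, i] <- log(model$priors[i]) - 0.5 * m$logdet - 0.5 * colSums(Z^2)
  }
  out
}

argmax_lowest_code <- function(scores, classes) {
  # ties broken by the lowest class code (classes are sorted ascending)
  classes[max.col(scores, ties.method = "first")]
}

#' Predict a label raster with a maximum-likelihood model
#'
#' Each unmasked pixel is assigned the class maximising the Gaussian
#' discriminant; ties break toward the lowest class code. Masked pixels get
#' NoData (0).
#'
#' @param model an `ml_model` from [fit_ml()].
#' @param stack a [feature_stack()] containing the model's layers.
#' @return a `classification_result` (see [classification_result()]).
#' @export
predict_ml <- function(model, stack) {
  missing <- setdiff(model$layer_names, stack_names(stack))
  if (length(missing)) stop("missing layer(s): ", paste(missing, collapse = ", "))
  geom <- stack$geom
  idx <- which(stack$mask)
  X <- vapply(model$layer_names, function(nm) stack$layers[[nm]][idx],
              numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1)
  lab <- matrix(0L, geom$height, geom$width)
  lab[idx] <- argmax_lowest_code(ml_scores(model, X), model$classes)
  classification_result(label_raster(lab, geom), classifier = "ML")
}

#' Predict classes for table rows with a maximum-likelihood model
#' @param model an `ml_model`.
#' @param table a sample table with the model's layers as columns.
#' @return integer class codes.
#' @export
predict_ml_table <- function(model, table) {
  X <- as.matrix(table[, model$layer_names, drop = FALSE])
  argmax_lowest_code(ml_scores(model, X), model$classes)
}

#' Train an RBF support vector machine and classify a stack
#'
#' Features are standardised by training-split mean and scale (the Gaussian
#' ML classifier is affine-equivariant, the SVM is not). Defaults are pinned
#' for reproducibility: radial basis kernel, cost 1, kernel width `1/d` on
#' the standardised features, one-vs-one multiclass voting.
#'
#' @param table a sample table (training rows are used).
#' @param layers feature column names.
#' @param stack optional [feature_stack()] to classify; if `NULL` only the
#'   model is returned.
#' @param cost,gamma SVM hyperparameters (defaults 1 and `1/d`).
#' @return if `stack` is given, a `classification_result`; otherwise an
#'   object of class `svm_model` usable with [predict_svm_table()].
#' @export
fit_predict_svm <- function(table, layers, stack = NULL, cost = 1,
                            gamma = NULL) {
  tr <- table[table$split == "train", , drop = FALSE]
  if (length(unique(tr$class_code)) < 2)
    stop("SVM training requires at least 2 classes")
  X <- as.matrix(tr[, layers, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  fit <- e1071::svm(Xs, factor(tr$class_code),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  model <- structure(list(fit = fit, layer_names = layers, center = center,
                          scale = scale), class = "svm_model")
  if (is.null(stack)) return(model)
  geom <- stack$geom
  idx <- which(stack$mask)
  Xp <- vapply(layers, function(nm) stack$layers[[nm]][idx],
               numeric(length(idx)))
  if (length(idx) == 1L) Xp <- matrix(Xp, nrow = 1)
  Xp <- sweep(sweep(Xp, 2, center), 2, scale, "/")
  lab <- matrix(0L, geom$height, geom$width)
  lab[idx] <- as.integer(as.character(stats::predict(fit, Xp)))
  classification_result(label_raster(lab, geom), classifier = "SVM")
}

#' Predict classes for table rows with a fitted SVM
#' @param model an `svm_model` from [fit_predict_svm()].
#' @param table a sample table.
#' @return integer class codes.
#' @export
predict_svm_table <- function(model, table) {
  X <- as.matrix(table[, model$layer_names, drop = FALSE])
  X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.integer(as.character(stats::predict(model$fit, X)))
}

#' Classification result container
#'
#' @param labels a [label_raster()].
#' @param combination combination id (e.g. `"FC15"`).
#' @param classifier classifier id (`"ML"`, `"SVM"`, `"KNN"`).
#' @param post_processed whether post-filtering was applied.
#' @export
classification_result <- function(labels, combination = NA_character_,
                                  classifier = NA_character_,
                                  post_processed = FALSE) {
  structure(list(labels = labels, combination = combination,
                 classifier = classifier, post_processed = post_processed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s / %s%s\n", x$combination,
              x$classifier, if (x$post_processed) " (post-processed)" else ""))
  print(x$labels)
  invisible(x)
}

# Box sum over a k x k neighbourhood via summed-area tables (edges
# truncated: the neighbourhood is clipped at the raster border).
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- apply(rbind(0, m), 2, cumsum)
  v <- cs[pmin(1:h + r, h) + 1L, , drop = FALSE] -
    cs[pmax(1:h - r - 1L, 0L) + 1L, , drop = FALSE]
  cs2 <- t(apply(cbind(0, v), 1, cumsum))
  cs2[, pmin(1:w + r, w) + 1L, drop = FALSE] -
    cs2[, pmax(1:w - r - 1L, 0L) + 1L, drop = FALSE]
}

#' Majority filter for label rasters
#'
#' Each pixel is replaced by the modal label of its `kernel x kernel`
#' neighbourhood (clipped at the raster border); NoData pixels are excluded
#' from the votes and remain NoData. On modal ties the current label is
#' retained when it participates in the tie, otherwise the lowest class code
#' among the modes wins. Removes the salt-and-pepper speckle typical of
#' per-pixel classification.
#'
#' @param labels a [label_raster()] or `classification_result`.
#' @param kernel odd neighbourhood side (default 3).
#' @param iterations number of passes (default 1).
#' @return object of the same type as `labels`, filtered.
#' @export
majority_filter <- function(labels, kernel = 3L, iterations = 1L) {
  if (inherits(labels, "classification_result")) {
    out <- labels
    out$labels <- majority_filter(labels$labels, kernel, iterations)
    out$post_processed <- TRUE
    return(out)
  }
  stopifnot(inherits(labels, "label_raster"), kernel %% 2 == 1)
  r <- kernel %/% 2
  v <- labels$values
  for (it in seq_len(iterations)) {
    counts <- lapply(CLASS_CODES, function(k) box_sum((v == k) * 1, r))
    best <- counts[[1]]; mode <- matrix(1L, nrow(v), ncol(v))
    for (k in 2:5) {
      take <- counts[[k]] > best # strict: earlier (lower) codes win ties
      mode[take] <- k; best[take] <- counts[[k]][take]
    }
    cur_count <- matrix(0, nrow(v), ncol(v))
    for (k in CLASS_CODES) {
      sel <- v == k
      cur_count[sel] <- counts[[k]][sel]
    }
    keep <- cur_count == best # current label ties the mode: retain it
    new_v <- mode
    new_v[keep] <- v[keep]
    new_v[v == 0L] <- 0L
    v <- new_v
  }
  label_raster(v, labels$geom)
}

#' Per-class pixel counts, areas and proportions
#'
#' @param labels a [label_raster()] or `classification_result`.
#' @param pixel_size metres per pixel; defaults to the raster's own.
#' @return data frame with `class_code`, `class_name`, `pixels`, `area_m2`,
#'   `proportion` (over unmasked pixels; sums to 1).
#' @export
area_statistics <- function(labels, pixel_size = NULL) {
  if (inherits(labels, "classification_result")) labels <- labels$labels
  if (is.null(pixel_size)) pixel_size <- labels$geom$pixel_size
  counts <- vapply(CLASS_CODES, function(k) sum(labels$values == k), integer(1))
  total <- sum(counts)
  data.frame(class_code = CLASS_CODES, class_name = CLASS_NAMES,
             pixels = counts, area_m2 = counts * pixel_size^2,
             proportion = if (total > 0) counts / total else rep(NA_real_, 5))
}
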