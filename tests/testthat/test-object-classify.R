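test_that("uniform images segment into exactly one object", {
  rgb <- make_rgb(array(120, dim = c(20, 20, 3)))
  sm <- segment(rgb, segmentation_params(scale = 50))
  expect_equal(nrow(sm$objects), 1)
  expect_true(all(sm$object_ids == 1L))
})

test_that("a two-region fixture with a large DN gap yields its two true objects", {
  v <- cbind(matrix(10, 40, 20), matrix(210, 40, 20))
  rgb <- rgb_from_bands(v, v, v)
  sm <- segment(rgb, segmentation_params(scale = 300))
  expect_equal(nrow(sm$objects), 2)
  expect_equal(length(unique(as.vector(sm$object_ids[, 1:20]))), 1)
  expect_equal(length(unique(as.vector(sm$object_ids[, 21:40]))), 1)
  expect_false(sm$object_ids[1, 1] == sm$object_ids[1, 40])
})

test_that("object ids always partition the unmasked grid", {
  sc <- small_scene()
  sm <- segment(sc$rgb, segmentation_params(scale = 25))
  expect_true(all(sm$object_ids >= 1L))
  expect_equal(sort(unique(as.vector(sm$object_ids))), seq_len(nrow(sm$objects)))
  # 4-connectivity of every object
  cc <- cc_bruteforce(sm$object_ids[1:40, 1:40])
  sub_ids <- sm$object_ids[1:40, 1:40]
  for (oid in unique(as.vector(sub_ids))) {
    comp <- unique(cc[sub_ids == oid])
    # objects clipped by the crop may split; full-grid objects may not
    full <- !any(sub_ids == oid & (row(sub_ids) %in% c(1, 40) |
                                     col(sub_ids) %in% c(1, 40)))
    if (full) expect_length(comp, 1)
  }
})

test_that("object statistics equal direct per-id aggregation", {
  sc <- small_scene()
  sm <- segment(sc$rgb, segmentation_params(scale = 40))
  R <- sc$rgb$values[, , 1]
  for (oid in sample(sm$objects$id, 10)) {
    msk <- sm$object_ids == oid
    expect_equal(sm$objects$n_pixels[sm$objects$id == oid], sum(msk))
    expect_equal(sm$objects$mean.R[sm$objects$id == oid], mean(R[msk]))
    expect_equal(sm$objects$sd.R[sm$objects$id == oid],
                 sqrt(mean(R[msk]^2) - mean(R[msk])^2), tolerance = 1e-8)
  }
})

test_that("object count decreases (weakly) as scale increases", {
  sc <- small_scene()
  counts <- sapply(c(15, 25, 40, 100), function(s)
    nrow(segment(sc$rgb, segmentation_params(scale = s))$objects))
  expect_true(all(diff(counts) <= 0))
})

test_that("shape = 0 reduces the fusion cost to pure color heterogeneity", {
  set.seed(50)
  v <- matrix(sample(c(10, 200), 64, TRUE), 8, 8)
  rgb <- rgb_from_bands(v, v, v)
  a <- segment(rgb, segmentation_params(scale = 20, shape = 0))
  # pure color criterion: only identical-DN neighbours can merge at tiny scale
  for (oid in a$objects$id) {
    msk <- a$object_ids == oid
    expect_equal(length(unique(v[msk])), 1)
  }
})

test_that("training points label objects and conflicts are dropped with counts", {
  sc <- small_scene()
  sm <- segment(sc$rgb, segmentation_params(scale = 25))
  samp <- small_samples()
  lb <- suppressWarnings(assign_training_objects(sm, samp))
  expect_true(all(lb$class_code %in% 1:5))
  expect_equal(attr(lb, "conflicts") + attr(lb, "untouched") + nrow(lb),
               nrow(sm$objects))
  # bijective case: one point per object
  v <- cbind(matrix(10, 10, 10), matrix(210, 10, 10))
  rgb2 <- rgb_from_bands(v, v, v)
  sm2 <- segment(rgb2, segmentation_params(scale = 100))
  pts <- data.frame(id = 1:2, x = c(5, 15), y = c(-5, -5),
                    class_code = c(1L, 4L), split = "train", fold = 1L,
                    radius_m = 0.2)
  lb2 <- assign_training_objects(sm2, pts)
  expect_equal(nrow(lb2), 2)
  expect_equal(attr(lb2, "conflicts"), 0)
  # conflicting points in one object: the object drops, the count reports it
  pts3 <- data.frame(id = 1:3, x = c(5, 6, 15), y = c(-5, -6, -5),
                     class_code = c(1L, 2L, 4L), split = "train", fold = 1L,
                     radius_m = 0.2)
  expect_warning(lb3 <- assign_training_objects(sm2, pts3), "conflicting")
  expect_equal(nrow(lb3), 1)
  expect_equal(lb3$class_code, 4L)
  expect_equal(attr(lb3, "conflicts"), 1)
  # all objects conflicted -> explicit error
  pts$class_code <- c(1L, 2L); pts$x <- c(5, 6); pts$y <- c(-5, -6)
  expect_error(suppressWarnings(assign_training_objects(sm2, pts)),
               "no labelled objects")
})

test_that("KNN object assignment equals exhaustive nearest-neighbour search", {
  set.seed(60)
  n <- 200
  feats <- data.frame(id = 1:n, mean.a = rnorm(n), mean.b = rnorm(n))
  lab_idx <- sample(n, 40)
  labelled <- data.frame(id = feats$id[lab_idx],
                         class_code = sample(1:4, 40, TRUE))
  ids <- matrix(rep(1:n, each = 2), 2, n) # each object: one 2px column
  sm <- list(object_ids = ids,
             geom = plotsieve:::new_grid_geometry(n, 2, 1))
  class(sm) <- "segment_map"
  for (k in c(1L, 3L)) {
    res <- classify_objects_knn(sm, feats, labelled, c("a", "b"), k = k)
    pred_obj <- res$labels$values[1, ] # one object per column
    # brute force with the same standardisation and tie rules
    Xtr <- as.matrix(feats[lab_idx, c("mean.a", "mean.b")])
    ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd)
    S <- function(M) sweep(sweep(M, 2, ctr), 2, scl, "/")
    Xs <- S(as.matrix(feats[, c("mean.a", "mean.b")])); Xt <- S(Xtr)
    for (i in seq_len(n)) {
      d <- sqrt(colSums((t(Xt) - Xs[i, ])^2))
      ord <- order(d, labelled$class_code)
      nn <- ord[1:k]
      votes <- table(labelled$class_code[nn])
      top <- as.integer(names(votes)[votes == max(votes)])
      want <- if (length(top) == 1) top else
        labelled$class_code[nn[labelled$class_code[nn] %in% top][1]]
      expect_equal(pred_obj[i], want)
    }
  }
  expect_error(classify_objects_knn(sm, feats, labelled, c("a", "b"), k = 41),
               "exceeds")
  # zero-distance query returns that object's class at k = 1
  r1 <- classify_objects_knn(sm, feats, labelled, c("a", "b"), k = 1)
  expect_equal(r1$labels$values[1, labelled$id],
               labelled$class_code)
})

test_that("object SVM relabels separable classes and rejects degenerate input", {
  v <- cbind(matrix(10, 12, 6), matrix(120, 12, 6), matrix(235, 12, 6))
  rgb <- rgb_from_bands(v, v, v)
  sm <- segment(rgb, segmentation_params(scale = 60))
  expect_equal(nrow(sm$objects), 3)
  feats <- object_features(sm, band_stack(rgb))
  labelled <- data.frame(id = feats$id, class_code = c(1L, 3L, 5L))
  res <- classify_objects_svm(sm, feats, labelled, c("R", "G", "B"))
  got <- sapply(labelled$id, function(oid)
    unique(res$labels$values[sm$object_ids == oid]))
  expect_equal(got, labelled$class_code)
  expect_error(classify_objects_svm(sm, feats, labelled[1, ], c("R", "G", "B")),
               "at least 2")
})

test_that("dissolving boundaries merges same-class neighbours, not others", {
  v <- cbind(matrix(10, 10, 10), matrix(210, 10, 10))
  rgb <- rgb_from_bands(v, v, v)
  sm <- segment(rgb, segmentation_params(scale = 100))
  res <- plotsieve:::rasterize_objects(sm, sm$objects$id, c(2L, 2L), "KNN")
  out <- dissolve_boundaries(res)
  cc <- connected_components(out)
  expect_equal(max(cc$ids), 1) # two same-class objects render as one region
  res2 <- plotsieve:::rasterize_objects(sm, sm$objects$id, c(2L, 3L), "KNN")
  cc2 <- connected_components(dissolve_boundaries(res2))
  expect_equal(max(cc2$ids), 2)
  # component count after dissolve never exceeds the object count
  sc <- small_scene()
  sm2 <- segment(sc$rgb, segmentation_params(scale = 25))
  feats <- object_features(sm2, band_stack(sc$rgb))
  lb <- suppressWarnings(assign_training_objects(sm2, small_samples()))
  res3 <- classify_objects_knn(sm2, feats, lb, c("R", "G", "B"))
  cc3 <- connected_components(dissolve_boundaries(res3))
  expect_lte(max(cc3$ids), nrow(sm2$objects))
})

test_that("connected-component labelling agrees with a flood-fill oracle", {
  set.seed(70)
  v <- matrix(sample(0:3, 15 * 12, TRUE), 15, 12)
  got <- connected_components(make_labels(v))$ids
  want <- cc_bruteforce(v)
  # same partition up to renaming
  expect_equal(max(got), max(want))
  key <- paste(got, want)
  expect_equal(length(unique(key[v != 0])), max(want))
})

test_that("scale profile reports a decreasing object count", {
  sc <- small_scene()
  prof <- scale_profile(sc$rgb, c(20, 60))
  expect_equal(nrow(prof), 2)
  expect_gte(prof$n_objects[1], prof$n_objects[2])
  expect_true(all(prof$mean_sd >= 0))
})
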