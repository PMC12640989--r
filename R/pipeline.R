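#' Pipeline configuration
#'
#' Validated, nested configuration for the end-to-end workflow. Unknown keys
#' are errors, not warnings. Every random stage receives a seed derived from
#' the master seed by a stable stage-name hash, so stages are individually
#' reproducible.
#'
#' @param scene list of [scene_config()] arguments (without `seed`).
#' @param samples list with `train` and `validation` per-class counts and
#'   `min_spacing_m`.
#' @param features list with `window` and `levels`.
#' @param segmentation list of [segmentation_params()] arguments.
#' @param classifiers list with `svm_cost` and `knn_k`.
#' @param evaluation list with `folds` and `baseline`.
#' @param seed master seed.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = list(), samples = list(),
                            features = list(), segmentation = list(),
                            classifiers = list(), evaluation = list(),
                            seed = 1L, out_dir = NULL) {
  defaults <- list(
    scene = list(width = 256, height = 256, pixel_size = 1.0,
                 n_plots = 8, fragmentation = 0.6, base_elevation_m = 600),
    samples = list(train = 60, validation = 120, min_spacing_m = 3),
    features = list(window = 3, levels = 64),
    # scale 25 fits the synthetic scene family (chosen from scale_profile();
    # segmentation scales are not transferable across implementations)
    segmentation = list(scale = 25, shape = 0.3, compactness = 0.5),
    classifiers = list(svm_cost = 1, knn_k = 1),
    evaluation = list(folds = 5, baseline = "RGB")
  )
  merge1 <- function(section, given) {
    unknown <- setdiff(names(given), names(defaults[[section]]))
    if (length(unknown))
      stop("unknown key(s) in ", section, ": ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults[[section]], given)
  }
  cfg <- list(scene = merge1("scene", scene),
              samples = merge1("samples", samples),
              features = merge1("features", features),
              segmentation = merge1("segmentation", segmentation),
              classifiers = merge1("classifiers", classifiers),
              evaluation = merge1("evaluation", evaluation),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with sections matching [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("scene", "samples", "features", "segmentation", "classifiers",
             "evaluation", "seed", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

# Per-stage seed derived from the master seed by a stable name hash.
stage_seed <- function(seed, stage) {
  hs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + hs) %% 2147483647)
}

#' Build the full analysis stack (color indices, textures, color components,
#' raw bands, DEM) from a scene
#'
#' @param rgb an [rgb_image()].
#' @param dem an [elevation_model()].
#' @param window,levels GLCM window and quantization levels.
#' @return a [feature_stack()] with 44 layers (41 features + R, G, B).
#' @export
build_analysis_stack <- function(rgb, dem, window = 3L, levels = 64L) {
  assemble_stack(compute_color_indices(rgb),
                 compute_texture_layers(rgb, window = window, Ng = levels),
                 compute_color_components(rgb),
                 band_stack(rgb),
                 dem = dem)
}

# Object-based cross-validation: relabel training objects per fold, classify
# all objects, evaluate against validation points through the rasterised map.
cv_object <- function(segments, features, samples, layers, classifier = "knn",
                      combination = NA_character_, k = 1L, cost = 1) {
  fold_ids <- sort(unique(samples$fold[samples$split == "train" &
                                         !is.na(samples$fold)]))
  lapply(fold_ids, function(f) {
    sub <- samples[samples$split == "validation" |
                     (samples$split == "train" & samples$fold != f), ,
                   drop = FALSE]
    labelled <- assign_training_objects(segments, sub)
    res <- if (tolower(classifier) == "knn")
      classify_objects_knn(segments, features, labelled, layers, k = k)
    else
      classify_objects_svm(segments, features, labelled, layers, cost = cost)
    res$combination <- combination
    cm <- confusion_matrix(res, samples)
    compute_metrics(cm, combination = combination,
                    classifier = paste0(toupper(classifier), "-obj"), fold = f)
  })
}

#' Run the full workflow on a synthetic scene
#'
#' Simulate, extract features, screen, enumerate combinations, cross-validate
#' the four classifier families (pixel ML and SVM, object KNN and SVM) on
#' every combination, and rank the combinations per family. Stage outputs are
#' written as CSV when `out_dir` is set, along with a run manifest of file
#' digests.
#'
#' @param config a [pipeline_config()].
#' @param combinations optional character vector restricting the combination
#'   ids evaluated (default: all 15 plus the RGB baseline).
#' @return list with `scene`, `samples`, `stack`, `screening`, `combos`,
#'   `reports` (data frame of per-fold metrics), `rankings` (per classifier
#'   family) and `manifest`.
#' @export
run_pipeline <- function(config, combinations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scene
  scene <- generate_scene(scene_config(
    width = sc$width, height = sc$height, pixel_size = sc$pixel_size,
    plot_geometry = list(n_plots = sc$n_plots, plot_size_range_m = NULL,
                         fragmentation = sc$fragmentation),
    base_elevation_m = sc$base_elevation_m,
    seed = stage_seed(config$seed, "scene")))
  samples <- generate_samples(
    scene$labels,
    counts = list(train = config$samples$train,
                  validation = config$samples$validation),
    min_spacing_m = config$samples$min_spacing_m,
    folds = config$evaluation$folds,
    seed = stage_seed(config$seed, "samples"))

  stack <- build_analysis_stack(scene$rgb, scene$dem,
                                window = config$features$window,
                                levels = config$features$levels)
  table <- extract_sample_values(stack, samples)

  feat_cols <- stack_names(stack)[stack$category %in% c("CI", "GLCM", "CS")]
  correlation <- pearson_matrix(table, feat_cols)
  dw <- dw_table(table, columns = feat_cols)
  selected <- select_representatives(dw, stack$category)
  combos <- build_combinations(selected)
  if (!is.null(combinations))
    combos <- Filter(function(cb) cb$id %in% combinations, combos)

  segments <- segment(scene$rgb,
                      segmentation_params(config$segmentation$scale,
                                          config$segmentation$shape,
                                          config$segmentation$compactness))
  ofeat <- object_features(segments, stack)

  reports <- list()
  for (cb in combos) {
    reports[[paste(cb$id, "ML")]] <-
      crossvalidate(table, cb$layer_names, "ml", combination = cb$id)
    reports[[paste(cb$id, "SVM")]] <-
      crossvalidate(table, cb$layer_names, "svm", combination = cb$id)
    reports[[paste(cb$id, "KNN-obj")]] <-
      cv_object(segments, ofeat, samples, cb$layer_names, "knn",
                combination = cb$id, k = config$classifiers$knn_k)
    reports[[paste(cb$id, "SVM-obj")]] <-
      cv_object(segments, ofeat, samples, cb$layer_names, "svm",
                combination = cb$id, cost = config$classifiers$svm_cost)
  }
  flat <- do.call(rbind, lapply(unlist(reports, recursive = FALSE), function(r)
    data.frame(combination = r$combination, classifier = r$classifier,
               fold = r$fold, overall_accuracy = r$overall_accuracy,
               kappa = r$kappa, pa_lc = r$producer_accuracy[1],
               ua_lc = r$user_accuracy[1], f1_lc = r$f1[1],
               composite = r$composite)))
  rownames(flat) <- NULL

  rankings <- NULL
  if (length(unique(flat$combination)) >= 2)
    rankings <- lapply(split(flat, flat$classifier), rank_combinations,
                       baseline = config$evaluation$baseline)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(f) file.path(config$out_dir, f)
    utils::write.csv(as.data.frame(table, check.names = FALSE),
                     outfile("sample_table.csv"), row.names = FALSE)
    utils::write.csv(round(correlation, 6), outfile("correlation.csv"))
    utils::write.csv(format_dw(dw), outfile("dw_table.csv"))
    utils::write.csv(attr(selected, "report"), outfile("selection_report.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(combos, function(cb)
      data.frame(id = cb$id,
                 categories = paste(cb$categories, collapse = "+"),
                 layers = paste(cb$layer_names, collapse = "+")))),
      outfile("combinations.csv"), row.names = FALSE)
    utils::write.csv(flat, outfile("metrics.csv"), row.names = FALSE)
    for (nm in names(rankings))
      utils::write.csv(rankings[[nm]]$table,
                       outfile(paste0("ranking_", gsub("[^A-Za-z0-9]", "_", nm),
                                      ".csv")), row.names = FALSE)
    files <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest <- list(seed = config$seed,
                     digests = tools::md5sum(files))
    jsonlite::write_json(list(seed = manifest$seed,
                              digests = as.list(manifest$digests)),
                         outfile("manifest.json"), auto_unbox = TRUE)
  }

  list(scene = scene, samples = samples, stack = stack,
       screening = list(correlation = correlation, dw = dw,
                        selected = selected),
       combos = combos, segments = segments, reports = flat,
       rankings = rankings, manifest = manifest)
}

# Dw table formatted with 2 decimals and percent signs, features as rows.
format_dw <- function(dw) {
  out <- as.data.frame(matrix(sprintf("%.2f%%", dw$dw), nrow(dw$dw),
                              dimnames = dimnames(dw$dw)),
                       check.names = FALSE)
  out
}
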