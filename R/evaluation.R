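#' Confusion matrix of a classification against reference points
#'
#' Rows are predicted classes, columns reference classes, in fixed class
#' order (LC first). Each point of the requested split contributes one count
#' at (predicted class at its pixel, its reference class). Points whose
#' predicted pixel is NoData go to a reject row reported separately and are
#' excluded from `n`.
#'
#' @param predicted a [label_raster()] or `classification_result`, or an
#'   integer vector of predictions aligned with `samples`.
#' @param samples a sample set.
#' @param split which split to tally (default `"validation"`).
#' @return object of class `confusion_matrix` with `counts` (5 x 5), `n`,
#'   and `reject` (per-reference-class NoData counts).
#' @export
confusion_matrix <- function(predicted, samples, split = "validation") {
  pts <- samples[samples$split == split, , drop = FALSE]
  if (nrow(pts) == 0) stop("no points in split '", split, "'")
  if (inherits(predicted, "classification_result")) predicted <- predicted$labels
  if (inherits(predicted, "label_raster")) {
    geom <- predicted$geom
    rc <- rowcol_from_xy(geom, pts$x, pts$y)
    inside <- in_extent(geom, rc[, 1], rc[, 2])
    if (!all(inside))
      stop("validation point(s) outside extent: ",
           paste(pts$id[!inside], collapse = ", "))
    pred <- predicted$values[cbind(rc[, 1], rc[, 2])]
  } else {
    pred <- as.integer(predicted)
    stopifnot(length(pred) == nrow(pts))
  }
  ref <- pts$class_code
  counts <- matrix(0L, 5, 5, dimnames = list(predicted = CLASS_NAMES,
                                             reference = CLASS_NAMES))
  keep <- pred != 0L
  for (i in which(keep)) counts[pred[i], ref[i]] <- counts[pred[i], ref[i]] + 1L
  reject <- tabulate(ref[!keep], nbins = 5)
  structure(list(counts = counts, n = sum(counts),
                 reject = stats::setNames(reject, CLASS_NAMES)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> n =", x$n, "\n")
  print(x$counts)
  if (sum(x$reject)) cat("rejected (NoData predictions):", sum(x$reject), "\n")
  invisible(x)
}

#' Accuracy metrics of a confusion matrix
#'
#' Overall accuracy is the diagonal fraction; the Kappa coefficient is the
#' chance-corrected agreement `(n * sum x_ii - sum x_i. x_.j) / (n^2 - sum
#' x_i. x_.j)`; per-class producer accuracy divides the diagonal by the
#' column (reference) sum, user accuracy by the row (prediction) sum, and F1
#' is their harmonic mean. All values are stored as fractions in `[0, 1]`.
#'
#' @param cm a [confusion_matrix()].
#' @param reference_class code of the class of interest (default 1, LC).
#' @param combination,classifier,fold provenance fields carried through.
#' @return object of class `metrics_report` with `overall_accuracy`, `kappa`,
#'   per-class `producer_accuracy`, `user_accuracy`, `f1`, the reference
#'   class's `composite`, and provenance.
#' @export
compute_metrics <- function(cm, reference_class = 1L,
                            combination = NA_character_,
                            classifier = NA_character_, fold = NA_integer_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  n <- cm$n
  if (n == 0) stop("empty confusion matrix")
  ri <- rowSums(m); cj <- colSums(m)
  oa <- sum(diag(m)) / n
  chance <- sum(ri * cj)
  kappa <- (n * sum(diag(m)) - chance) / (n^2 - chance)
  pa <- ifelse(cj > 0, diag(m) / cj, NA_real_)
  ua <- ifelse(ri > 0, diag(m) / ri, NA_real_)
  f1 <- ifelse(!is.na(pa) & !is.na(ua) & pa + ua > 0,
               2 * pa * ua / (pa + ua), NA_real_)
  rep <- structure(list(overall_accuracy = oa, kappa = kappa,
                        producer_accuracy = pa, user_accuracy = ua, f1 = f1,
                        reference_class = reference_class,
                        combination = combination, classifier = classifier,
                        fold = fold),
                   class = "metrics_report")
  rep$composite <- composite_score(rep)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  k <- x$reference_class
  cat(sprintf(paste0("<metrics_report> %s/%s OA %.2f%% Kappa %.2f | %s: ",
                     "PA %.2f%% UA %.2f%% F1 %.2f%% | composite %.2f\n"),
              x$combination, x$classifier, 100 * x$overall_accuracy, x$kappa,
              CLASS_NAMES[k], 100 * x$producer_accuracy[k],
              100 * x$user_accuracy[k], 100 * x$f1[k], x$composite))
  invisible(x)
}

#' Invert the F1 formula for producer accuracy
#'
#' Given F1 and user accuracy, returns the producer accuracy satisfying
#' `F1 = 2 PA UA / (PA + UA)`, i.e. `PA = F1 UA / (2 UA - F1)`. Requires
#' `0 < F1 < 2 UA`.
#'
#' @param f1,ua fractions in (0, 1].
#' @return producer accuracy as a fraction.
#' @export
pa_from_f1_ua <- function(f1, ua) {
  if (any(f1 <= 0) || any(2 * ua <= f1))
    stop("pa_from_f1_ua requires 0 < f1 < 2 * ua")
  f1 * ua / (2 * ua - f1)
}

#' Equal-weight composite score
#'
#' `0.2 * (OA + Kappa + PA_ref + UA_ref + F1_ref)`, all five terms as
#' fractions in `[0, 1]`. Accepts a [compute_metrics()] report or the five
#' values.
#'
#' @param report a `metrics_report`, or OA when giving the five values.
#' @param kappa,pa,ua,f1 remaining terms when calling with plain values.
#' @return composite score in `[0, 1]` (`NA` when any term is undefined).
#' @export
composite_score <- function(report, kappa = NULL, pa = NULL, ua = NULL,
                            f1 = NULL) {
  if (inherits(report, "metrics_report")) {
    k <- report$reference_class
    vals <- c(report$overall_accuracy, report$kappa,
              report$producer_accuracy[k], report$user_accuracy[k],
              report$f1[k])
  } else {
    vals <- c(report, kappa, pa, ua, f1)
    stopifnot(length(vals) == 5)
  }
  if (any(is.na(vals))) return(NA_real_)
  0.2 * sum(vals)
}

#' Cross-validate a classifier over sample-table folds
#'
#' For each fold, the classifier is trained on the training rows outside the
#' fold and evaluated both on the held-out fold and on the validation split.
#' Validation-split metrics are the replicate unit used for ranking (they
#' assess the full map against the verification samples; the held-out-fold
#' metrics are returned for diagnostics).
#'
#' @param table a sample table with fold assignments.
#' @param layers feature column names.
#' @param classifier `"ml"` or `"svm"` for pixel classifiers; or a function
#'   `f(train_table, layers, eval_table)` returning predicted codes for
#'   `eval_table`.
#' @param combination provenance id.
#' @param folds number of folds (default: all folds present).
#' @return list of `metrics_report` (one per fold, validation-split based),
#'   each with a `holdout` attribute carrying the held-out-fold report.
#' @export
crossvalidate <- function(table, layers, classifier = "ml",
                          combination = NA_character_, folds = NULL) {
  fold_ids <- sort(unique(table$fold[table$split == "train" & !is.na(table$fold)]))
  if (!is.null(folds)) fold_ids <- seq_len(folds)
  if (length(fold_ids) < 2) stop("need at least 2 folds")
  predfun <- if (is.function(classifier)) classifier
  else switch(tolower(classifier),
    ml = function(tr, layers, ev) predict_ml_table(fit_ml(tr, layers), ev),
    svm = function(tr, layers, ev)
      predict_svm_table(fit_predict_svm(tr, layers), ev),
    stop("unknown classifier: ", classifier))
  clf_id <- if (is.function(classifier)) "custom" else toupper(classifier)
  val <- table[table$split == "validation", , drop = FALSE]
  lapply(fold_ids, function(f) {
    tr <- table[table$split == "train" & table$fold != f, , drop = FALSE]
    missing <- setdiff(CLASS_CODES, unique(tr$class_code))
    missing <- intersect(missing, unique(table$class_code))
    if (length(missing))
      stop("fold ", f, ": class(es) ", paste(missing, collapse = ", "),
           " absent from the training portion")
    ho <- table[table$split == "train" & table$fold == f, , drop = FALSE]
    rep_val <- compute_metrics(
      tally_predictions(predfun(tr, layers, val), val),
      combination = combination, classifier = clf_id, fold = f)
    attr(rep_val, "holdout") <- compute_metrics(
      tally_predictions(predfun(tr, layers, ho), ho),
      combination = combination, classifier = clf_id, fold = f)
    rep_val
  })
}

# Tally predicted codes against a table's class_code into a confusion matrix.
tally_predictions <- function(pred, table) {
  counts <- matrix(0L, 5, 5, dimnames = list(predicted = CLASS_NAMES,
                                             reference = CLASS_NAMES))
  keep <- pred != 0L
  for (i in which(keep))
    counts[pred[i], table$class_code[i]] <- counts[pred[i], table$class_code[i]] + 1L
  structure(list(counts = counts, n = sum(counts),
                 reject = stats::setNames(tabulate(table$class_code[!keep],
                                                   nbins = 5), CLASS_NAMES)),
            class = "confusion_matrix")
}

#' Rank feature combinations by composite score with significance marks
#'
#' One-way ANOVA across combinations on the per-fold composite scores,
#' followed by Tukey HSD contrasts of every combination against the
#' baseline; rows are sorted by mean composite descending (ties by id) and
#' combinations significantly above the baseline (Tukey p < 0.05) are
#' starred.
#'
#' @param reports list of `metrics_report` objects (all combinations and
#'   folds for one classifier family), or a data frame with columns
#'   `combination`, `fold`, `composite`.
#' @param baseline baseline combination id (default `"RGB"`).
#' @return object of class `ranking_table`: the ranking data frame plus
#'   `anova_f`, `anova_p` and the Tukey contrast table.
#' @export
rank_combinations <- function(reports, baseline = "RGB") {
  df <- if (is.data.frame(reports)) reports else
    do.call(rbind, lapply(reports, function(r)
      data.frame(combination = r$combination, fold = r$fold,
                 composite = r$composite)))
  if (length(unique(df$combination)) < 2)
    stop("ranking requires at least 2 combinations")
  if (!baseline %in% df$combination)
    stop("baseline '", baseline, "' not among the combinations")
  df$combination <- factor(df$combination)
  fit <- stats::aov(composite ~ combination, data = df)
  an <- summary(fit)[[1]]
  tuk <- tryCatch(stats::TukeyHSD(fit)$combination, error = function(e) NULL)

  agg <- stats::aggregate(composite ~ combination, df,
                          function(z) c(mean = mean(z), sd = stats::sd(z)))
  tab <- data.frame(combination = as.character(agg$combination),
                    mean_composite = agg$composite[, "mean"],
                    sd_composite = agg$composite[, "sd"])
  tab$p_vs_baseline <- NA_real_
  tab$significant <- FALSE
  if (!is.null(tuk)) {
    for (i in seq_len(nrow(tab))) {
      cb <- tab$combination[i]
      if (cb == baseline) next
      key <- c(paste0(cb, "-", baseline), paste0(baseline, "-", cb))
      hit <- key[key %in% rownames(tuk)][1]
      if (!is.na(hit)) {
        p <- tuk[hit, "p adj"]
        dirn <- tuk[hit, "diff"] * (if (startsWith(hit, paste0(cb, "-"))) 1 else -1)
        tab$p_vs_baseline[i] <- p
        tab$significant[i] <- isTRUE(!is.na(p) && p < 0.05 && dirn > 0)
      }
    }
  }
  ord <- order(-tab$mean_composite, tab$combination)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$marker <- ifelse(tab$significant, "*", "")
  rownames(tab) <- NULL
  structure(list(table = tab,
                 anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tuk, baseline = baseline),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table> ANOVA F = %.3g, p = %.3g (baseline %s)\n",
              x$anova_f, x$anova_p, x$baseline))
  df <- x$table
  df$mean_composite <- sprintf("%.2f", df$mean_composite)
  print(df[, c("rank", "combination", "mean_composite", "marker")],
        row.names = FALSE)
  invisible(x)
}
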