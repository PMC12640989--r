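#' Extract per-point feature values from a stack
#'
#' Each sample point reads the single pixel containing it (points are
#' nominally 0.2 m discs, but at 0.10 m/pixel a disc spans ~2 pixels and no
#' averaging is defined, so the containing pixel is used). Points that fall
#' on masked pixels are dropped with a warning; points outside the stack
#' extent are an error.
#'
#' @param stack a [feature_stack()].
#' @param samples a sample set data frame.
#' @return a `sample_table` data frame: `id`, `class_code`, `split`, `fold`
#'   plus one column per stack layer (names preserved verbatim).
#' @export
extract_sample_values <- function(stack, samples) {
  geom <- stack$geom
  rc <- rowcol_from_xy(geom, samples$x, samples$y)
  inside <- in_extent(geom, rc[, 1], rc[, 2])
  if (!all(inside))
    stop("sample point(s) outside the stack extent: ",
         paste(samples$id[!inside], collapse = ", "))
  lin <- (rc[, 2] - 1L) * geom$height + rc[, 1]
  valid <- stack$mask[lin]
  if (any(!valid))
    warning(sum(!valid), " sample point(s) on masked pixels were dropped")
  vals <- vapply(stack$layers, function(l) l[lin], numeric(nrow(samples)))
  if (nrow(samples) == 1L) vals <- matrix(vals, nrow = 1,
                                          dimnames = list(NULL, stack_names(stack)))
  out <- data.frame(id = samples$id, class_code = samples$class_code,
                    split = samples$split, fold = samples$fold,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  out <- out[valid, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Pearson correlation matrix over feature columns
#'
#' Pairwise-complete Pearson correlations; zero-variance columns yield `NA`
#' entries, flagged in the `undefined` attribute.
#'
#' @param table a sample table from [extract_sample_values()].
#' @param columns feature column names (default: all non-metadata columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, columns = NULL) {
  meta <- c("id", "class_code", "split", "fold")
  if (is.null(columns)) columns <- setdiff(names(table), meta)
  if (nrow(table) < 3) stop("need at least 3 rows")
  m <- as.matrix(table[, columns, drop = FALSE])
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  zero <- names(sds)[!is.na(sds) & sds == 0]
  diag(cm) <- 1
  attr(cm, "undefined") <- zero
  cm
}

#' Interclass difference score between two class means
#'
#' `Dw = |(Mc - Mn) / Mc| * 100`, where `Mc` is the reference (LC) class mean
#' and `Mn` another class's mean, in percent. Undefined (`NA`) when `Mc = 0`.
#'
#' @param Mc reference class mean.
#' @param Mn comparison class mean.
#' @return Dw in percent (vectorised).
#' @export
interclass_difference <- function(Mc, Mn) {
  out <- abs((Mc - Mn) / Mc) * 100
  out[!is.na(Mc) & Mc == 0] <- NA_real_
  out
}

#' Per-feature interclass difference table
#'
#' Class means are computed from training-split rows only (screening precedes
#' classification and must not touch validation data); `Dw` compares the
#' reference class's mean against each other class's.
#'
#' @param table a sample table.
#' @param reference_class class code of the target class (default 1, LC).
#' @param columns feature columns (default: all).
#' @return list with `dw` (features x other classes matrix, percent),
#'   `class_means` (features x classes) and `reference_class`.
#' @export
dw_table <- function(table, reference_class = 1L, columns = NULL) {
  meta <- c("id", "class_code", "split", "fold")
  if (is.null(columns)) columns <- setdiff(names(table), meta)
  tr <- table[table$split == "train", , drop = FALSE]
  if (!reference_class %in% tr$class_code)
    stop("reference class ", reference_class, " absent from training rows")
  classes <- sort(unique(tr$class_code))
  means <- sapply(classes, function(k)
    colMeans(tr[tr$class_code == k, columns, drop = FALSE], na.rm = TRUE))
  means <- matrix(means, nrow = length(columns),
                  dimnames = list(columns, classes))
  others <- setdiff(classes, reference_class)
  dw <- sapply(others, function(k)
    interclass_difference(means[, as.character(reference_class)],
                          means[, as.character(k)]))
  dw <- matrix(dw, nrow = length(columns),
               dimnames = list(columns, CLASS_NAMES[others]))
  list(dw = dw, class_means = means, reference_class = reference_class)
}

#' Select one representative feature per category
#'
#' Within each of the CI, GLCM and CS categories the feature maximising the
#' minimum Dw across the non-reference classes is chosen; ties break by
#' higher mean Dw, then lexicographically. Features with any undefined Dw are
#' excluded. The DEM category has a single member and needs no screening.
#'
#' @param dw result of [dw_table()].
#' @param category named character vector mapping feature names to categories
#'   (as stored in a [feature_stack()]).
#' @return named list `list(CI =, GLCM =, CS =)` with a `report` attribute
#'   (per-candidate min/mean Dw and selection flag).
#' @export
select_representatives <- function(dw, category) {
  D <- dw$dw
  pick <- function(cat) {
    cand <- intersect(rownames(D), names(category)[category == cat])
    cand <- cand[!apply(is.na(D[cand, , drop = FALSE]), 1, any)]
    if (!length(cand))
      stop("no candidate with defined Dw in category ", cat)
    mind <- apply(D[cand, , drop = FALSE], 1, min)
    meand <- rowMeans(D[cand, , drop = FALSE])
    ord <- order(-mind, -meand, cand)
    list(name = cand[ord[1]],
         report = data.frame(feature = cand, category = cat,
                             min_dw = unname(mind), mean_dw = unname(meand),
                             selected = cand == cand[ord[1]]))
  }
  picks <- lapply(c(CI = "CI", GLCM = "GLCM", CS = "CS"), pick)
  out <- lapply(picks, `[[`, "name")
  attr(out, "report") <- do.call(rbind, lapply(picks, `[[`, "report"))
  out
}

#' Enumerate the 15 feature combinations plus the RGB baseline
#'
#' All non-empty subsets of the CI, CS, GLCM and DEM categories in the
#' canonical order (single categories CI, CS, GLCM, DEM; then pairs; then
#' triples; then all four), each resolved to the selected representative
#' layers, plus an RGB baseline spec over the raw bands.
#'
#' @param selected list from [select_representatives()].
#' @param dem_present whether a DEM layer is available (default `TRUE`).
#' @return list of `combination_spec` records: `id`, `categories`,
#'   `layer_names`.
#' @export
build_combinations <- function(selected, dem_present = TRUE) {
  if (!dem_present) stop("the combination design requires a DEM layer")
  cats <- list(
    "CI", "CS", "GLCM", "DEM",
    c("CI", "CS"), c("CI", "GLCM"), c("CI", "DEM"),
    c("CS", "GLCM"), c("CS", "DEM"), c("GLCM", "DEM"),
    c("CI", "CS", "GLCM"), c("CI", "CS", "DEM"), c("CI", "GLCM", "DEM"),
    c("CS", "GLCM", "DEM"), c("CI", "CS", "GLCM", "DEM")
  )
  resolve <- function(cs) vapply(cs, function(ct)
    if (ct == "DEM") "DEM" else selected[[ct]], character(1), USE.NAMES = FALSE)
  combos <- lapply(seq_along(cats), function(i)
    structure(list(id = paste0("FC", i), categories = cats[[i]],
                   layer_names = resolve(cats[[i]])),
              class = "combination_spec"))
  combos[[16]] <- structure(list(id = "RGB", categories = character(0),
                                 layer_names = c("R", "G", "B")),
                            class = "combination_spec")
  combos
}
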