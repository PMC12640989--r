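random_confusion <- function(n = 5) {
  counts <- matrix(rpois(25, 8) + diag(5) * rpois(5, 30), 5, 5,
                   dimnames = list(predicted = plotsieve:::CLASS_NAMES,
                                   reference = plotsieve:::CLASS_NAMES))
  structure(list(counts = counts, n = sum(counts),
                 reject = setNames(rep(0L, 5), plotsieve:::CLASS_NAMES)),
            class = "confusion_matrix")
}

test_that("confusion matrices tally predictions against reference points", {
  sc <- small_scene()
  samp <- small_samples()
  # perfect prediction -> diagonal matrix
  cm <- confusion_matrix(sc$labels, samp)
  expect_equal(sum(diag(cm$counts)), cm$n)
  expect_equal(cm$n, sum(samp$split == "validation"))
  # constant prediction -> single nonzero row
  const <- make_labels(matrix(3L, 120, 120))
  cm2 <- confusion_matrix(const, samp)
  expect_equal(unname(rowSums(cm2$counts) > 0), c(F, F, T, F, F))
  # random predictions equal a brute-force tally
  set.seed(19)
  v <- matrix(sample(1:5, 120 * 120, TRUE), 120, 120)
  cm3 <- confusion_matrix(make_labels(v), samp)
  val <- samp[samp$split == "validation", ]
  rc <- plotsieve:::rowcol_from_xy(sc$labels$geom, val$x, val$y)
  want <- matrix(0L, 5, 5)
  for (i in seq_len(nrow(val)))
    want[v[rc[i, 1], rc[i, 2]], val$class_code[i]] <-
      want[v[rc[i, 1], rc[i, 2]], val$class_code[i]] + 1L
  expect_equal(unname(cm3$counts), want)
  # NoData predictions land in the reject tally, not n
  v[rc[1, 1], rc[1, 2]] <- 0L
  cm4 <- confusion_matrix(make_labels(v), samp)
  expect_equal(sum(cm4$reject), sum(v[rc] == 0L))
  expect_equal(cm4$n + sum(cm4$reject), nrow(val))
})

test_that("metrics match a literal transcription on random matrices", {
  set.seed(23)
  for (rep in 1:1000) {
    cm <- random_confusion()
    got <- compute_metrics(cm)
    want <- metrics_transcription(cm$counts)
    expect_equal(got$overall_accuracy, want$oa, tolerance = 1e-12)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
    expect_equal(got$producer_accuracy, want$pa, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$user_accuracy, want$ua, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$f1, want$f1, tolerance = 1e-12, ignore_attr = TRUE)
    # F1 is a harmonic mean: bracketed by PA and UA
    ok <- !is.na(got$f1)
    expect_true(all(got$f1[ok] >= pmin(got$producer_accuracy,
                                       got$user_accuracy)[ok] - 1e-12))
    expect_true(all(got$f1[ok] <= pmax(got$producer_accuracy,
                                       got$user_accuracy)[ok] + 1e-12))
  }
})

test_that("perfect and chance-level matrices hit their closed forms", {
  diagm <- structure(list(counts = diag(c(10L, 20L, 30L, 5L, 7L)), n = 72L,
                          reject = rep(0L, 5)), class = "confusion_matrix")
  m <- compute_metrics(diagm)
  expect_equal(m$overall_accuracy, 1)
  expect_equal(m$kappa, 1)
  expect_equal(unname(m$producer_accuracy), rep(1, 5))
  expect_equal(unname(m$f1), rep(1, 5))
  expect_equal(m$composite, 1)

  even <- matrix(0L, 5, 5); even[1:2, 1:2] <- 25L
  ev <- compute_metrics(structure(list(counts = even, n = 100L,
                                       reject = rep(0L, 5)),
                                  class = "confusion_matrix"))
  expect_equal(ev$overall_accuracy, 0.5)
  expect_equal(ev$kappa, 0)
})

test_that("kappa reaches 1 exactly when agreement is perfect", {
  set.seed(29)
  for (rep in 1:200) {
    cm <- random_confusion()
    m <- compute_metrics(cm)
    off <- sum(cm$counts) - sum(diag(cm$counts))
    if (off == 0) expect_equal(m$kappa, 1)
    else expect_lt(m$kappa, 1)
  }
})

test_that("producer accuracy inverts the F1 formula and round-trips", {
  expect_equal(pa_from_f1_ua(0.8, 0.8), 0.8)
  pa <- pa_from_f1_ua(0.9275, 0.9405)
  expect_equal(pa, 0.9275 * 0.9405 / (2 * 0.9405 - 0.9275))
  expect_equal(2 * pa * 0.9405 / (pa + 0.9405), 0.9275, tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:50) {
    p <- runif(1, 0.1, 1); u <- runif(1, 0.1, 1)
    f1 <- 2 * p * u / (p + u)
    expect_equal(pa_from_f1_ua(f1, u), p, tolerance = 1e-12)
  }
  expect_error(pa_from_f1_ua(0.9, 0.45), "2 \\* ua")
})

test_that("the composite score is the equal-weight mean of its five terms", {
  expect_equal(composite_score(1, 1, 1, 1, 1), 1)
  expect_equal(composite_score(0, 0, 0, 0, 0), 0)
  set.seed(35)
  v <- runif(5)
  expect_equal(composite_score(v[1], v[2], v[3], v[4], v[5]), 0.2 * sum(v))
  # order invariance and strict monotonicity in each term
  expect_equal(composite_score(v[5], v[4], v[3], v[2], v[1]),
               composite_score(v[1], v[2], v[3], v[4], v[5]))
  for (i in 1:5) {
    w <- v; w[i] <- w[i] + 0.01
    expect_gt(composite_score(w[1], w[2], w[3], w[4], w[5]),
              composite_score(v[1], v[2], v[3], v[4], v[5]))
  }
})

test_that("cross-validation trains per fold on a stratified partition", {
  tab <- small_table()
  reps <- crossvalidate(tab, c("VDVI", "DEM"), "ml", combination = "FC7")
  expect_length(reps, 5)
  for (f in 1:5) {
    expect_equal(reps[[f]]$fold, f)
    expect_s3_class(attr(reps[[f]], "holdout"), "metrics_report")
  }
  # fold assignments stratify classes within +-1
  tr <- tab[tab$split == "train", ]
  per <- table(tr$class_code, tr$fold)
  expect_true(all(abs(per - rowMeans(per)) <= 1))
  # a perfectly separable feature gives OA 1 in every fold
  tab$sep <- tab$class_code * 10
  reps2 <- crossvalidate(tab, "sep", "ml")
  expect_true(all(sapply(reps2, `[[`, "overall_accuracy") == 1))
  expect_true(all(sapply(reps2, function(r)
    attr(r, "holdout")$overall_accuracy) == 1))
})

test_that("ranking sorts by mean composite and stars only real separations", {
  base <- expand.grid(combination = c("RGB", "FC1", "FC15"), fold = 1:5)
  base$composite <- 0.8
  rk0 <- rank_combinations(base)
  expect_false(any(rk0$table$significant))
  expect_equal(rk0$table$combination[order(rk0$table$combination)],
               sort(c("RGB", "FC1", "FC15")))

  set.seed(37)
  df <- base
  df$composite <- 0.8 + rnorm(nrow(df), 0, 0.005)
  df$composite[df$combination == "FC15"] <-
    df$composite[df$combination == "FC15"] + 0.1 # +10 or so SDs
  rk <- rank_combinations(df)
  tab <- rk$table
  expect_equal(tab$combination[1], "FC15")
  expect_true(tab$significant[tab$combination == "FC15"])
  expect_equal(tab$marker[tab$combination == "FC15"], "*")
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$mean_composite) <= 0))
  expect_error(rank_combinations(df[df$combination == "RGB", ]),
               "at least 2")
})
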