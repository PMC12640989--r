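# Shared fixtures, built in code at test time.

# Small metameric scene + samples + full analysis stack, memoised per session.
local({
  cache <- new.env(parent = emptyenv())
  small_scene <<- function() {
    if (is.null(cache$scene))
      cache$scene <- generate_scene(
        scene_config(width = 120, height = 120, pixel_size = 1, seed = 7))
    cache$scene
  }
  small_samples <<- function() {
    if (is.null(cache$samples))
      cache$samples <- generate_samples(
        small_scene()$labels, list(train = 30, validation = 60),
        min_spacing_m = 3, seed = 3)
    cache$samples
  }
  small_stack <<- function() {
    if (is.null(cache$stack))
      cache$stack <- build_analysis_stack(small_scene()$rgb, small_scene()$dem)
    cache$stack
  }
  small_table <<- function() {
    if (is.null(cache$table))
      cache$table <- suppressWarnings(
        extract_sample_values(small_stack(), small_samples()))
    cache$table
  }
})

# An rgb_image from an h x w x 3 array of DNs.
make_rgb <- function(arr, pixel_size = 1) {
  rgb_image(arr, plotsieve:::new_grid_geometry(dim(arr)[2], dim(arr)[1],
                                               pixel_size))
}

rgb_from_bands <- function(R, G, B, pixel_size = 1) {
  make_rgb(array(c(R, G, B), dim = c(nrow(R), ncol(R), 3)), pixel_size)
}

make_labels <- function(m, pixel_size = 1) {
  label_raster(m, plotsieve:::new_grid_geometry(ncol(m), nrow(m), pixel_size))
}

# Scalar transcription of the eight texture statistics of a normalised,
# symmetric co-occurrence matrix P (levels indexed from 0), written as a
# literal double loop, independent of the package implementation.
glcm_stats_transcription <- function(P) {
  Ng <- nrow(P)
  mu <- 0
  for (i in 1:Ng) for (j in 1:Ng) mu <- mu + (i - 1) * P[i, j]
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((0:(Ng - 1)) * px); muy <- sum((0:(Ng - 1)) * py)
  sx <- sqrt(sum(((0:(Ng - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(Ng - 1)) - muy)^2 * py))
  mea <- var <- hom <- con <- dis <- ent <- sem <- cor_n <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]; a <- i - 1; b <- j - 1
    mea <- mea + a * p
    var <- var + (a - mu)^2 * p
    hom <- hom + p / (1 + (a - b)^2)
    con <- con + (a - b)^2 * p
    dis <- dis + abs(a - b) * p
    if (p > 0) ent <- ent - p * log(p)
    sem <- sem + p^2
    cor_n <- cor_n + a * b * p
  }
  cor <- if (sx * sy > 0) (cor_n - mux * muy) / (sx * sy) else 0
  c(MEA = mea, VAR = var, HOM = hom, CON = con, DIS = dis, ENT = ent,
    SEM = sem, COR = cor)
}

# Random normalised symmetric co-occurrence matrix.
random_glcm_P <- function(Ng = 6) {
  M <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  M <- M + t(M)
  M / sum(M)
}

# Transcription of the confusion-matrix metrics (fractions).
metrics_transcription <- function(m) {
  n <- sum(m)
  r <- nrow(m)
  ri <- rowSums(m); cj <- colSums(m)
  oa <- sum(diag(m)) / n
  kappa <- (n * sum(diag(m)) - sum(ri * cj)) / (n^2 - sum(ri * cj))
  pa <- diag(m) / cj
  ua <- diag(m) / ri
  f1 <- 2 * pa * ua / (pa + ua)
  list(oa = oa, kappa = kappa, pa = pa, ua = ua, f1 = f1)
}

# Brute-force windowed mode with the package's tie rule (keep current label
# when it ties the mode; else the lowest modal code), clipped window, NoData
# excluded from votes.
mode_filter_bruteforce <- function(v, kernel = 3L) {
  r <- kernel %/% 2
  h <- nrow(v); w <- ncol(v)
  out <- v
  for (i in 1:h) for (j in 1:w) {
    if (v[i, j] == 0L) next
    win <- v[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    win <- win[win != 0L]
    tab <- table(win)
    modes <- as.integer(names(tab)[tab == max(tab)])
    out[i, j] <- if (v[i, j] %in% modes) v[i, j] else min(modes)
  }
  out
}

# 4-connected components by flood fill, independent of the C++ labelling.
cc_bruteforce <- function(v) {
  h <- nrow(v); w <- ncol(v)
  out <- matrix(0L, h, w)
  nxt <- 0L
  for (i0 in 1:h) for (j0 in 1:w) {
    if (v[i0, j0] <= 0L || out[i0, j0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0)); out[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            out[q[1], q[2]] == 0L && v[q[1], q[2]] == v[i0, j0])
          { out[q[1], q[2]] <- nxt; queue <- c(queue, list(q)) }
      }
    }
  }
  out
}
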