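GLCM_STATS <- c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEM", "COR")

#' Quantize an 8-bit band to Ng gray levels
#'
#' Linear mapping `level = floor(DN * Ng / 256)`, monotone non-decreasing in
#' DN; with the default `Ng = 64` each level covers 4 consecutive DNs.
#'
#' @param band numeric matrix of digital numbers in `[0, 255]`.
#' @param Ng number of gray levels (>= 2).
#' @return integer matrix of levels in `[0, Ng - 1]`, with `Ng` attached as an
#'   attribute.
#' @export
quantize_band <- function(band, Ng = 64L) {
  if (Ng < 2) stop("Ng must be at least 2")
  v <- range(band, na.rm = TRUE, finite = TRUE)
  if (any(is.finite(v)) && (v[1] < 0 || v[2] > 255))
    stop("band values must lie in [0, 255]")
  lev <- matrix(as.integer(floor(band * Ng / 256)), nrow(band), ncol(band))
  attr(lev, "Ng") <- as.integer(Ng)
  lev
}

mirror_index <- function(i, n) {
  # reflect-101: index 0 -> 2, n+1 -> n-1 (1-based)
  while (any(bad <- i < 1 | i > n)) {
    i[bad & i < 1] <- 2 - i[bad & i < 1]
    i[bad & i > n] <- 2 * n - i[bad & i > n]
  }
  i
}

#' Gray-level co-occurrence matrix of one window
#'
#' Accumulates co-occurrences of level pairs at displacement (0, +1) — the 0
#' degree direction at distance 1 — over a window centred on a pixel,
#' symmetrises (each unordered pair counted in both directions) and
#' normalises to sum 1. Edges are handled by reflect-101 padding. Marginal
#' moments are attached.
#'
#' @param levels level raster from [quantize_band()].
#' @param center integer `c(row, col)` of the window center.
#' @param window odd window side length (default 3).
#' @return object of class `glcm_matrix` with fields `P`, `Ng`, `mu`, `mu_x`,
#'   `mu_y`, `sigma_x`, `sigma_y` and an `empty` flag.
#' @export
glcm_at_window <- function(levels, center, window = 3L) {
  if (window %% 2 == 0) stop("window must be odd")
  Ng <- attr(levels, "Ng")
  if (is.null(Ng)) Ng <- max(levels, na.rm = TRUE) + 1L
  h <- nrow(levels); w <- ncol(levels)
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w)
    stop("center outside the raster")
  r <- window %/% 2
  rows <- mirror_index(center[1] + (-r:r), h)
  cols <- mirror_index(center[2] + (-r:r), w)
  P <- matrix(0, Ng, Ng)
  for (ri in rows) {
    for (k in seq_len(window - 1)) {
      a <- levels[ri, cols[k]]; b <- levels[ri, cols[k + 1]]
      if (is.na(a) || is.na(b)) next
      P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
      P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
    }
  }
  tot <- sum(P)
  if (tot == 0)
    return(structure(list(P = P, Ng = Ng, mu = NA_real_, mu_x = NA_real_,
                          mu_y = NA_real_, sigma_x = NA_real_,
                          sigma_y = NA_real_, empty = TRUE),
                     class = "glcm_matrix"))
  P <- P / tot
  lev <- 0:(Ng - 1)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  structure(list(P = P, Ng = Ng,
                 mu = sum(outer(lev, rep(1, Ng)) * P),
                 mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sqrt(sum((lev - mu_x)^2 * px)),
                 sigma_y = sqrt(sum((lev - mu_y)^2 * py)),
                 empty = FALSE),
            class = "glcm_matrix")
}

#' The eight GLCM statistics of one co-occurrence matrix
#'
#' Mean is the row-marginal mean `sum i * P(i, j)` (levels indexed from 0);
#' Variance uses that mean; Homogeneity, Contrast and Dissimilarity weight
#' `P` by `1/(1+(i-j)^2)`, `(i-j)^2` and `|i-j|`; Entropy uses
#' `-sum P log P` with `0 log 0 = 0`; Second Moment is `sum P^2`;
#' Correlation is `(sum i*j*P - mu_x mu_y) / (sigma_x sigma_y)`, defined as 0
#' (with a flag) when a marginal standard deviation vanishes, as happens for
#' constant windows.
#'
#' @param m a `glcm_matrix` from [glcm_at_window()].
#' @return named numeric vector of MEA, VAR, HOM, CON, DIS, ENT, SEM, COR;
#'   attribute `cor_degenerate` flags the zero-variance case.
#' @export
glcm_statistics <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  if (isTRUE(m$empty))
    return(stats::setNames(rep(NA_real_, 8), GLCM_STATS))
  lev <- 0:(m$Ng - 1)
  I <- matrix(lev, m$Ng, m$Ng)            # row index value
  J <- t(I)
  P <- m$P
  mea <- sum(I * P)
  pos <- P > 0
  degenerate <- m$sigma_x * m$sigma_y == 0
  out <- c(
    MEA = mea,
    VAR = sum((I - mea)^2 * P),
    HOM = sum(P / (1 + (I - J)^2)),
    CON = sum((I - J)^2 * P),
    DIS = sum(abs(I - J) * P),
    ENT = -sum(P[pos] * log(P[pos])),
    SEM = sum(P^2),
    COR = if (degenerate) 0 else
      (sum(I * J * P) - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  )
  attr(out, "cor_degenerate") <- degenerate
  out
}

#' Compute the 24 GLCM texture layers
#'
#' For each band (R, G, B) and each of the eight statistics, a layer named
#' `<band>-<STAT>` (e.g. `"B-MEA"`) is produced by sliding the co-occurrence
#' window over every pixel.
#'
#' @param rgb an [rgb_image()].
#' @param window odd window side length (default 3).
#' @param Ng quantization levels (default 64).
#' @return a [feature_stack()] with 24 layers of category `"GLCM"`.
#' @export
compute_texture_layers <- function(rgb, window = 3L, Ng = 64L) {
  stopifnot(inherits(rgb, "rgb_image"))
  if (window %% 2 == 0) stop("window must be odd")
  layers <- list()
  for (bi in 1:3) {
    bname <- c("R", "G", "B")[bi]
    lev <- quantize_band(band(rgb, bi), Ng)
    res <- glcm_stats_cpp(lev, rgb$mask, as.integer(window))
    for (st in GLCM_STATS) layers[[paste0(bname, "-", st)]] <- res[[st]]
  }
  feature_stack(layers, stats::setNames(rep("GLCM", length(layers)),
                                        names(layers)),
                rgb$geom, rgb$mask)
}
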