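test_that("color indices hit their closed-form anchor pixels", {
  px <- rgb_from_bands(matrix(c(0, 100)), matrix(c(255, 100)),
                       matrix(c(0, 100)))
  ci <- compute_color_indices(px)
  g <- function(nm) get_layer(ci, nm)
  # pure green pixel
  expect_equal(g("GCC")[1, 1], 1)
  expect_equal(g("RCC")[1, 1], 0)
  expect_equal(g("BCC")[1, 1], 0)
  expect_equal(g("GRVI")[1, 1], 1)
  expect_equal(g("VDVI")[1, 1], 1)
  expect_equal(g("EXG")[1, 1], 2)
  # gray pixel: ratios collapse, WI masked (R - G = 0)
  expect_equal(g("GRVI")[2, 1], 0)
  expect_equal(g("VARI")[2, 1], 0)
  expect_equal(g("GCC")[2, 1], 1 / 3)
  expect_equal(g("VDVI")[2, 1], -1 / 3)
  expect_true(is.na(g("WI")[2, 1]))
})

test_that("all 12 index layers match a scalar re-evaluation of the formulas", {
  set.seed(42)
  h <- 25; w <- 40
  R <- matrix(sample(0:255, h * w, TRUE), h, w)
  G <- matrix(sample(0:255, h * w, TRUE), h, w)
  B <- matrix(sample(0:255, h * w, TRUE), h, w)
  ci <- compute_color_indices(rgb_from_bands(R, G, B))
  expect_equal(length(ci$layers), 12)
  expect_equal(unname(ci$category), rep("CI", 12))
  scalar <- function(r, g, b) {
    s <- r + g + b
    gcc <- if (s == 0) NA else g / s
    rcc <- if (s == 0) NA else r / s
    bcc <- if (s == 0) NA else b / s
    c(GCC = gcc, RCC = rcc, BCC = bcc,
      GRVI = if (g + r == 0) NA else (g - r) / (g + r),
      WI = if (r == g) NA else (g - b) / (r - g),
      GLI = if (2 * g + r + b == 0) NA else (2 * g - r - b) / (2 * g + r + b),
      VARI = if (g + r - b == 0) NA else (g - r) / (g + r - b),
      EXR = 1.4 * rcc - gcc, EXG = 2 * gcc - rcc - bcc,
      EXB = 1.4 * bcc - gcc,
      CIVE = 0.441 * r - 0.881 * g + 0.385 * b + 18.78745,
      VDVI = if (s == 0) NA else (g - b - r) / (g + b + r))
  }
  idx <- cbind(sample(h, 200, TRUE), sample(w, 200, TRUE))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    want <- scalar(R[i, j], G[i, j], B[i, j])
    for (nm in names(want)) {
      got <- get_layer(ci, nm)[i, j]
      if (is.na(want[[nm]])) expect_true(is.na(got))
      else expect_equal(got, want[[nm]], tolerance = 1e-12)
    }
  }
  # chromatic closure on unmasked pixels
  s3 <- get_layer(ci, "GCC") + get_layer(ci, "RCC") + get_layer(ci, "BCC")
  expect_lt(max(abs(s3[ci$mask] - 1)), 1e-9)
  expect_equal(get_layer(ci, "EXG")[ci$mask],
               (3 * get_layer(ci, "GCC") - 1)[ci$mask], tolerance = 1e-9)
  for (nm in c("VDVI", "GRVI", "GLI")) {
    v <- get_layer(ci, nm)
    expect_true(all(v[ci$mask] >= -1 - 1e-12 & v[ci$mask] <= 1 + 1e-12))
  }
})

test_that("quantization maps DN ramps onto Ng uniform levels", {
  expect_equal(quantize_band(matrix(0))[1, 1], 0L)
  expect_equal(quantize_band(matrix(255))[1, 1], 63L)
  expect_equal(quantize_band(matrix(4))[1, 1], 1L)
  ramp <- quantize_band(matrix(0:255, 1))
  expect_equal(length(unique(as.vector(ramp))), 64)
  expect_equal(as.vector(table(as.vector(ramp))), rep(4L, 64))
  expect_true(all(diff(as.vector(ramp)) >= 0))
  expect_equal(max(quantize_band(matrix(0:255, 1), Ng = 16)), 15L)
  expect_error(quantize_band(matrix(1), Ng = 1), "Ng")
})

test_that("single-window co-occurrence matrices match brute-force pair counts", {
  # constant window
  lev <- quantize_band(matrix(100, 5, 5))
  m <- glcm_at_window(lev, c(3, 3))
  expect_equal(sum(m$P), 1)
  expect_equal(m$P[26, 26], 1) # level 25
  expect_equal(m$mu, 25); expect_equal(m$mu_x, 25); expect_equal(m$mu_y, 25)
  expect_equal(m$sigma_x, 0)

  # checkerboard of two levels: support only on the off-diagonal pair
  ck <- matrix(rep(c(0L, 63L), 13)[1:25], 5, 5)
  attr(ck, "Ng") <- 64L
  m2 <- glcm_at_window(ck, c(3, 3))
  expect_equal(sum(m2$P), 1)
  expect_equal(m2$P[1, 64], 0.5); expect_equal(m2$P[64, 1], 0.5)
  expect_equal(sum(m2$P != 0), 2)

  # random windows vs literal enumeration of horizontal neighbour pairs
  set.seed(5)
  lev <- matrix(sample(0:7, 100, TRUE), 10, 10)
  attr(lev, "Ng") <- 8L
  for (ctr in list(c(5, 5), c(2, 9), c(1, 1), c(10, 10))) {
    m3 <- glcm_at_window(lev, ctr)
    ref <- matrix(0, 8, 8)
    mirror <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }; i }
    rows <- sapply(ctr[1] + (-1:1), mirror, n = 10)
    cols <- sapply(ctr[2] + (-1:1), mirror, n = 10)
    for (ri in rows) for (k in 1:2) {
      a <- lev[ri, cols[k]]; b <- lev[ri, cols[k + 1]]
      ref[a + 1, b + 1] <- ref[a + 1, b + 1] + 1
      ref[b + 1, a + 1] <- ref[b + 1, a + 1] + 1
    }
    expect_equal(m3$P, ref / sum(ref))
  }
})

test_that("texture statistics match a literal transcription on random matrices", {
  set.seed(99)
  for (rep in 1:100) {
    Ng <- sample(3:8, 1)
    P <- random_glcm_P(Ng)
    m <- structure(list(P = P, Ng = Ng), class = "glcm_matrix")
    lev <- 0:(Ng - 1)
    px <- rowSums(P); py <- colSums(P)
    m$mu_x <- sum(lev * px); m$mu_y <- sum(lev * py)
    m$sigma_x <- sqrt(sum((lev - m$mu_x)^2 * px))
    m$sigma_y <- sqrt(sum((lev - m$mu_y)^2 * py))
    m$empty <- FALSE
    got <- glcm_statistics(m)
    want <- glcm_stats_transcription(P)
    expect_equal(unclass(got), want, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate and uniform matrices hit their closed forms", {
  lev <- quantize_band(matrix(40, 3, 3)) # constant level 10
  s <- glcm_statistics(glcm_at_window(lev, c(2, 2)))
  expect_equal(unname(s["MEA"]), 10)
  expect_equal(unname(s["VAR"]), 0)
  expect_equal(unname(s["HOM"]), 1)
  expect_equal(unname(s["CON"]), 0)
  expect_equal(unname(s["DIS"]), 0)
  expect_equal(unname(s["ENT"]), 0)
  expect_equal(unname(s["SEM"]), 1)
  expect_equal(unname(s["COR"]), 0) # degenerate, flagged
  expect_true(attr(s, "cor_degenerate"))

  Ng <- 16
  uni <- structure(list(P = matrix(1 / Ng^2, Ng, Ng), Ng = Ng,
                        mu_x = (Ng - 1) / 2, mu_y = (Ng - 1) / 2,
                        sigma_x = sqrt((Ng^2 - 1) / 12),
                        sigma_y = sqrt((Ng^2 - 1) / 12), empty = FALSE),
                   class = "glcm_matrix")
  su <- glcm_statistics(uni)
  expect_equal(unname(su["SEM"]), 1 / Ng^2)
  expect_equal(unname(su["ENT"]), 2 * log(Ng))
})

test_that("sliding texture layers equal per-pixel window recomputation", {
  set.seed(12)
  arr <- array(sample(0:255, 32 * 32 * 3, TRUE), dim = c(32, 32, 3))
  rgb <- make_rgb(arr)
  tex <- compute_texture_layers(rgb)
  expect_equal(length(tex$layers), 24)
  expect_equal(unname(tex$category), rep("GLCM", 24))
  set.seed(13)
  pts <- cbind(sample(32, 20, TRUE), sample(32, 20, TRUE))
  for (bi in 1:3) {
    bn <- c("R", "G", "B")[bi]
    lev <- quantize_band(arr[, , bi])
    for (k in seq_len(nrow(pts))) {
      want <- glcm_statistics(glcm_at_window(lev, pts[k, ]))
      for (st in names(want))
        expect_equal(get_layer(tex, paste0(bn, "-", st))[pts[k, 1], pts[k, 2]],
                     unname(want[st]), tolerance = 1e-10)
    }
  }
})

test_that("constant images give the constant-image texture identities", {
  rgb <- make_rgb(array(77, dim = c(8, 8, 3)))
  tex <- compute_texture_layers(rgb)
  for (b in c("R", "G", "B")) {
    expect_true(all(get_layer(tex, paste0(b, "-CON")) == 0))
    expect_true(all(get_layer(tex, paste0(b, "-HOM")) == 1))
    expect_true(all(get_layer(tex, paste0(b, "-SEM")) == 1))
  }
})

test_that("color components match an independent HSV/HLS conversion", {
  red <- make_rgb(array(c(255, 128, 0, 128, 0, 128), dim = c(2, 1, 3)))
  cs <- compute_color_components(red)
  expect_equal(get_layer(cs, "Hue")[1, 1], 0)
  expect_equal(get_layer(cs, "Saturation")[1, 1], 1)
  expect_equal(get_layer(cs, "Value")[1, 1], 1)
  expect_equal(get_layer(cs, "Light")[1, 1], 0.5)
  # achromatic pixel
  expect_equal(get_layer(cs, "Saturation")[2, 1], 0)
  expect_equal(get_layer(cs, "Hue")[2, 1], 0)
  expect_equal(get_layer(cs, "Value")[2, 1], 128 / 255)
  expect_equal(get_layer(cs, "Light")[2, 1], 128 / 255)

  set.seed(3)
  n <- 1000
  rgbv <- matrix(sample(0:255, 3 * n, TRUE), ncol = 3)
  cs2 <- compute_color_components(
    make_rgb(array(rgbv, dim = c(n, 1, 3))))
  # scalar textbook conversion
  for (k in sample(n, 60)) {
    r <- rgbv[k, 1] / 255; g <- rgbv[k, 2] / 255; b <- rgbv[k, 3] / 255
    mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
    hue <- if (d == 0) 0 else {
      hh <- if (mx == r) ((g - b) / d) %% 6
      else if (mx == g) (b - r) / d + 2 else (r - g) / d + 4
      hh / 6
    }
    expect_equal(get_layer(cs2, "Hue")[k, 1], hue, tolerance = 1e-9)
    expect_equal(get_layer(cs2, "Saturation")[k, 1],
                 if (mx == 0) 0 else d / mx, tolerance = 1e-9)
    expect_equal(get_layer(cs2, "Value")[k, 1], mx, tolerance = 1e-9)
    expect_equal(get_layer(cs2, "Light")[k, 1], (mx + mn) / 2, tolerance = 1e-9)
  }
})

test_that("stack assembly yields 41 named layers with a combined mask", {
  sc <- small_scene()
  full <- assemble_stack(compute_color_indices(sc$rgb),
                         compute_texture_layers(sc$rgb),
                         compute_color_components(sc$rgb),
                         dem = sc$dem)
  expect_equal(length(full$layers), 41)
  expect_equal(sum(full$category == "CI"), 12)
  expect_equal(sum(full$category == "GLCM"), 24)
  expect_equal(sum(full$category == "CS"), 4)
  expect_equal(sum(full$category == "DEM"), 1)
  # masked anywhere => masked in the assembled stack
  wi_na <- is.na(get_layer(full, "WI"))
  expect_true(all(!full$mask[wi_na]))

  expect_error(assemble_stack(compute_color_indices(sc$rgb),
                              compute_color_indices(sc$rgb)),
               "duplicate layer name")
  shifted <- generate_scene(scene_config(width = 121, height = 120,
                                         pixel_size = 1, seed = 1))
  expect_error(assemble_stack(compute_color_indices(sc$rgb),
                              dem = shifted$dem),
               "geometry mismatch")
})
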