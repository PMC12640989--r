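CS_NAMES <- c("Hue", "Light", "Saturation", "Value")

#' Compute the four HSV/HLS color components
#'
#' Hue is shared between the HSV and HLS models (identical by definition) and
#' stored once, scaled to `[0, 1)`; Light comes from HLS (`(max+min)/2`),
#' Saturation and Value from HSV. Achromatic pixels (max = min) get Hue 0 and
#' Saturation 0.
#'
#' @param rgb an [rgb_image()].
#' @return a [feature_stack()] with layers Hue, Light, Saturation, Value of
#'   category `"CS"`.
#' @export
compute_color_components <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_image"))
  h <- rgb$geom$height; w <- rgb$geom$width
  R <- band(rgb, 1); G <- band(rgb, 2); B <- band(rgb, 3)
  m <- rbind(as.vector(R), as.vector(G), as.vector(B))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  mx <- pmax(R, G, B); mn <- pmin(R, G, B)
  layers <- list(
    Hue        = matrix(hsv["h", ], h, w),
    Light      = (mx + mn) / 2 / 255,
    Saturation = matrix(hsv["s", ], h, w),
    Value      = matrix(hsv["v", ], h, w)
  )
  for (nm in names(layers)) layers[[nm]][!rgb$mask] <- NA_real_
  feature_stack(layers, stats::setNames(rep("CS", 4), CS_NAMES), rgb$geom,
                rgb$mask)
}
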