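# Visible-band color indices computed pixel-wise on 8-bit digital numbers.
# The excess-red/green/blue indices are defined on the chromatic coordinates
# (RCC/GCC/BCC); CIVE keeps its published constants, which assume DN scale.
CI_NAMES <- c("GCC", "RCC", "BCC", "GRVI", "WI", "GLI", "VARI",
              "EXR", "EXG", "EXB", "CIVE", "VDVI")

#' Compute the 12 visible-band color indices
#'
#' One float layer per index: GCC, RCC, BCC, GRVI, WI, GLI, VARI, EXR, EXG,
#' EXB, CIVE and VDVI. Pixels where an index's denominator vanishes (e.g. WI
#' with R = G, VARI with G + R = B, ratios with R + G + B = 0) are set to
#' NoData in that layer rather than infinity.
#'
#' @param rgb an [rgb_image()].
#' @return a [feature_stack()] with 12 layers of category `"CI"`.
#' @export
compute_color_indices <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_image"))
  R <- band(rgb, 1); G <- band(rgb, 2); B <- band(rgb, 3)
  R[!rgb$mask] <- NA; G[!rgb$mask] <- NA; B[!rgb$mask] <- NA
  s <- R + G + B

  safe_div <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  GCC <- safe_div(G, s); RCC <- safe_div(R, s); BCC <- safe_div(B, s)
  layers <- list(
    GCC  = GCC,
    RCC  = RCC,
    BCC  = BCC,
    GRVI = safe_div(G - R, G + R),
    WI   = safe_div(G - B, R - G),
    GLI  = safe_div(2 * G - R - B, 2 * G + R + B),
    VARI = safe_div(G - R, G + R - B),
    EXR  = 1.4 * RCC - GCC,
    EXG  = 2 * GCC - RCC - BCC,
    EXB  = 1.4 * BCC - GCC,
    CIVE = 0.441 * R - 0.881 * G + 0.385 * B + 18.78745,
    VDVI = safe_div(G - B - R, G + B + R)
  )
  feature_stack(layers, stats::setNames(rep("CI", 12), CI_NAMES)[CI_NAMES],
                rgb$geom, rgb$mask)
}
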