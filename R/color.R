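#' @title Colour-plane conversions
#' @description Per-pixel conversion of 8-bit RGB into the HSI, CIELab and
#'   CIELuv colour spaces. All CIE conversions assume sRGB encoding
#'   (IEC 61966-2-1) and the D65 reference white; no chromatic adaptation or
#'   ICC profile handling is applied, matching how consumer-camera JPEG output
#'   is normally treated in field phenotyping.
#' @name color_models
NULL

# sRGB (IEC 61966-2-1) constants, D65 reference white
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.d65_white <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

# inverse sRGB transfer function: encoded [0,1] -> linear [0,1]
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

# forward sRGB transfer function: linear [0,1] -> encoded [0,1]
srgb_encode <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

# CIE 1976 lightness helper
.f_lab <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

# flat N x 3 matrix of encoded sRGB values in [0,1] -> N x 3 XYZ (Y of white = 1)
.rgb_to_xyz <- function(rgb01) {
  srgb_decode(rgb01) %*% t(.srgb_to_xyz_matrix)
}

.xyz_to_lab <- function(xyz) {
  fx <- .f_lab(xyz[, 1] / .d65_white[["X"]])
  fy <- .f_lab(xyz[, 2] / .d65_white[["Y"]])
  fz <- .f_lab(xyz[, 3] / .d65_white[["Z"]])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.xyz_to_luv <- function(xyz) {
  wd <- .d65_white[["X"]] + 15 * .d65_white[["Y"]] + 3 * .d65_white[["Z"]]
  un <- 4 * .d65_white[["X"]] / wd
  vn <- 9 * .d65_white[["Y"]] / wd
  den <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  up <- ifelse(den > 0, 4 * xyz[, 1] / den, un)
  vp <- ifelse(den > 0, 9 * xyz[, 2] / den, vn)
  L <- 116 * .f_lab(xyz[, 2] / .d65_white[["Y"]]) - 16
  cbind(L = L, u = 13 * L * (up - un), v = 13 * L * (vp - vn))
}

.flat_rgb01 <- function(img) {
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3L)  # column j = channel j
  list(m = m / 255, h = d[1], w = d[2])
}

.plane <- function(v, h, w) matrix(v, nrow = h, ncol = w)

new_color_planes <- function(h, w, source_id) {
  structure(list(hue = NULL, saturation = NULL, intensity = NULL,
                 L = NULL, a_star = NULL, b_star = NULL,
                 u_star = NULL, v_star = NULL,
                 valid_mask = NULL, dim = c(h, w), source_id = source_id),
            class = "color_planes")
}

#' @export
print.color_planes <- function(x, ...) {
  have <- names(x)[vapply(x, function(p) is.matrix(p), logical(1))]
  cat(sprintf("<color_planes> %d x %d px, planes: %s\n",
              x$dim[1], x$dim[2], paste(have, collapse = ", ")))
  invisible(x)
}

#' Convert an RGB image to HSI colour planes
#'
#' Hue is the hexcone hue angle in degrees (red at 0, green at 120, blue at
#' 240), undefined for achromatic pixels (saturation 0), where `valid_mask`
#' is set to `FALSE`. Saturation is the hexcone saturation in `[0,1]`;
#' intensity is `mean(R, G, B) / 255` so that it stays distinct from CIELab
#' lightness in downstream summaries.
#'
#' @param img an [rgb_image()].
#' @return A `color_planes` object with `hue`, `saturation`, `intensity` and
#'   `valid_mask` populated (each an H x W matrix).
#' @examples
#' p <- rgb_to_hsi(rgb_image(array(c(0, 255, 0), c(1, 1, 3))))
#' p$hue[1, 1]  # 120
#' @export
rgb_to_hsi <- function(img) {
  img <- assert_rgb_image(img)
  f <- .flat_rgb01(img)
  hsv <- grDevices::rgb2hsv(t(f$m * 255), maxColorValue = 255)
  out <- new_color_planes(f$h, f$w, attr(img, "source_id"))
  sat <- hsv[2, ]
  hue <- hsv[1, ] * 360
  hue[sat == 0] <- NA_real_
  out$hue        <- .plane(hue, f$h, f$w)
  out$saturation <- .plane(sat, f$h, f$w)
  out$intensity  <- .plane(rowMeans(f$m), f$h, f$w)
  out$valid_mask <- .plane(sat > 0, f$h, f$w)
  out
}

#' Convert an RGB image to CIELab planes
#'
#' sRGB gamma decoding and D65 white are assumed. `L` is CIE 1976 lightness in
#' `[0,100]` for in-gamut input; `a_star` (green–red) and `b_star`
#' (blue–yellow) are on the CIE 1976 scale.
#'
#' @inheritParams rgb_to_hsi
#' @return A `color_planes` object with `L`, `a_star`, `b_star` populated.
#' @export
rgb_to_cielab <- function(img) {
  img <- assert_rgb_image(img)
  f <- .flat_rgb01(img)
  lab <- .xyz_to_lab(.rgb_to_xyz(f$m))
  out <- new_color_planes(f$h, f$w, attr(img, "source_id"))
  out$L      <- .plane(lab[, "L"], f$h, f$w)
  out$a_star <- .plane(lab[, "a"], f$h, f$w)
  out$b_star <- .plane(lab[, "b"], f$h, f$w)
  out
}

#' Convert an RGB image to CIELuv planes
#'
#' As [rgb_to_cielab()] but returning the CIE 1976 `u*`, `v*` chromatic axes
#' (u'v' formulation, D65 white).
#'
#' @inheritParams rgb_to_hsi
#' @return A `color_planes` object with `L`, `u_star`, `v_star` populated.
#' @export
rgb_to_cieluv <- function(img) {
  img <- assert_rgb_image(img)
  f <- .flat_rgb01(img)
  luv <- .xyz_to_luv(.rgb_to_xyz(f$m))
  out <- new_color_planes(f$h, f$w, attr(img, "source_id"))
  out$L      <- .plane(luv[, "L"], f$h, f$w)
  out$u_star <- .plane(luv[, "u"], f$h, f$w)
  out$v_star <- .plane(luv[, "v"], f$h, f$w)
  out
}

#' Compute all colour planes of an image at once
#'
#' Convenience wrapper populating HSI, CIELab and CIELuv planes in a single
#' `color_planes` object; this is what the plot-level index summary consumes.
#'
#' @inheritParams rgb_to_hsi
#' @return A fully populated `color_planes` object.
#' @export
color_planes <- function(img) {
  img <- assert_rgb_image(img)
  out <- rgb_to_hsi(img)
  lab <- rgb_to_cielab(img)
  luv <- rgb_to_cieluv(img)
  out$L <- lab$L
  out$a_star <- lab$a_star
  out$b_star <- lab$b_star
  out$u_star <- luv$u_star
  out$v_star <- luv$v_star
  out
}
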