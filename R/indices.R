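#' @title Plot-level RGB vegetation indices
#' @description Vegetation indices computed from one canopy image: the
#'   hue-threshold canopy-cover indices GA and GGA, the crop senescence index
#'   CSI, the broadband triangular greenness index TGI, NGRDI, and the
#'   CIE-colour-space normalized-difference indices NDLab and NDLuv.
#' @name vegetation_indices
NULL

.need_plane <- function(planes, what) {
  if (!inherits(planes, "color_planes"))
    stop("expected a `color_planes` object", call. = FALSE)
  missing <- what[!vapply(planes[what], is.matrix, logical(1))]
  if (length(missing))
    stop("colour planes not populated: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Green area (GA)
#'
#' Fraction of image pixels whose hue lies in `[60, 180)` degrees — yellow
#' through bluish green — a proxy for vegetation cover. Achromatic pixels
#' (undefined hue) count in the denominator but never as green.
#'
#' @param planes a `color_planes` object with the hue plane populated
#'   (see [rgb_to_hsi()] / [color_planes()]).
#' @param lower,upper hue bounds in degrees, closed-left/open-right interval.
#' @return Fraction in `[0, 1]`.
#' @export
green_area <- function(planes, lower = 60, upper = 180) {
  .need_plane(planes, c("hue", "valid_mask"))
  n <- prod(planes$dim)
  if (n == 0L) stop("image has no pixels", call. = FALSE)
  hue <- planes$hue
  sum(planes$valid_mask & !is.na(hue) & hue >= lower & hue < upper) / n
}

#' Greener green area (GGA)
#'
#' As [green_area()] but over the more restrictive hue range `[80, 180)`,
#' excluding yellowish-green tones of partially stressed or senescent tissue.
#'
#' @inheritParams green_area
#' @return Fraction in `[0, 1]`; always `<=` the matching GA.
#' @export
greener_green_area <- function(planes, lower = 80, upper = 180) {
  green_area(planes, lower = lower, upper = upper)
}

#' Crop senescence index (CSI)
#'
#' `CSI = 100 * (GA - GGA) / GA`: the share of the detected canopy that is
#' yellowish rather than green, in percent. When `GA = 0` there is no canopy
#' to assess and the index is undefined (`NA`), not zero.
#'
#' @param GA,GGA fractions in `[0, 1]` with `GGA <= GA`.
#' @return Percent in `[0, 100]`, or `NA` when `GA = 0`.
#' @export
crop_senescence_index <- function(GA, GGA) {
  if (any(GGA > GA + 1e-12, na.rm = TRUE))
    stop("invariant violated: GGA must not exceed GA", call. = FALSE)
  ifelse(GA > 0, 100 * (GA - GGA) / GA, NA_real_)
}

#' Triangle-area coefficients for broadband greenness
#'
#' Expands the triangle-area form
#' `A = +/- 0.5 * [(l1 - l3)(R1 - R2) - (l1 - l2)(R1 - R3)]`
#' for band centres `lambda = (l1, l2, l3)`. With the red/green/blue camera
#' bands at 670, 550 and 480 nm this yields the familiar coefficients
#' 190 (on `R670 - R550`) and 120 (on `R670 - R480`).
#'
#' @param lambda numeric length-3 vector of band-centre wavelengths (nm),
#'   ordered red, green, blue.
#' @return Named numeric vector `c(green_diff = l1 - l3, blue_diff = l1 - l2)`.
#' @export
tgi_coefficients <- function(lambda = c(670, 550, 480)) {
  stopifnot(length(lambda) == 3)
  c(green_diff = lambda[1] - lambda[3], blue_diff = lambda[1] - lambda[2])
}

#' Triangular greenness index (TGI)
#'
#' `TGI = -0.5 * [190 * (R670 - R550) - 120 * (R670 - R480)]`, with the camera
#' red, green and blue channels standing in for reflectance at 670, 550 and
#' 480 nm. "Reflectance" is the 8-bit digital number divided by 255 (no
#' radiometric calibration). By default band values are the channel means of
#' the image; `per_pixel = TRUE` evaluates the index per pixel and averages,
#' which is identical for TGI (the formula is linear in the bands).
#'
#' @param img an [rgb_image()].
#' @param lambda band-centre wavelengths (nm) for red, green, blue.
#' @param per_pixel evaluate per pixel then average instead of using channel
#'   means.
#' @return Scalar, in wavelength x reflectance units.
#' @export
tgi <- function(img, lambda = c(670, 550, 480), per_pixel = FALSE) {
  img <- assert_rgb_image(img)
  k <- tgi_coefficients(lambda)
  f <- .flat_rgb01(img)
  if (per_pixel) {
    v <- -0.5 * (k[[1]] * (f$m[, 1] - f$m[, 2]) - k[[2]] * (f$m[, 1] - f$m[, 3]))
    return(mean(v))
  }
  r <- colMeans(f$m)
  -0.5 * (k[[1]] * (r[1] - r[2]) - k[[2]] * (r[1] - r[3]))
}

#' Normalized green-red difference index (NGRDI)
#'
#' `NGRDI = (G - R) / (G + R)` on channel means scaled to `[0, 1]`. Ranges
#' over `[-1, 1]`; soil is typically negative, healthy vegetation positive.
#' Undefined (`NA`) when both bands are zero (an all-black image).
#'
#' @inheritParams tgi
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
ngrdi <- function(img, per_pixel = FALSE) {
  img <- assert_rgb_image(img)
  f <- .flat_rgb01(img)
  if (per_pixel) {
    den <- f$m[, 2] + f$m[, 1]
    v <- ifelse(den > 0, (f$m[, 2] - f$m[, 1]) / den, NA_real_)
    return(if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  r <- colMeans(f$m)
  if (r[1] + r[2] <= 0) return(NA_real_)
  unname((r[2] - r[1]) / (r[2] + r[1]))
}

# shared core for the CIE normalized-difference indices:
# per-pixel ((1 - p) - q)/((1 - p) + q) + 1 averaged over pixels with
# |denominator| >= eps, or the same expression on plane means
.nd_index <- function(p, q, per_pixel, eps) {
  if (per_pixel) {
    num <- (1 - p) - q
    den <- (1 - p) + q
    keep <- is.finite(den) & abs(den) >= eps
    if (!any(keep)) return(NA_real_)
    mean(num[keep] / den[keep]) + 1
  } else {
    pm <- mean(p); qm <- mean(q)
    den <- (1 - pm) + qm
    if (!is.finite(den) || abs(den) < eps) return(NA_real_)
    ((1 - pm) - qm) / den + 1
  }
}

#' Normalized difference CIELab index (NDLab)
#'
#' `NDLab = ((1 - a*) - b*) / ((1 - a*) + b*) + 1`. The complement of `a*`
#' makes greener vegetation (more negative `a*`) raise the index the way
#' near-infrared raises NDVI, while yellow chlorotic tissue (higher `b*`)
#' lowers it. By default the expression is evaluated per pixel and averaged,
#' excluding pixels whose denominator is within `eps` of zero;
#' `per_pixel = FALSE` evaluates it once on the plot-mean `a*`, `b*`.
#'
#' Note the formula is implemented literally: at `a* = b* = 0` it evaluates
#' to 2, and the denominator can change sign for strongly coloured soil, so
#' individual pixel values are not confined to `[-1, 1]` (see the methods
#' vignette).
#'
#' @param planes a `color_planes` object with `a_star`, `b_star` populated.
#' @param per_pixel per-pixel evaluation then averaging (default), versus
#'   evaluation on plane means.
#' @param eps exclusion guard for near-zero denominators.
#' @return Scalar, or `NA` when every pixel is excluded.
#' @export
ndlab <- function(planes, per_pixel = TRUE, eps = 1e-6) {
  .need_plane(planes, c("a_star", "b_star"))
  .nd_index(planes$a_star, planes$b_star, per_pixel, eps)
}

#' Normalized difference CIELuv index (NDLuv)
#'
#' As [ndlab()] on the CIELuv chromatic axes:
#' `NDLuv = ((1 - u*) - v*) / ((1 - u*) + v*) + 1`.
#'
#' @param planes a `color_planes` object with `u_star`, `v_star` populated.
#' @inheritParams ndlab
#' @return Scalar, or `NA` when every pixel is excluded.
#' @export
ndluv <- function(planes, per_pixel = TRUE, eps = 1e-6) {
  .need_plane(planes, c("u_star", "v_star"))
  .nd_index(planes$u_star, planes$v_star, per_pixel, eps)
}

#' Circular mean of hue angles
#'
#' Mean of unit vectors, in degrees in `[0, 360)`; the arithmetic mean of
#' angles is wrong across the 0/360 wrap.
#'
#' @param deg numeric vector of angles in degrees; `NA`s dropped.
#' @return Scalar in `[0, 360)`, or `NA` if no finite angles.
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (!length(deg)) return(NA_real_)
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (m + 360) %% 360
}

#' Summarize one plot image into a row of index values
#'
#' Computes every plot-level variable from a single canopy image: GA, GGA,
#' CSI, circular mean hue, mean intensity/saturation/lightness, mean `a*`,
#' `b*`, `u*`, `v*`, NDLab, NDLuv, TGI and NGRDI.
#'
#' @param img an [rgb_image()] (or a file path readable by
#'   [read_rgb_image()]).
#' @param plot_id identifier written into the record; defaults to the image's
#'   `source_id`.
#' @param nd_per_pixel per-pixel (default) vs plane-mean evaluation of
#'   NDLab/NDLuv.
#' @param nd_eps denominator guard for NDLab/NDLuv.
#' @return A one-row `data.frame` (a plot index record) with columns
#'   `plot_id`, `GA`, `GGA`, `CSI`, `hue`, `intensity`, `saturation`,
#'   `lightness`, `a_star`, `b_star`, `u_star`, `v_star`, `NDLab`, `NDLuv`,
#'   `TGI`, `NGRDI`.
#' @export
summarize_plot <- function(img, plot_id = NULL, nd_per_pixel = TRUE,
                           nd_eps = 1e-6) {
  if (is.character(img)) img <- read_rgb_image(img)
  img <- assert_rgb_image(img)
  if (is.null(plot_id)) plot_id <- attr(img, "source_id")
  pl <- color_planes(img)
  ga  <- green_area(pl)
  gga <- greener_green_area(pl)
  data.frame(
    plot_id    = as.character(plot_id),
    GA         = ga,
    GGA        = gga,
    CSI        = crop_senescence_index(ga, gga),
    hue        = circular_mean_deg(pl$hue[pl$valid_mask]),
    intensity  = mean(pl$intensity),
    saturation = mean(pl$saturation),
    lightness  = mean(pl$L),
    a_star     = mean(pl$a_star),
    b_star     = mean(pl$b_star),
    u_star     = mean(pl$u_star),
    v_star     = mean(pl$v_star),
    NDLab      = ndlab(pl, per_pixel = nd_per_pixel, eps = nd_eps),
    NDLuv      = ndluv(pl, per_pixel = nd_per_pixel, eps = nd_eps),
    TGI        = tgi(img),
    NGRDI      = ngrdi(img),
    stringsAsFactors = FALSE
  )
}
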