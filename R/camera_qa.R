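#' @title Camera quality assurance
#' @description Colour-calibration check against a 24-chip reference chart
#'   and vignetting assessment via centre transects with hue-based soil
#'   filtering.
#' @name camera_qa
NULL

#' Nominal 24-chip colour reference table
#'
#' Loads the packaged nominal sRGB values of the classic 24-patch colour
#' reference chart together with CIELab values derived from them under D65
#' (see the file header of
#' `system.file("extdata", "colorchecker_reference.csv", package = "phenorgb")`
#' for provenance). The calibration regression is invariant to affine
#' re-specification of the reference, so any published edition of the chart
#' may be substituted via the `path` argument.
#'
#' @param path optional CSV with columns
#'   `chip_id, name, R, G, B, L, a_star, b_star`.
#' @return A 24-row `data.frame`.
#' @export
colorchecker_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "colorchecker_reference.csv",
                        package = "phenorgb")
  ref <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chip_id", "R", "G", "B", "L", "a_star", "b_star")
  miss <- setdiff(need, names(ref))
  if (length(miss))
    stop("reference table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ref$chip_id) || nrow(ref) != 24L)
    stop("reference table must contain 24 unique chips", call. = FALSE)
  ref
}

#' Measure chart chips from an image
#'
#' Extracts one colour tuple per chip as the per-channel median over the
#' chip's ROI rectangle (median for robustness to specular pixels), plus the
#' CIELab values of that median colour.
#'
#' @param img an [rgb_image()] of the chart.
#' @param chip_rois `data.frame` with columns `chip_id, x0, y0, x1, y1`
#'   (0-based half-open rectangles).
#' @return `data.frame` with `chip_id, R, G, B, L, a_star, b_star`.
#' @export
measure_chips <- function(img, chip_rois) {
  img <- assert_rgb_image(img)
  chip_rois$plot_id <- chip_rois$chip_id
  crops <- crop_plots(img, chip_rois)
  rows <- lapply(seq_along(crops), function(i) {
    px <- unclass(crops[[i]])
    med <- apply(matrix(px, ncol = 3), 2, stats::median)
    lab <- .xyz_to_lab(.rgb_to_xyz(matrix(med / 255, 1)))
    data.frame(chip_id = chip_rois$chip_id[i], R = med[1], G = med[2],
               B = med[3], L = lab[1, "L"], a_star = lab[1, "a"],
               b_star = lab[1, "b"])
  })
  do.call(rbind, rows)
}

#' Colour-calibration check against the 24-chip reference
#'
#' Ordinary least-squares regression of measured chip values on the published
#' reference values, per channel (R, G, B, L, a*, b*). Channels with
#' R-squared below `r2_flag` are flagged as poorly calibrated. If the
#' measured table lacks `L`/`a_star`/`b_star` they are derived from its RGB
#' columns.
#'
#' @param measured `data.frame` with `chip_id, R, G, B` (optionally
#'   `L, a_star, b_star`), e.g. from [measure_chips()].
#' @param reference reference table, default [colorchecker_reference()].
#' @param r2_flag R-squared threshold below which a channel is flagged.
#' @return A `calibration_report`: `data.frame` with one row per channel and
#'   columns `channel, slope, intercept, r_squared, flagged`.
#' @export
color_check <- function(measured, reference = colorchecker_reference(),
                        r2_flag = 0.80) {
  if (!all(c("chip_id", "R", "G", "B") %in% names(measured)))
    stop("`measured` needs columns chip_id, R, G, B", call. = FALSE)
  miss <- setdiff(reference$chip_id, measured$chip_id)
  if (length(miss))
    stop("missing measured chips: ", paste(miss, collapse = ", "),
         call. = FALSE)
  measured <- measured[match(reference$chip_id, measured$chip_id), ]
  if (!all(c("L", "a_star", "b_star") %in% names(measured))) {
    lab <- .xyz_to_lab(.rgb_to_xyz(cbind(measured$R, measured$G,
                                         measured$B) / 255))
    measured$L <- lab[, "L"]
    measured$a_star <- lab[, "a"]
    measured$b_star <- lab[, "b"]
  }
  channels <- c("R", "G", "B", "L", "a_star", "b_star")
  rows <- lapply(channels, function(ch) {
    fit <- stats::lm(measured[[ch]] ~ reference[[ch]])
    s <- summary(fit)
    data.frame(channel = ch,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = s$r.squared,
               flagged = s$r.squared < r2_flag)
  })
  structure(do.call(rbind, rows), class = c("calibration_report",
                                            "data.frame"))
}

#' Apply a per-channel linear colour correction (opt-in)
#'
#' Maps measured values back onto the reference scale using the slopes and
#' intercepts of a [color_check()] report:
#' `corrected = (measured - intercept) / slope`, per RGB channel. Reporting
#' calibration quality without correcting is the default workflow — applying
#' correction coefficients from a single chart photo can degrade index
#' performance — so this is never applied implicitly.
#'
#' @param img an [rgb_image()].
#' @param report a `calibration_report` from [color_check()].
#' @return A corrected [rgb_image()] (values clipped to `[0, 255]`).
#' @export
apply_color_correction <- function(img, report) {
  img <- assert_rgb_image(img)
  px <- unclass(img) * 1.0
  for (i in 1:3) {
    ch <- c("R", "G", "B")[i]
    row <- report[report$channel == ch, ]
    px[, , i] <- (px[, , i] - row$intercept) / row$slope
  }
  rgb_image(pmin(pmax(px, 0), 255), source_id = attr(img, "source_id"))
}

#' Vignetting assessment via centre transects
#'
#' Extracts the central-row (x axis) and central-column (y axis) transects of
#' the R, G, B, hue, a* and b* planes, restricted to sunlit-soil pixels
#' selected with a hue-based filter: hue outside the vegetation range
#' `[veg_hue[1], veg_hue[2])` (or undefined), saturation above `sat_min` and
#' intensity above `int_min` (excluding shadow). Radial lens falloff shows up
#' as a brightness dip towards both ends of the R/G/B transects, while the
#' lightness-separated a*/b* transects stay comparatively flat.
#'
#' @param img an [rgb_image()].
#' @param veg_hue hue range (degrees) regarded as vegetation and excluded.
#' @param sat_min,int_min saturation / intensity floor for "sunlit soil".
#' @return List with `x` and `y` transect `data.frame`s (columns `pos, R, G,
#'   B, hue, a_star, b_star`, soil pixels only), and `soil_mask` (H x W
#'   logical). Empty transects (no soil pixels on the line) emit a warning.
#' @export
vignetting_transects <- function(img, veg_hue = c(60, 180), sat_min = 0.1,
                                 int_min = 0.2) {
  img <- assert_rgb_image(img)
  pl <- color_planes(img)
  hue <- pl$hue
  non_veg <- !pl$valid_mask | is.na(hue) | hue < veg_hue[1] | hue >= veg_hue[2]
  soil <- non_veg & pl$saturation > sat_min & pl$intensity > int_min
  d <- dim(img)
  ry <- (d[1] + 1L) %/% 2L  # central row    -> x-axis transect
  cx <- (d[2] + 1L) %/% 2L  # central column -> y-axis transect
  px <- unclass(img)
  take <- function(idx_keep, pos, R, G, B, H, A, Bst) {
    data.frame(pos = pos[idx_keep], R = R[idx_keep], G = G[idx_keep],
               B = B[idx_keep], hue = H[idx_keep], a_star = A[idx_keep],
               b_star = Bst[idx_keep])
  }
  x_tr <- take(which(soil[ry, ]), seq_len(d[2]), px[ry, , 1], px[ry, , 2],
               px[ry, , 3], hue[ry, ], pl$a_star[ry, ], pl$b_star[ry, ])
  y_tr <- take(which(soil[, cx]), seq_len(d[1]), px[, cx, 1], px[, cx, 2],
               px[, cx, 3], hue[, cx], pl$a_star[, cx], pl$b_star[, cx])
  if (nrow(x_tr) == 0L || nrow(y_tr) == 0L)
    warning("no pixels passed the soil filter on a centre transect",
            call. = FALSE)
  list(x = x_tr, y = y_tr, soil_mask = soil)
}

#' Ground sample distance of a camera at altitude
#'
#' Physical footprint of one pixel on the ground:
#' `GSD = sensor_width * altitude / (focal_length * image_width)`. A 4/3"
#' sensor 17.3 mm wide at 4592 px, a 20 mm lens and 50 m altitude give
#' 0.9419 cm/pixel.
#'
#' @param sensor_width_mm physical sensor width (mm).
#' @param image_width_px image width (pixels).
#' @param focal_length_mm lens focal length (mm).
#' @param altitude_m camera height above ground (m).
#' @return GSD in cm/pixel.
#' @export
ground_sample_distance <- function(sensor_width_mm, image_width_px,
                                   focal_length_mm, altitude_m) {
  stopifnot(sensor_width_mm > 0, image_width_px > 0, focal_length_mm > 0,
            altitude_m > 0)
  sensor_width_mm * altitude_m * 100 / (focal_length_mm * image_width_px)
}
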