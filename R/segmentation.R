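#' @title Plot segmentation
#' @description Crop per-plot micro-images out of an orthomosaic using a
#'   table of axis-aligned rectangular regions of interest, and batch-index
#'   lists of plot images.
#' @name plot_segmentation
NULL

#' Read a plot-ROI table from CSV
#'
#' Expected columns: `plot_id, x0, y0, x1, y1` and optionally
#' `genotype, replicate, treatment`. Coordinates are 0-based, half-open
#' pixel rectangles `[x0, x1) x [y0, y1)` (x = column, y = row).
#'
#' @param path CSV file path.
#' @return A `data.frame` of ROIs.
#' @export
read_plot_rois <- function(path) {
  rois <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rois(rois)
  rois
}

validate_rois <- function(rois, mosaic_dim = NULL) {
  need <- c("plot_id", "x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(rois))
  if (length(miss))
    stop("ROI table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rois$plot_id)) {
    dup <- unique(rois$plot_id[duplicated(rois$plot_id)])
    stop("duplicate plot_id in ROI table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- rois$x1 <= rois$x0 | rois$y1 <= rois$y0
  if (any(bad))
    stop("degenerate ROI (x1 <= x0 or y1 <= y0) for plot_id: ",
         paste(rois$plot_id[bad], collapse = ", "), call. = FALSE)
  if (!is.null(mosaic_dim)) {
    h <- mosaic_dim[1]; w <- mosaic_dim[2]
    oob <- rois$x0 < 0 | rois$y0 < 0 | rois$x1 > w | rois$y1 > h
    if (any(oob))
      stop("ROI outside mosaic bounds for plot_id: ",
           paste(rois$plot_id[oob], collapse = ", "), call. = FALSE)
  }
  invisible(rois)
}

#' Crop per-plot micro-images from a mosaic
#'
#' Pixel-exact crops of each ROI rectangle, one micro-image per plot, in the
#' order of the ROI table.
#'
#' @param mosaic an [rgb_image()].
#' @param rois a `data.frame` as returned by [read_plot_rois()].
#' @return Named list of [rgb_image()]s, names = `plot_id`.
#' @export
crop_plots <- function(mosaic, rois) {
  mosaic <- assert_rgb_image(mosaic)
  validate_rois(rois, mosaic_dim = dim(mosaic))
  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    # 0-based half-open -> 1-based inclusive R indexing
    px <- unclass(mosaic)[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1, , drop = FALSE]
    out[[i]] <- rgb_image(px, source_id = r$plot_id)
  }
  names(out) <- rois$plot_id
  out
}

#' Batch-compute plot index records
#'
#' Runs [summarize_plot()] over a list of plot images (or image file paths).
#' A failure on one plot is recorded (`ok = FALSE`, message in `error`) and
#' does not abort the batch.
#'
#' @param images named list of [rgb_image()]s or file paths; names are used
#'   as `plot_id` when present.
#' @param ... passed to [summarize_plot()].
#' @return A `data.frame` with one row per input: all [summarize_plot()]
#'   columns plus `ok` (logical) and `error` (message or `NA`).
#' @export
batch_index <- function(images, ...) {
  if (!length(images)) stop("empty image list", call. = FALSE)
  ids <- names(images)
  if (is.null(ids)) ids <- rep(NA_character_, length(images))
  rows <- lapply(seq_along(images), function(i) {
    id <- ids[i]
    res <- tryCatch({
      rec <- summarize_plot(images[[i]],
                            plot_id = if (!is.na(id) && nzchar(id)) id else NULL,
                            ...)
      rec$ok <- TRUE
      rec$error <- NA_character_
      rec
    }, error = function(e) {
      rec <- empty_index_record(if (!is.na(id)) id else sprintf("image_%d", i))
      rec$ok <- FALSE
      rec$error <- conditionMessage(e)
      rec
    })
    res
  })
  do.call(rbind, rows)
}

empty_index_record <- function(plot_id) {
  data.frame(plot_id = as.character(plot_id), GA = NA_real_, GGA = NA_real_,
             CSI = NA_real_, hue = NA_real_, intensity = NA_real_,
             saturation = NA_real_, lightness = NA_real_, a_star = NA_real_,
             b_star = NA_real_, u_star = NA_real_, v_star = NA_real_,
             NDLab = NA_real_, NDLuv = NA_real_, TGI = NA_real_,
             NGRDI = NA_real_, stringsAsFactors = FALSE)
}

#' Write plot index records to CSV
#'
#' One row per plot; missing values are written as empty cells.
#'
#' @param records `data.frame` from [batch_index()] / [summarize_plot()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
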