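#' @title End-to-end pipeline
#' @description One-call workflow: crop plots from a mosaic, compute plot
#'   index records, join the trial table, and emit correlation, quartile,
#'   overlap and model report CSVs. Outputs are a pure function of
#'   (inputs, config, seed).
#' @name cli_app
NULL

#' Pipeline run configuration
#'
#' Central place for every tunable constant, validated on construction.
#'
#' @param ga_hue_low,gga_hue_low,ga_hue_high hue thresholds (degrees) for GA
#'   and GGA; must satisfy `ga_hue_low < gga_hue_low < ga_hue_high`.
#' @param nd_per_pixel,nd_eps NDLab/NDLuv evaluation mode and denominator
#'   guard.
#' @param soil_sat_min,soil_int_min soil-filter floors for the vignetting
#'   transects.
#' @param collinearity collinearity threshold for [simplify_model()].
#' @param alpha significance level, in `(0, 1)`.
#' @param area_m2 harvested plot area for [grain_yield()].
#' @param seed integer seed for any stochastic step.
#' @return A validated `run_config` list.
#' @export
run_config <- function(ga_hue_low = 60, gga_hue_low = 80, ga_hue_high = 180,
                       nd_per_pixel = TRUE, nd_eps = 1e-6,
                       soil_sat_min = 0.1, soil_int_min = 0.2,
                       collinearity = 0.7, alpha = 0.05, area_m2 = 5.25,
                       seed = 1L) {
  if (!(ga_hue_low < gga_hue_low && gga_hue_low < ga_hue_high))
    stop("hue thresholds must satisfy ga_hue_low < gga_hue_low < ga_hue_high",
         call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (area_m2 <= 0) stop("area_m2 must be positive", call. = FALSE)
  structure(list(ga_hue_low = ga_hue_low, gga_hue_low = gga_hue_low,
                 ga_hue_high = ga_hue_high, nd_per_pixel = nd_per_pixel,
                 nd_eps = nd_eps, soil_sat_min = soil_sat_min,
                 soil_int_min = soil_int_min, collinearity = collinearity,
                 alpha = alpha, area_m2 = area_m2, seed = as.integer(seed)),
            class = "run_config")
}

# plot summary honouring configured hue thresholds
.summarize_with_config <- function(img, plot_id, config) {
  rec <- summarize_plot(img, plot_id = plot_id,
                        nd_per_pixel = config$nd_per_pixel,
                        nd_eps = config$nd_eps)
  pl <- rgb_to_hsi(img)
  rec$GA <- green_area(pl, config$ga_hue_low, config$ga_hue_high)
  rec$GGA <- green_area(pl, config$gga_hue_low, config$ga_hue_high)
  rec$CSI <- crop_senescence_index(rec$GA, rec$GGA)
  rec
}

#' Run the full plot-to-model workflow
#'
#' Crops every ROI out of the mosaic, computes one plot index record per
#' plot, joins the trial table by `plot_id`, then produces the standard
#' trial outputs: index-vs-yield correlations (in the LOW treatment when a
#' treatment column is present), the genotype yield summary with quartile
#' groups, the cross-treatment group overlap, and a stepwise model report
#' (full and simplified). When `outdir` is given, each table is written as a
#' CSV (`plot_indices.csv`, `correlations.csv`, `yield_summary.csv`,
#' `group_overlap.csv`, `models.csv`).
#'
#' @param mosaic an [rgb_image()] or path to one.
#' @param rois ROI `data.frame` or CSV path (see [read_plot_rois()]).
#' @param trial trial `data.frame` or CSV path; must carry `plot_id`,
#'   `genotype`, `treatment` and either `GY` or `grain_weight`.
#' @param outdir optional output directory for CSVs.
#' @param config a [run_config()].
#' @param model_predictors predictor columns for the stepwise model; default
#'   agronomic data plus the image indices.
#' @return List with `records`, `joined`, `correlations`, `yield_summary`,
#'   `overlap`, `models` (and `fits`).
#' @export
run_pipeline <- function(mosaic, rois, trial, outdir = NULL,
                         config = run_config(),
                         model_predictors = NULL) {
  if (is.character(mosaic)) mosaic <- read_rgb_image(mosaic)
  if (is.character(rois)) rois <- read_plot_rois(rois)
  if (is.character(trial)) trial <- utils::read.csv(trial,
                                                    stringsAsFactors = FALSE)
  if (!"GY" %in% names(trial)) {
    if (!"grain_weight" %in% names(trial))
      stop("trial table needs a GY or grain_weight column", call. = FALSE)
    trial$GY <- grain_yield(trial$grain_weight, config$area_m2)
  }
  set.seed(config$seed)
  crops <- crop_plots(mosaic, rois)
  records <- do.call(rbind, lapply(names(crops), function(id)
    .summarize_with_config(crops[[id]], id, config)))
  joined <- merge(trial, records, by = "plot_id", sort = TRUE)
  low <- if ("treatment" %in% names(joined))
    joined[joined$treatment == "LOW", ] else joined
  if (!nrow(low)) low <- joined
  index_vars <- c("GA", "GGA", "CSI", "hue", "intensity", "saturation",
                  "lightness", "a_star", "b_star", "u_star", "v_star",
                  "NDLab", "NDLuv", "TGI", "NGRDI")
  correlations <- correlate_yield(low, vars = index_vars)
  ys <- if ("treatment" %in% names(trial) &&
            all(c("LOW", "OP") %in% trial$treatment))
    yield_summary(trial) else NULL
  overlap <- if (!is.null(ys)) {
    pct <- group_overlap(ys$groups_op, ys$groups_low)
    data.frame(group = names(pct), overlap_pct = as.integer(pct),
               shared = attr(pct, "shared"))
  } else NULL
  if (is.null(model_predictors))
    model_predictors <- intersect(c("ASI", "AD", "SEN", "PH", "GA", "GGA",
                                    "CSI", "hue", "NDLab", "NDLuv"),
                                  names(low))
  fits <- NULL
  models <- NULL
  if (length(model_predictors) >= 2 &&
      nrow(low) >= length(model_predictors) + 10) {
    full <- stepwise_fit(low, model_predictors, direction = "forward",
                         label = "agronomy + image indices")
    simp <- simplify_model(full, alpha = config$alpha,
                           collinearity = config$collinearity)
    fits <- list(full = full, simplified = simp)
    models <- model_report(fits)
  }
  out <- list(records = records, joined = joined,
              correlations = correlations,
              yield_summary = if (!is.null(ys)) ys$summary else NULL,
              overlap = overlap, models = models, fits = fits)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(outdir, f), row.names = FALSE, na = "")
    w(records, "plot_indices.csv")
    w(correlations, "correlations.csv")
    w(out$yield_summary, "yield_summary.csv")
    w(overlap, "group_overlap.csv")
    w(models, "models.csv")
  }
  out
}
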