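#' @title Synthetic canopy scenes and trials
#' @description Seeded generators for canopy images (soil background, green
#'   and chlorotic vegetation blobs, optional cos^4 vignetting) with
#'   ground-truth masks, and for two-treatment maize trial tables with known
#'   generative parameters. Every module of the package is testable against
#'   these ground truths without field data.
#' @name synthetic_scenes
NULL

#' Specification of a synthetic canopy scene
#'
#' Class colours are base 8-bit RGB triplets with truncated-Gaussian
#' per-pixel jitter (clamped at two sigma so each class provably stays inside
#' its hue band: soil below 60 degrees, chlorotic vegetation in `[60, 80)`,
#' green vegetation in `[80, 180)`). Vegetation is placed as seeded
#' elliptical Gaussian blobs thresholded at the exact class fraction, so that
#' green area at aerial-like downsampling behaves like a real canopy rather
#' than per-pixel noise.
#'
#' @param width,height scene size in pixels.
#' @param veg_fraction programmed vegetation fraction in `[0, 1]`.
#' @param chlorotic_share share of the vegetation rendered yellow-green
#'   (hue 60-80 degrees) in `[0, 1]`.
#' @param soil_color,green_color,chlorotic_color base RGB triplets.
#' @param soil_jitter,green_jitter,chlorotic_jitter per-channel jitter sigma
#'   (DN).
#' @param vignetting_strength relative corner falloff in `[0, 1)` of a cos^4
#'   radial model applied multiplicatively in linear RGB (0 = none).
#' @param blob_scale blob radius scale as a fraction of the smaller image
#'   dimension.
#' @param seed integer seed; same seed, same scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 160, height = 120, veg_fraction = 0.35,
                       chlorotic_share = 0.2,
                       soil_color = c(130, 90, 60),
                       green_color = c(70, 150, 60),
                       chlorotic_color = c(140, 160, 40),
                       soil_jitter = 8, green_jitter = 8, chlorotic_jitter = 4,
                       vignetting_strength = 0, blob_scale = 0.15,
                       seed = 1L) {
  stopifnot(width >= 1, height >= 1,
            veg_fraction >= 0, veg_fraction <= 1,
            chlorotic_share >= 0, chlorotic_share <= 1,
            vignetting_strength >= 0, vignetting_strength < 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 veg_fraction = veg_fraction,
                 chlorotic_share = chlorotic_share,
                 soil_color = soil_color, green_color = green_color,
                 chlorotic_color = chlorotic_color,
                 soil_jitter = soil_jitter, green_jitter = green_jitter,
                 chlorotic_jitter = chlorotic_jitter,
                 vignetting_strength = vignetting_strength,
                 blob_scale = blob_scale, seed = as.integer(seed)),
            class = "scene_spec")
}

# truncated-at-2-sigma Gaussian jitter, keeps class colours in-band
.trunc_jitter <- function(n, sigma) {
  pmin(pmax(stats::rnorm(n, 0, sigma), -2 * sigma), 2 * sigma)
}

# smooth blob field: sum of seeded elliptical Gaussians plus a whisper of
# noise so quantile thresholding has no ties
.blob_field <- function(h, w, blob_scale) {
  n_blob <- max(4L, round(h * w / 2500))
  cx <- stats::runif(n_blob, 1, w)
  cy <- stats::runif(n_blob, 1, h)
  sx <- stats::runif(n_blob, 0.5, 1.5) * blob_scale * min(h, w)
  sy <- stats::runif(n_blob, 0.5, 1.5) * blob_scale * min(h, w)
  th <- stats::runif(n_blob, 0, pi)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  fld <- matrix(0, h, w)
  for (b in seq_len(n_blob)) {
    dx <- (xs - cx[b]) * cos(th[b]) + (ys - cy[b]) * sin(th[b])
    dy <- -(xs - cx[b]) * sin(th[b]) + (ys - cy[b]) * cos(th[b])
    fld <- fld + exp(-(dx^2 / (2 * sx[b]^2) + dy^2 / (2 * sy[b]^2)))
  }
  fld + matrix(stats::rnorm(h * w, 0, 1e-6), h, w)
}

# exact-count mask of the m largest field values
.top_mask <- function(field, m) {
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (m > 0) mask[order(field, decreasing = TRUE)[seq_len(m)]] <- TRUE
  mask
}

#' Render a synthetic canopy scene
#'
#' Produces an 8-bit RGB canopy image together with its ground-truth
#' vegetation mask, chlorotic mask (a subset of the vegetation mask) and the
#' applied vignetting field. Class pixel counts equal
#' `round(fraction * n_pixels)` exactly by construction; vignetting, when
#' requested, multiplies linear RGB by `cos(theta)^4` with the corner
#' attenuated to `1 - vignetting_strength`.
#'
#' @param spec a [scene_spec()].
#' @return A `canopy_scene` list: `image` ([rgb_image()]), `veg_mask`,
#'   `chlorotic_mask` (logical H x W), `vignette_field` (numeric H x W),
#'   `spec`, and `hue_bands` (the programmed per-class hue bands).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  n <- h * w
  if (n == 0L) stop("zero-area scene", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_veg <- round(spec$veg_fraction * n)
  veg <- .top_mask(.blob_field(h, w, spec$blob_scale), n_veg)
  n_chl <- round(spec$chlorotic_share * n_veg)
  chl_field <- .blob_field(h, w, spec$blob_scale)
  chl_field[!veg] <- -Inf
  chl <- .top_mask(chl_field, n_chl)

  px <- array(0, c(h, w, 3))
  fill <- function(px, mask, base, sigma) {
    m <- sum(mask)
    if (m == 0) return(px)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- base[ch] + .trunc_jitter(m, sigma)
      px[, , ch] <- plane
    }
    px
  }
  px <- fill(px, !veg, spec$soil_color, spec$soil_jitter)
  px <- fill(px, veg & !chl, spec$green_color, spec$green_jitter)
  px <- fill(px, chl, spec$chlorotic_color, spec$chlorotic_jitter)
  px <- pmin(pmax(px, 0), 255)

  vig <- matrix(1, h, w)
  if (spec$vignetting_strength > 0) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    r <- sqrt((matrix(rep(seq_len(h), w), h, w) - cy)^2 +
              (matrix(rep(seq_len(w), each = h), h, w) - cx)^2)
    rmax <- sqrt((h - cy)^2 + (w - cx)^2)
    theta_max <- acos((1 - spec$vignetting_strength)^(1 / 4))
    vig <- cos(r / rmax * theta_max)^4
    for (ch in 1:3)
      px[, , ch] <- 255 * srgb_encode(srgb_decode(px[, , ch] / 255) * vig)
  }

  list(image = rgb_image(px, source_id = sprintf("scene_seed%d", spec$seed)),
       veg_mask = veg, chlorotic_mask = chl, vignette_field = vig,
       spec = spec,
       hue_bands = list(green = c(80, 180), chlorotic = c(60, 80),
                        soil_excludes = c(60, 180)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic two-treatment maize trial
#'
#' Defaults emulate a 64-genotype, 3-replicate low-N/optimal-N maize trial:
#' genotype yield effects are bivariate normal across the two treatments
#' with correlation `genotype_cor`; treatment means and genotype standard
#' deviations default to 2.93 +/- 0.58 Mg/ha (LOW) and 9.62 +/- 1.24 Mg/ha
#' (OP). Under LOW, anthesis date and anthesis-silking interval are linked
#' negatively to the genotype yield effect, senescence negatively, plant
#' height and the sensor/index columns positively; under OP the phenology
#' links are switched off.
#'
#' @param n_genotypes,n_reps trial dimensions.
#' @param gy_mean,gy_genotype_sd,gy_resid_sd named numeric (`LOW`, `OP`):
#'   treatment mean yield, genotype-effect SD and plot residual SD (Mg/ha).
#' @param genotype_cor correlation of genotype effects across treatments,
#'   in `[-1, 1]`.
#' @param seed integer seed.
#' @return A `trial_spec` list (the `coef` element records every generative
#'   link so recovery tests can compare against truth).
#' @export
trial_spec <- function(n_genotypes = 64, n_reps = 3,
                       gy_mean = c(LOW = 2.93, OP = 9.62),
                       gy_genotype_sd = c(LOW = 0.58, OP = 1.24),
                       gy_resid_sd = c(LOW = 0.25, OP = 0.45),
                       genotype_cor = 0.55, seed = 1L) {
  stopifnot(n_genotypes >= 4, n_reps >= 1,
            all(gy_genotype_sd > 0), all(gy_resid_sd >= 0),
            genotype_cor >= -1, genotype_cor <= 1)
  coef <- list(
    AD  = list(LOW = c(base = 68, z = -2.2, noise = 1.5),
               OP  = c(base = 66, z = 0,    noise = 1.5)),
    ASI = list(LOW = c(base = 2.5, z = -1.0, noise = 0.8),
               OP  = c(base = 1.0, z = 0,    noise = 0.8)),
    PH  = list(LOW = c(base = 165, z = 6, noise = 8),
               OP  = c(base = 185, z = 6, noise = 8)),
    SEN = list(LOW = c(logit_base = qlogis(0.25), z = -0.5, noise = 0.4),
               OP  = c(logit_base = qlogis(0.08), z = 0,    noise = 0.4)),
    NDVI   = list(LOW = c(base = 0.62, z = 0.04, noise = 0.03),
                  OP  = c(base = 0.75, z = 0.02, noise = 0.03)),
    SPAD_V = list(LOW = c(base = 42, z = 3.5, noise = 2.5),
                  OP  = c(base = 52, z = 2.0, noise = 2.5)),
    SPAD_R = list(LOW = c(base = 38, z = 3.0, noise = 3.0),
                  OP  = c(base = 50, z = 2.0, noise = 3.0)),
    # plot-level index columns: intercept + slope * GY + noise
    NDLab_ground = c(base = 0.30, gy = 0.080, noise = 0.10),
    GGA_ground   = c(base = 0.12, gy = 0.050, noise = 0.07))
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_reps = as.integer(n_reps), gy_mean = gy_mean,
                 gy_genotype_sd = gy_genotype_sd, gy_resid_sd = gy_resid_sd,
                 genotype_cor = genotype_cor, coef = coef,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Simulate a two-treatment trial table
#'
#' @param spec a [trial_spec()].
#' @return List with `trial` (plot-level `data.frame`: `plot_id, genotype,
#'   replicate, treatment, grain_weight, GY, AD, SD, ASI, PH, GC, YC, DC,
#'   SEN, NDVI, SPAD_V, SPAD_R, NDLab_ground, GGA_ground`) and `truth`
#'   (genotype effects and generative parameters).
#' @export
simulate_trial <- function(spec = trial_spec()) {
  stopifnot(inherits(spec, "trial_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  ng <- spec$n_genotypes
  geno <- sprintf("G%03d", seq_len(ng))
  # bivariate standard-normal genotype effects
  z1 <- stats::rnorm(ng)
  z2 <- spec$genotype_cor * z1 +
    sqrt(max(0, 1 - spec$genotype_cor^2)) * stats::rnorm(ng)
  z <- list(OP = z1, LOW = z2)
  rows <- list()
  for (tr in c("LOW", "OP")) {
    g_eff <- spec$gy_mean[[tr]] + spec$gy_genotype_sd[[tr]] * z[[tr]]
    for (rep_i in seq_len(spec$n_reps)) {
      gy <- pmax(0.05, g_eff + stats::rnorm(ng, 0, spec$gy_resid_sd[[tr]]))
      cf <- function(nm) spec$coef[[nm]][[tr]]
      lin <- function(p) p[["base"]] + p[["z"]] * z[[tr]] +
        stats::rnorm(ng, 0, p[["noise"]])
      ad  <- lin(cf("AD"))
      asi_v <- lin(cf("ASI"))
      ph  <- pmax(60, lin(cf("PH")))
      sen_p <- cf("SEN")
      sen <- stats::plogis(sen_p[["logit_base"]] + sen_p[["z"]] * z[[tr]] +
                           stats::rnorm(ng, 0, sen_p[["noise"]]))
      cover <- pmin(pmax(stats::rnorm(ng, 0.85, 0.05), 0.5), 1)
      ndvi <- pmin(pmax(lin(cf("NDVI")), 0.2), 0.95)
      ndlab_p <- spec$coef$NDLab_ground
      gga_p <- spec$coef$GGA_ground
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = sprintf("%s_R%d_%s", geno, rep_i, tr),
        genotype = geno, replicate = rep_i, treatment = tr,
        grain_weight = gy * 5.25 / 10, GY = gy,
        AD = ad, SD = ad + asi_v, ASI = asi_v, PH = ph,
        GC = cover * (1 - sen), YC = cover * sen * 0.6,
        DC = cover * sen * 0.4, SEN = sen,
        NDVI = ndvi,
        SPAD_V = pmax(10, lin(cf("SPAD_V"))),
        SPAD_R = pmax(10, lin(cf("SPAD_R"))),
        NDLab_ground = ndlab_p[["base"]] + ndlab_p[["gy"]] * gy +
          stats::rnorm(ng, 0, ndlab_p[["noise"]]),
        GGA_ground = pmin(pmax(gga_p[["base"]] + gga_p[["gy"]] * gy +
          stats::rnorm(ng, 0, gga_p[["noise"]]), 0), 1),
        stringsAsFactors = FALSE)
    }
  }
  trial <- do.call(rbind, rows)
  rownames(trial) <- NULL
  list(trial = trial,
       truth = list(genotype = geno, z_op = z1, z_low = z2,
                    genotype_gy = data.frame(
                      genotype = geno,
                      GY_LOW = spec$gy_mean[["LOW"]] +
                        spec$gy_genotype_sd[["LOW"]] * z2,
                      GY_OP = spec$gy_mean[["OP"]] +
                        spec$gy_genotype_sd[["OP"]] * z1),
                    coef = spec$coef),
       spec = spec)
}

#' Render a synthetic orthomosaic for a trial
#'
#' Lays one synthetic canopy scene per plot out on a rectangular grid,
#' linking each plot's vegetation fraction and chlorotic share to its yield
#' and senescence, and returns the mosaic plus a matching plot-ROI table
#' (0-based half-open rectangles).
#'
#' @param trial plot-level trial `data.frame` (needs `plot_id, genotype,
#'   replicate, treatment, GY, SEN`), e.g. one treatment's rows from
#'   [simulate_trial()].
#' @param plot_px size of each square plot micro-image in pixels.
#' @param veg_base,veg_per_gy linear link from GY (Mg/ha) to vegetation
#'   fraction (clamped to `[0.02, 0.95]`).
#' @param seed integer seed.
#' @return List with `mosaic` ([rgb_image()]), `rois` (`data.frame`), and
#'   `scenes` (the per-plot `canopy_scene`s, for ground truth).
#' @export
render_mosaic <- function(trial, plot_px = 48, veg_base = 0.10,
                          veg_per_gy = 0.06, seed = 1L) {
  n <- nrow(trial)
  if (!n) stop("empty trial table", call. = FALSE)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  mosaic <- array(0L, c(nr * plot_px, nc * plot_px, 3))
  rois <- vector("list", n)
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    veg <- pmin(pmax(veg_base + veg_per_gy * trial$GY[i], 0.02), 0.95)
    chl <- pmin(pmax(trial$SEN[i], 0), 0.9)
    sp <- scene_spec(width = plot_px, height = plot_px, veg_fraction = veg,
                     chlorotic_share = chl, seed = seed + i)
    sc <- render_scene(sp)
    r <- (i - 1) %/% nc
    cc <- (i - 1) %% nc
    y0 <- r * plot_px; x0 <- cc * plot_px
    mosaic[(y0 + 1):(y0 + plot_px), (x0 + 1):(x0 + plot_px), ] <-
      unclass(sc$image)
    rois[[i]] <- data.frame(plot_id = trial$plot_id[i], x0 = x0, y0 = y0,
                            x1 = x0 + plot_px, y1 = y0 + plot_px,
                            genotype = trial$genotype[i],
                            replicate = trial$replicate[i],
                            treatment = trial$treatment[i],
                            stringsAsFactors = FALSE)
    scenes[[i]] <- sc
  }
  list(mosaic = rgb_image(mosaic, source_id = "synthetic_mosaic"),
       rois = do.call(rbind, rois), scenes = scenes)
}
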