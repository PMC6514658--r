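#' @title Trial-level agronomy
#' @description Grain yield, yield loss index, senescence, anthesis-silking
#'   interval, rank-based quartile yield groups and cross-treatment group
#'   overlap.
#' @name agronomy
NULL

#' Grain yield from plot grain weight
#'
#' `GY = weight_kg * 10 / area_m2`, in Mg/ha. The default harvested area is
#' 5.25 m² (two rows 0.75 m apart, central 3.5 m of each row). Grain weight
#' is assumed already standardized to ~12.5% moisture upstream.
#'
#' @param weight_kg grain weight per plot (kg); vectorized.
#' @param area_m2 harvested area (m²), default 5.25.
#' @return Grain yield in Mg/ha.
#' @export
grain_yield <- function(weight_kg, area_m2 = 5.25) {
  if (area_m2 <= 0) stop("harvested area must be positive", call. = FALSE)
  if (any(weight_kg < 0, na.rm = TRUE))
    stop("grain weight must be non-negative", call. = FALSE)
  weight_kg * 10 / area_m2
}

#' Grain yield loss index (GYLI)
#'
#' `GYLI = (GY_OP - GY_LOW) / GY_OP * 100`: percent yield lost under the
#' stress (low-input) treatment relative to the optimal treatment. Negative
#' when the stress treatment outyields the optimum; `NA` with a warning when
#' `gy_op <= 0`.
#'
#' @param gy_op genotype grain yield under optimal conditions (Mg/ha).
#' @param gy_low genotype grain yield under the stress treatment (Mg/ha).
#' @return Percent loss; vectorized.
#' @export
gyli <- function(gy_op, gy_low) {
  bad <- !is.na(gy_op) & gy_op <= 0
  if (any(bad))
    warning("GYLI undefined where optimal-treatment yield <= 0", call. = FALSE)
  out <- (gy_op - gy_low) / gy_op * 100
  out[bad] <- NA_real_
  out
}

#' Visual canopy senescence index
#'
#' `SEN = (YC + DC) / (YC + DC + GC)`: the senesced (yellow + dry) share of
#' total canopy cover. `NA` when total cover is zero.
#'
#' @param GC,YC,DC green, yellow and dry canopy cover (non-negative
#'   fractions or percentages on a common scale); vectorized.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
senescence <- function(GC, YC, DC) {
  if (any(c(GC, YC, DC) < 0, na.rm = TRUE))
    stop("cover classes must be non-negative", call. = FALSE)
  tot <- GC + YC + DC
  ifelse(tot > 0, (YC + DC) / tot, NA_real_)
}

#' Anthesis-silking interval
#'
#' `ASI = SD - AD` (silking date minus anthesis date, days from sowing).
#' Negative values (silking before anthesis) are retained.
#'
#' @param SD,AD silking and anthesis dates, days from sowing; vectorized.
#' @return ASI in days.
#' @export
asi <- function(SD, AD) SD - AD

#' Rank-based quartile yield groups
#'
#' Splits genotypes into four groups by descending grain yield: HY (high
#' yield), MHY, MLY and LY, each holding n/4 genotypes (within 1 for n not
#' divisible by 4). Ties are broken by genotype name so the labelling is
#' invariant to input row order.
#'
#' @param genotype character vector of genotype names (unique).
#' @param GY genotype-level grain yield (e.g. replicate means), same length.
#' @return `data.frame` with `genotype, GY, rank, group` (factor with levels
#'   `HY, MHY, MLY, LY`).
#' @export
quartile_groups <- function(genotype, GY) {
  stopifnot(length(genotype) == length(GY))
  if (anyDuplicated(genotype))
    stop("genotype names must be unique (aggregate replicates first)",
         call. = FALSE)
  n <- length(genotype)
  if (n < 4L) stop("need at least 4 genotypes to form quartiles",
                   call. = FALSE)
  ord <- order(-GY, as.character(genotype))
  sizes <- diff(floor(seq(0, n, length.out = 5)))
  grp <- rep(c("HY", "MHY", "MLY", "LY"), times = sizes)
  out <- data.frame(genotype = as.character(genotype)[ord], GY = GY[ord],
                    rank = seq_len(n),
                    group = factor(grp, levels = c("HY", "MHY", "MLY", "LY")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-treatment quartile-group overlap
#'
#' For each yield group, the percentage of its genotypes (under the first
#' labelling) that fall in the same group under the second labelling,
#' rounded to the nearest integer percent.
#'
#' @param labels_a,labels_b `data.frame`s from [quartile_groups()] over the
#'   same genotype set (e.g. the OP and LOW treatments).
#' @return Named integer vector of percentages (`HY, MHY, MLY, LY`), with a
#'   `shared` attribute holding the shared-genotype counts.
#' @export
group_overlap <- function(labels_a, labels_b) {
  if (!setequal(labels_a$genotype, labels_b$genotype))
    stop("genotype sets differ: ",
         paste(c(setdiff(labels_a$genotype, labels_b$genotype),
                 setdiff(labels_b$genotype, labels_a$genotype)),
               collapse = ", "), call. = FALSE)
  gb <- labels_b$group[match(labels_a$genotype, labels_b$genotype)]
  lv <- levels(labels_a$group)
  shared <- vapply(lv, function(g)
    sum(labels_a$group == g & gb == g), integer(1))
  size <- vapply(lv, function(g) sum(labels_a$group == g), integer(1))
  pct <- round(100 * shared / size)
  attr(pct, "shared") <- shared
  pct
}

#' Genotype-level yield summary across two treatments
#'
#' Aggregates a plot-level trial table to genotype means per treatment,
#' computes GYLI and assigns quartile yield groups within each treatment.
#'
#' @param trial `data.frame` with columns `genotype`, `treatment`
#'   (`"LOW"`/`"OP"`) and `GY` (Mg/ha per plot).
#' @return List with `summary` (`data.frame`: genotype, GY_OP, GY_LOW, GYLI,
#'   group_OP, group_LOW), and the two [quartile_groups()] tables
#'   (`groups_op`, `groups_low`).
#' @export
yield_summary <- function(trial) {
  need <- c("genotype", "treatment", "GY")
  miss <- setdiff(need, names(trial))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(GY ~ genotype + treatment, data = trial, FUN = mean)
  op  <- agg[agg$treatment == "OP", ]
  low <- agg[agg$treatment == "LOW", ]
  if (!nrow(op) || !nrow(low))
    stop("trial must contain both LOW and OP treatments", call. = FALSE)
  g_op  <- quartile_groups(op$genotype, op$GY)
  g_low <- quartile_groups(low$genotype, low$GY)
  sm <- data.frame(genotype = g_op$genotype,
                   GY_OP = g_op$GY,
                   GY_LOW = g_low$GY[match(g_op$genotype, g_low$genotype)],
                   stringsAsFactors = FALSE)
  sm$GYLI <- gyli(sm$GY_OP, sm$GY_LOW)
  sm$group_OP <- g_op$group
  sm$group_LOW <- g_low$group[match(sm$genotype, g_low$genotype)]
  list(summary = sm, groups_op = g_op, groups_low = g_low)
}
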