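#' @title Correlation and multivariate yield models
#' @description Pearson correlations of indices against grain yield,
#'   ground-vs-UAV level agreement, one-way ANOVA with Fisher LSD letter
#'   display, and stepwise-AIC multiple regression with simplified-formula
#'   reduction.
#' @name yield_models
NULL

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Pearson correlations of variables against a response
#'
#' Two-sided Pearson correlation of each named variable against the response
#' (grain yield by default) on pairwise-complete observations, with the
#' usual significance stars (0.05 / 0.01 / 0.001). Constant variables give
#' a missing `r` with a warning.
#'
#' @param data `data.frame` holding response and variables.
#' @param vars character vector of variable names; default every numeric
#'   column except the response.
#' @param response response column name, default `"GY"`.
#' @return `data.frame` with `variable, n, r, p, signif`.
#' @export
correlate_yield <- function(data, vars = NULL, response = "GY") {
  if (!response %in% names(data))
    stop("response column not found: ", response, call. = FALSE)
  if (is.null(vars)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(num, response)
  }
  y <- data[[response]]
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    if (n < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      if (n >= 3) warning("constant variable, correlation undefined: ", v,
                          call. = FALSE)
      return(data.frame(variable = v, n = n, r = NA_real_, p = NA_real_,
                        signif = ""))
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    data.frame(variable = v, n = n, r = unname(ct$estimate), p = ct$p.value,
               signif = .stars(ct$p.value))
  })
  do.call(rbind, rows)
}

#' Ground-vs-UAV index agreement
#'
#' For each index shared between the two observation levels: the Pearson
#' correlation across matched plots, and a one-way ANOVA p-value for a
#' systematic level effect (ground vs aerial) on the index values.
#'
#' @param ground,uav plot index record `data.frame`s with a `plot_id` column
#'   (see [batch_index()]).
#' @param vars index columns to compare; default all shared numeric columns.
#' @return `data.frame` with `variable, n, r, p_cor, signif_cor,
#'   p_level_anova, signif_anova`.
#' @export
level_agreement <- function(ground, uav, vars = NULL) {
  un <- setdiff(ground$plot_id, uav$plot_id)
  un2 <- setdiff(uav$plot_id, ground$plot_id)
  if (length(un) || length(un2))
    stop("unmatched plot_ids: ", paste(c(un, un2), collapse = ", "),
         call. = FALSE)
  uav <- uav[match(ground$plot_id, uav$plot_id), ]
  if (is.null(vars)) {
    shared <- intersect(names(ground), names(uav))
    vars <- shared[vapply(ground[shared], is.numeric, logical(1))]
    vars <- setdiff(vars, "plot_id")
  }
  rows <- lapply(vars, function(v) {
    g <- ground[[v]]; u <- uav[[v]]
    keep <- is.finite(g) & is.finite(u)
    n <- sum(keep)
    if (n < 3 || stats::sd(g[keep]) == 0 || stats::sd(u[keep]) == 0)
      return(data.frame(variable = v, n = n, r = NA_real_, p_cor = NA_real_,
                        signif_cor = "", p_level_anova = NA_real_,
                        signif_anova = ""))
    ct <- stats::cor.test(g[keep], u[keep])
    lv <- factor(rep(c("ground", "uav"), each = n))
    av <- summary(stats::aov(c(g[keep], u[keep]) ~ lv))[[1]]
    p_aov <- av[["Pr(>F)"]][1]
    data.frame(variable = v, n = n, r = unname(ct$estimate), p_cor = ct$p.value,
               signif_cor = .stars(ct$p.value), p_level_anova = p_aov,
               signif_anova = .stars(p_aov))
  })
  do.call(rbind, rows)
}

#' One-way ANOVA with Fisher LSD letter display
#'
#' Fits a one-way ANOVA over the groups and assigns compact letters using
#' Fisher's Least Significant Difference on the pooled mean-square error:
#' groups sharing a letter are not significantly different at `alpha`.
#' Letters are assigned over groups ordered by descending mean, merging
#' maximal runs of mutually non-different groups.
#'
#' @param values numeric response vector.
#' @param groups grouping factor/vector, `>= 2` levels with `>= 2` values
#'   each.
#' @param alpha significance level, default 0.05.
#' @return `data.frame` with `group, n, mean, letters`, ordered by
#'   descending mean; ANOVA p-value in attribute `p_anova`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  cnt <- table(groups)
  if (any(cnt < 2L))
    stop("each group needs at least 2 values; degenerate: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(values ~ groups)
  av <- summary(fit)[[1]]
  mse <- av["Residuals", "Mean Sq"]
  dfe <- av["Residuals", "Df"]
  p_anova <- av[["Pr(>F)"]][1]
  mns <- tapply(values, groups, mean)
  ns <- as.numeric(cnt)[order(-mns)]
  lv <- names(sort(mns, decreasing = TRUE))
  mns <- sort(mns, decreasing = TRUE)
  k <- length(lv)
  # pairwise Fisher-LSD significance on pooled MSE
  sig <- matrix(FALSE, k, k)
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lsd <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    sig[i, j] <- sig[j, i] <- abs(mns[i] - mns[j]) > lsd
  }
  # maximal non-significant runs over mean-ordered groups -> letters
  ends <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1L
    j
  }, integer(1))
  runs <- unique(lapply(seq_len(k), function(i) c(i, ends[i])))
  maximal <- vapply(runs, function(a) !any(vapply(runs, function(b)
    !identical(a, b) && b[1] <= a[1] && b[2] >= a[2], logical(1))),
    logical(1))
  runs <- runs[maximal]
  letters_vec <- rep("", k)
  for (r in seq_along(runs)) {
    span <- runs[[r]][1]:runs[[r]][2]
    letters_vec[span] <- paste0(letters_vec[span], letters[r])
  }
  out <- data.frame(group = lv, n = ns, mean = as.numeric(mns),
                    letters = letters_vec, stringsAsFactors = FALSE)
  attr(out, "p_anova") <- p_anova
  out
}

#' Stepwise-AIC multiple regression for grain yield
#'
#' AIC-guided stepwise selection (via `MASS::stepAIC`, penalty `k = 2`) of a
#' multiple linear regression of the response on a named predictor set, on
#' complete cases. Aliased (perfectly collinear) predictors are dropped from
#' the scope with a message before selection.
#'
#' @param data `data.frame` holding response and predictors.
#' @param predictors character vector of candidate predictor columns.
#' @param response response column name, default `"GY"`.
#' @param direction `"forward"`, `"backward"` or `"both"`.
#' @param label free-text label for the predictor set (reporting only).
#' @return A `model_fit` object: list with `fit` (the `lm`), `response`,
#'   `predictors` (selected), `coefficients`, `p_values`, `r_squared`,
#'   `rse`, `aic`, `p_model` (overall F test), `direction`, `label`,
#'   `simplified`, `equation` (Table-style string) and `data` (complete
#'   cases used).
#' @export
stepwise_fit <- function(data, predictors, response = "GY",
                         direction = c("forward", "backward", "both"),
                         label = "") {
  direction <- match.arg(direction)
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("columns not found: ", paste(miss, collapse = ", "), call. = FALSE)
  cc <- stats::complete.cases(data[cols])
  d <- data[cc, cols, drop = FALSE]
  if (nrow(d) < length(predictors) + 10)
    stop("too few complete cases (", nrow(d), ") for ", length(predictors),
         " predictors", call. = FALSE)
  # drop aliased/constant predictors from scope
  drop_const <- predictors[vapply(d[predictors], function(x)
    stats::sd(x) == 0, logical(1))]
  predictors <- setdiff(predictors, drop_const)
  full_fml <- stats::reformulate(predictors, response)
  full <- stats::lm(full_fml, data = d)
  ali <- names(which(is.na(stats::coef(full))))
  if (length(c(drop_const, ali)))
    message("dropping aliased/constant predictors: ",
            paste(c(drop_const, ali), collapse = ", "))
  predictors <- setdiff(predictors, ali)
  full <- stats::lm(stats::reformulate(predictors, response), data = d)
  null <- stats::lm(stats::reformulate("1", response), data = d)
  scope <- list(lower = stats::formula(null), upper = stats::formula(full))
  sel <- switch(direction,
    forward  = MASS::stepAIC(null, scope = scope, direction = "forward",
                             trace = 0),
    backward = MASS::stepAIC(full, scope = scope, direction = "backward",
                             trace = 0),
    both     = MASS::stepAIC(null, scope = scope, direction = "both",
                             trace = 0))
  new_model_fit(sel, response, direction, label, simplified = FALSE, data = d)
}

new_model_fit <- function(fit, response, direction, label, simplified, data) {
  s <- summary(fit)
  co <- s$coefficients
  preds <- setdiff(rownames(co), "(Intercept)")
  fstat <- s$fstatistic
  p_model <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    fit = fit, response = response, predictors = preds,
    coefficients = stats::coef(fit), p_values = co[, 4],
    r_squared = s$r.squared, rse = s$sigma, aic = stats::AIC(fit),
    p_model = unname(p_model), direction = direction, label = label,
    simplified = simplified, equation = format_equation(fit, response),
    data = data), class = "model_fit")
}

#' Format a fitted model as an equation string
#'
#' Renders an `lm` fit in the compact report style
#' `GY = -AD*0.28 + NDLab*15.20 + 5.97`.
#'
#' @param fit an `lm` object or `model_fit`.
#' @param response response name used on the left-hand side.
#' @param digits coefficient digits.
#' @return Character scalar.
#' @export
format_equation <- function(fit, response = "GY", digits = 3) {
  if (inherits(fit, "model_fit")) fit <- fit$fit
  co <- stats::coef(fit)
  ic <- co[names(co) == "(Intercept)"]
  sl <- co[names(co) != "(Intercept)"]
  term <- function(b, nm) sprintf("%s %s*%s", ifelse(b < 0, "-", "+"), nm,
                                  format(abs(b), digits = digits))
  parts <- mapply(term, sl, names(sl))
  rhs <- paste(parts, collapse = " ")
  if (length(ic))
    rhs <- paste(rhs, ifelse(ic < 0, "-", "+"),
                 format(abs(ic), digits = digits))
  rhs <- sub("^\\+ ", "", rhs)
  rhs <- sub("^- ", "-", rhs)
  paste(response, "=", trimws(rhs))
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit%s> %s (%s stepwise)\n",
              if (x$simplified) ", simplified" else "", x$label, x$direction))
  cat("  ", x$equation, "\n", sep = "")
  cat(sprintf("  R^2 = %.3f, RSE = %.3f, AIC = %.1f, model p = %.3g\n",
              x$r_squared, x$rse, x$aic, x$p_model))
  invisible(x)
}

#' Reduce a fitted model to its simplified formula
#'
#' Iteratively removes weak terms from a [stepwise_fit()] model, refitting
#' after each drop: (1) among predictor pairs whose mutual correlation
#' exceeds `collinearity` in absolute value, the one with the weaker
#' marginal correlation to the response is dropped; (2) the predictor with
#' the largest p-value `>= alpha` is dropped. Stops when all remaining
#' predictors are significant and mutually below the collinearity threshold.
#' Since predictors are only ever removed, the simplified R-squared can
#' never exceed the full model's.
#'
#' @param model a `model_fit` from [stepwise_fit()].
#' @param alpha significance threshold for keeping a predictor.
#' @param collinearity absolute pairwise-correlation threshold, default 0.7.
#' @return A simplified `model_fit` (intercept-only, with a warning, if
#'   every predictor is dropped).
#' @export
simplify_model <- function(model, alpha = 0.05, collinearity = 0.7) {
  stopifnot(inherits(model, "model_fit"))
  d <- model$data
  y <- d[[model$response]]
  preds <- model$predictors
  repeat {
    if (!length(preds)) break
    fit <- stats::lm(stats::reformulate(preds, model$response), data = d)
    co <- summary(fit)$coefficients
    pr <- setdiff(rownames(co), "(Intercept)")
    pv <- stats::setNames(co[pr, 4], pr)  # single-row indexing drops names
    # collinear pairs first: keep the predictor closer to the response
    if (length(preds) > 1) {
      cm <- abs(stats::cor(d[preds]))
      diag(cm) <- 0
      if (max(cm) >= collinearity) {
        idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
        pair <- preds[idx]
        marg <- abs(vapply(pair, function(p) stats::cor(d[[p]], y),
                           numeric(1)))
        preds <- setdiff(preds, pair[which.min(marg)])
        next
      }
    }
    if (any(pv >= alpha)) {
      preds <- setdiff(preds, names(which.max(pv)))
      next
    }
    break
  }
  if (!length(preds)) {
    warning("all predictors dropped; returning intercept-only model",
            call. = FALSE)
    fit <- stats::lm(stats::reformulate("1", model$response), data = d)
  } else {
    fit <- stats::lm(stats::reformulate(preds, model$response), data = d)
  }
  new_model_fit(fit, model$response, model$direction, model$label,
                simplified = TRUE, data = d)
}

#' Export model fits as a report table
#'
#' @param fits list of `model_fit` objects.
#' @return `data.frame` with `label, direction, simplified, equation,
#'   r_squared, rse, p_model` (one row per fit).
#' @export
model_report <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f)
    data.frame(label = f$label, direction = f$direction,
               simplified = f$simplified, equation = f$equation,
               r_squared = f$r_squared, rse = f$rse, p_model = f$p_model,
               stringsAsFactors = FALSE)))
}
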