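test_that("correlations report r, p and stars correctly", {
  d <- data.frame(GY = 1:20, exact = 1:20, noise = NA_real_,
                  flat = rep(3, 20))
  set.seed(1); d$noise <- rnorm(20)
  out <- suppressWarnings(correlate_yield(d, c("exact", "noise", "flat")))
  expect_equal(out$r[out$variable == "exact"], 1, tolerance = 1e-12)
  expect_lt(out$p[out$variable == "exact"], 1e-10)
  expect_equal(out$signif[out$variable == "exact"], "***")
  expect_true(is.na(out$r[out$variable == "flat"]))
  expect_warning(correlate_yield(d, "flat"), "constant")
})

test_that("independent variables rarely look correlated at n = 192", {
  set.seed(202)
  hits <- replicate(100, {
    d <- data.frame(GY = rnorm(192), x = rnorm(192))
    abs(correlate_yield(d, "x")$r) < 0.2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a programmed signal-to-noise ratio is recovered as r", {
  # index = GY + noise tuned for r ~ 0.6; average over 200 seeds
  target_r <- 0.6
  sd_noise <- sqrt(1 / target_r^2 - 1)
  set.seed(303)
  rs <- replicate(200, {
    gy <- rnorm(192)
    d <- data.frame(GY = gy, idx = gy + rnorm(192, 0, sd_noise))
    correlate_yield(d, "idx")$r
  })
  expect_equal(mean(rs), target_r, tolerance = 0.05 / target_r)
})

test_that("level agreement sees identity, bias and attenuated copies", {
  set.seed(9)
  ground <- data.frame(plot_id = sprintf("p%03d", 1:192),
                       GA = runif(192, 0.1, 0.6))
  same <- level_agreement(ground, ground)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_gt(same$p_level_anova, 0.99)  # no level effect
  biased <- ground; biased$GA <- biased$GA + 0.2
  bi <- level_agreement(ground, biased)
  expect_equal(bi$r, 1, tolerance = 1e-12)
  expect_lt(bi$p_level_anova, 0.001)   # constant bias detected at n = 192
  expect_error(level_agreement(ground, biased[-1, ]), "unmatched")
  # attenuated + noisy copy recovers the programmed correlation
  set.seed(10)
  rs <- replicate(100, {
    g <- data.frame(plot_id = sprintf("p%03d", 1:192), GA = rnorm(192))
    u <- g; u$GA <- 0.8 * g$GA + rnorm(192, 0, sqrt(0.64 / 0.81 - 0.64))
    level_agreement(g, u)$r
  })
  expect_equal(mean(rs), 0.9, tolerance = 0.05 / 0.9)
})

test_that("Fisher LSD letters separate what ANOVA can separate", {
  set.seed(21)
  # four groups with huge separation -> four distinct letters, ordered
  v <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20), rnorm(10, 30))
  g <- rep(c("LY", "MLY", "MHY", "HY"), each = 10)
  out <- anova_lsd(v, g)
  expect_equal(out$group, c("HY", "MHY", "MLY", "LY"))
  expect_equal(out$letters, c("a", "b", "c", "d"))
  expect_lt(attr(out, "p_anova"), 1e-10)
  # two identical groups share a letter
  v2 <- c(rnorm(10), rnorm(10))
  out2 <- anova_lsd(v2, rep(c("x", "y"), each = 10))
  expect_equal(out2$letters, c("a", "a"))
  expect_error(anova_lsd(1:5, c("a", "a", "a", "a", "b")), "degenerate")
  expect_error(anova_lsd(1:4, rep("a", 4)), "2 groups")
})

test_that("LSD letters hold the type-I error on null groups", {
  set.seed(22)
  all_shared <- replicate(100, {
    v <- rnorm(40)
    out <- anova_lsd(v, rep(letters[1:4], each = 10))
    all(out$letters == "a")
  })
  # ~0.05 familywise per pair; most seeds show one shared letter
  expect_gte(mean(all_shared), 0.6)
  expect_lte(mean(all_shared), 0.95)
})

test_that("stepwise selection finds a single true predictor among noise", {
  set.seed(31)
  found <- replicate(100, {
    n <- 192
    X <- matrix(rnorm(n * 11), n, 11,
                dimnames = list(NULL, paste0("x", 1:11)))
    d <- data.frame(GY = 0.5 * X[, "x1"] + rnorm(n), X)
    fit <- stepwise_fit(d, paste0("x", 1:11), direction = "forward")
    "x1" %in% fit$predictors
  })
  expect_gte(mean(found), 0.95)
})

test_that("zero-signal data yields near-zero stepwise R^2", {
  set.seed(32)
  r2 <- replicate(40, {
    n <- 192
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    d <- data.frame(GY = rnorm(n), X)
    stepwise_fit(d, paste0("x", 1:10), direction = "forward")$r_squared
  })
  expect_gte(mean(r2 < 0.15), 0.9)
})

test_that("a generative R^2 of 0.6 is recovered by the fitted model", {
  set.seed(33)
  r2 <- replicate(50, {
    n <- 192
    x1 <- rnorm(n); x2 <- rnorm(n)
    mu <- x1 + x2                       # var 2
    y <- mu + rnorm(n, 0, sqrt(2 * (1 - 0.6) / 0.6))
    d <- data.frame(GY = y, x1 = x1, x2 = x2, x3 = rnorm(n))
    stepwise_fit(d, c("x1", "x2", "x3"), direction = "both")$r_squared
  })
  expect_equal(mean(r2), 0.6, tolerance = 0.08 / 0.6)
})

test_that("stepwise selection is deterministic and reports Table-style output", {
  set.seed(34)
  n <- 60
  d <- data.frame(GY = rnorm(n), ASI = rnorm(n), AD = rnorm(n),
                  NDLab = rnorm(n))
  d$GY <- 3 - 0.5 * d$ASI + 2 * d$NDLab + rnorm(n, 0, 0.5)
  f1 <- stepwise_fit(d, c("ASI", "AD", "NDLab"), direction = "forward",
                     label = "demo")
  f2 <- stepwise_fit(d, c("ASI", "AD", "NDLab"), direction = "forward",
                     label = "demo")
  expect_identical(f1$equation, f2$equation)
  expect_match(f1$equation, "^GY = ")
  expect_true(all(c("ASI", "NDLab") %in% f1$predictors))
  rep_tab <- model_report(list(f1, simplify_model(f1)))
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(c("equation", "r_squared", "rse") %in% names(rep_tab)))
})

test_that("simplify_model applies the p-value and collinearity rules", {
  set.seed(35)
  n <- 120
  x1 <- rnorm(n)
  junk <- rnorm(n)
  d <- data.frame(GY = 2 * x1 + rnorm(n, 0, 0.5), x1 = x1, junk = junk)
  full <- stepwise_fit(d, c("x1", "junk"), direction = "backward")
  # force the junk predictor in so the p-rule has something to drop
  full$fit <- lm(GY ~ x1 + junk, data = d)
  full$predictors <- c("x1", "junk")
  simp <- simplify_model(full)
  expect_equal(simp$predictors, "x1")
  expect_true(simp$simplified)
  # collinear pair: keep the one with stronger marginal correlation
  x1b <- x1 + rnorm(n, 0, 0.05)        # |r| > 0.99 with x1, weaker vs GY
  d2 <- data.frame(GY = d$GY, x1 = x1, x1b = x1b)
  f2 <- stepwise_fit(d2, c("x1", "x1b"), direction = "backward")
  f2$fit <- lm(GY ~ x1 + x1b, data = d2)
  f2$predictors <- c("x1", "x1b")
  s2 <- simplify_model(f2)
  keep <- names(which.max(abs(c(x1 = cor(d2$x1, d2$GY),
                                x1b = cor(d2$x1b, d2$GY)))))
  expect_equal(s2$predictors, keep)
  # dropping everything falls back to intercept-only with a warning
  d3 <- data.frame(GY = rnorm(30), z = rnorm(30))
  f3 <- stepwise_fit(d3, "z", direction = "backward")
  f3$fit <- lm(GY ~ z, data = d3)
  f3$predictors <- "z"
  if (summary(f3$fit)$coefficients["z", 4] >= 0.05)
    expect_warning(simplify_model(f3), "intercept-only")
})

test_that("the simplified model never outperforms the full model", {
  set.seed(36)
  for (i in 1:10) {
    n <- 100
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
    d <- data.frame(GY = X %*% runif(6, -0.3, 0.3) + rnorm(n), X)
    full <- stepwise_fit(d, paste0("v", 1:6), direction = "backward")
    simp <- suppressWarnings(simplify_model(full))
    expect_lte(simp$r_squared, full$r_squared + 1e-12)
  }
})

test_that("multivariate models beat single predictors on structured trials", {
  tt <- simulate_trial(trial_spec(seed = 44))
  low <- tt$trial[tt$trial$treatment == "LOW", ]
  preds <- c("ASI", "AD", "SEN", "PH", "NDLab_ground", "GGA_ground")
  fit <- stepwise_fit(low, preds, direction = "forward")
  r_single <- max(correlate_yield(low, preds)$r^2)
  expect_gt(fit$r_squared, r_single)
  # generated sign structure survives fitting: ASI and AD negative under LOW
  co <- coef(lm(GY ~ ASI + AD, data = low))
  expect_lt(co[["ASI"]], 0)
  expect_lt(co[["AD"]], 0)
})
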