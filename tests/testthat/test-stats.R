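test_that("interaction lm: closed-form slope, residual df, exact fits, aliasing", {
  set.seed(81)
  # single group degenerates to simple regression
  x <- rnorm(30); y <- 1 + 2 * x + rnorm(30)
  f1 <- fit_lm_interaction(y, x, rep("a", 30))
  expect_equal(f1$fixed$b[f1$fixed$term == ".x"],
               stats::cov(x, y) / stats::var(x), tolerance = 1e-12)
  expect_equal(f1$fit$df_residual, 28L)

  # G groups leave n - 2G residual df
  n <- 200; g <- rep(letters[1:4], each = 50)
  x <- rnorm(n); y <- rnorm(n)
  f4 <- fit_lm_interaction(y, x, g)
  expect_equal(f4$fit$df_residual, n - 8L)

  # exactly linear within groups: zero residual SS
  slopes <- c(a = 1, b = -2, c = 0.5, d = 3)
  ints <- c(a = 0, b = 1, c = -1, d = 2)
  yy <- ints[g] + slopes[g] * x
  fex <- suppressWarnings(fit_lm_interaction(yy, x, g))  # perfect-fit notice
  expect_lt(sum(stats::residuals(fex$model)^2), 1e-10)

  # aliased design errors with the term named
  expect_error(fit_lm_interaction(y, rep(1, n), g), "aliased")
})

test_that("interaction lm marginal F tests match car::Anova type III", {
  skip_if_not_installed("car")
  set.seed(82)
  n <- 150; g <- factor(sample(letters[1:3], n, TRUE))
  x <- rnorm(n)
  y <- 0.5 * x + c(a = 0, b = 1, c = -0.5)[g] + rnorm(n)
  fit <- fit_lm_interaction(y, x, g, contrasts = "sum")
  ca <- car::Anova(fit$model, type = "III")
  for (trm in fit$terms$term) {
    expect_equal(fit$terms$statistic[fit$terms$term == trm],
                 ca[trm, "F value"], tolerance = 1e-8)
    expect_equal(fit$terms$p[fit$terms$term == trm],
                 ca[trm, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("standardized beta equals the slope of the z-scored regression", {
  set.seed(83)
  x <- rnorm(80, sd = 3); y <- 2 + 0.7 * x + rnorm(80)
  raw <- fit_lm_interaction(y, x, rep("a", 80))
  std <- fit_lm_interaction(as.numeric(scale(y)), as.numeric(scale(x)),
                            rep("a", 80))
  expect_equal(raw$fixed$beta[raw$fixed$term == ".x"],
               std$fixed$b[std$fixed$term == ".x"], tolerance = 1e-10)
  expect_equal(raw$fixed$beta[raw$fixed$term == ".x"],
               raw$fixed$b[raw$fixed$term == ".x"] * sd(x) / sd(y),
               tolerance = 1e-12)
})

test_that("crossed REML matches one-way ANOVA closed forms and the deviance oracle", {
  # balanced one-way design (single random factor): textbook REML estimates
  set.seed(5)
  a <- 12; m <- 8
  g <- rep(seq_len(a), each = m)
  y <- 2 + rnorm(a)[g] * 1.3 + rnorm(a * m)
  fit <- fit_crossed_lmm(y, NULL, id1 = g)
  tab <- stats::anova(stats::lm(y ~ factor(g)))
  mse <- tab["Residuals", "Mean Sq"]
  msa <- tab["factor(g)", "Mean Sq"]
  est <- setNames(fit$varcomp$variance, fit$varcomp$component)
  expect_equal(unname(est["id1"]), (msa - mse) / m, tolerance = 1e-8)
  expect_equal(unname(est["residual"]), mse, tolerance = 1e-8)

  # crossed design: the returned optimum beats a coarse grid of the
  # independently coded dense REML deviance, and reproduces the criterion
  set.seed(6)
  d <- expand.grid(i = seq_len(8), j = seq_len(8))
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 0.5 * d$x + rnorm(8)[d$i] + rnorm(8)[d$j] * 0.7 + rnorm(nrow(d))
  f2 <- fit_crossed_lmm(d$y, d$x, paste0("a", d$i), paste0("b", d$j))
  v <- setNames(f2$varcomp$variance, f2$varcomp$component)
  X <- cbind(1, d$x)
  dev_at_est <- oracle_reml_deviance(d$y, X, d$i, d$j,
                                     v["id1"], v["id2"], v["residual"])
  expect_equal(dev_at_est, f2$fit$criterion, tolerance = 1e-6)
  grid <- expand.grid(s1 = seq(0.02, 3, length.out = 50),
                      s2 = seq(0.02, 3, length.out = 50))
  grid_dev <- mapply(function(s1, s2) {
    oracle_reml_deviance(d$y, X, d$i, d$j, s1, s2, v["residual"])
  }, grid$s1, grid$s2)
  expect_gte(min(grid_dev), dev_at_est - 1e-6)
})

test_that("double-boundary REML fits reduce to ordinary least squares", {
  set.seed(12)
  d <- expand.grid(i = seq_len(10), j = seq_len(10))
  d$x <- rnorm(nrow(d))
  y <- 0.3 + 0.9 * d$x + rnorm(nrow(d))   # no station effects at all
  fit <- fit_crossed_lmm(y, d$x, paste0("a", d$i), paste0("b", d$j))
  v <- setNames(fit$varcomp$variance, fit$varcomp$component)
  expect_true(fit$fit$boundary)
  expect_lt(max(v["id1"], v["id2"]), 1e-10)
  ols <- coef(stats::lm(y ~ d$x))
  expect_equal(fit$fixed$b, unname(ols), tolerance = 1e-6)
})

test_that("Wald and LRT term tests agree where they must", {
  set.seed(84)
  # single-coefficient term: Wald chi-square equals z squared
  d <- expand.grid(i = seq_len(12), j = seq_len(12))
  d$x <- rnorm(nrow(d))
  y <- 1 + 0.4 * d$x + rnorm(12)[d$i] * 0.5 + rnorm(12)[d$j] * 0.5 +
    rnorm(nrow(d))
  fit <- fit_crossed_lmm(y, d$x, paste0("a", d$i), paste0("b", d$j))
  wt <- term_tests(fit, "wald")
  z <- fit$fixed$z[fit$fixed$term == ".x"]
  expect_equal(wt$statistic[wt$term == ".x"], z^2, tolerance = 1e-10)

  # coefficients exactly zero (response orthogonal to the design):
  # statistic 0, p = 1
  set.seed(85)
  n <- 120; g <- factor(rep(letters[1:3], length.out = n)); x <- rnorm(n)
  X <- stats::model.matrix(~ x * g,
                           contrasts.arg = list(g = "contr.sum"))
  e <- stats::residuals(stats::lm(rnorm(n) ~ X))
  f0 <- fit_lm_interaction(as.numeric(e), x, g)
  expect_lt(max(f0$terms$statistic), 1e-18)
  expect_equal(f0$terms$p, rep(1, 3), tolerance = 1e-12)

  # asymptotic equivalence on a large well-conditioned simulation
  set.seed(86)
  d2 <- expand.grid(i = seq_len(45), j = seq_len(45))
  d2$x <- rnorm(nrow(d2))
  d2$g <- sample(c("A", "B"), nrow(d2), TRUE)
  slopes <- c(A = 0.3, B = 0.5)
  y2 <- slopes[d2$g] * d2$x + rnorm(45)[d2$i] * 0.4 + rnorm(45)[d2$j] * 0.4 +
    rnorm(nrow(d2))
  f2 <- fit_crossed_lmm(y2, d2$x, paste0("a", d2$i), paste0("b", d2$j),
                        g = d2$g)
  wald <- term_tests(f2, "wald")
  lrt <- suppressMessages(term_tests(f2, "lrt"))
  for (trm in wald$term) {
    w <- wald$statistic[wald$term == trm]
    l <- lrt$statistic[lrt$term == trm]
    expect_lt(abs(w - l) / max(w, 1), 0.10)
  }
})

test_that("simple slopes are coding-invariant and recover generating slopes", {
  set.seed(87)
  # single group: the one slope is the x coefficient
  x <- rnorm(40); y <- 1 + 0.6 * x + rnorm(40)
  f1 <- fit_lm_interaction(y, x, rep("only", 40))
  s1 <- simple_slopes(f1)
  expect_equal(s1$b, f1$fixed$b[f1$fixed$term == ".x"], tolerance = 1e-12)

  # sum vs treatment coding: identical per-group slopes and SEs
  g <- rep(letters[1:5], each = 500)
  x <- rnorm(2500)
  slopes <- c(a = 0.04, b = 0.03, c = 0.01, d = 0.05, e = 0.02)
  y <- slopes[g] * x + rnorm(2500, sd = 0.5)
  fs <- fit_lm_interaction(y, x, g, contrasts = "sum")
  ft <- fit_lm_interaction(y, x, g, contrasts = "treatment")
  ss <- simple_slopes(fs); st <- simple_slopes(ft)
  expect_equal(ss$b, st$b, tolerance = 1e-10)
  expect_equal(ss$se, st$se, tolerance = 1e-10)

  # recovery within 3 SEs of the generating slopes
  expect_true(all(abs(ss$b - slopes[ss$group]) <= 3 * ss$se))

  # relabeling levels permutes, never changes, the slopes
  relab <- c(a = "v", b = "w", c = "x", d = "y", e = "z")
  fr <- fit_lm_interaction(y, x, relab[g])
  sr <- simple_slopes(fr)
  expect_equal(sr$b[match(relab[ss$group], sr$group)], ss$b,
               tolerance = 1e-10)
})

test_that("simple slopes agree with emmeans trends", {
  skip_if_not_installed("emmeans")
  set.seed(88)
  g <- rep(c("A", "B", "C"), each = 60)
  x <- rnorm(180)
  y <- c(A = 0.2, B = -0.4, C = 0.9)[g] * x + rnorm(180)
  fit <- fit_lm_interaction(y, x, g)
  ours <- simple_slopes(fit)
  em <- as.data.frame(emmeans::emtrends(fit$model, ".g", var = ".x",
                                        data = fit$data))
  expect_equal(ours$b, em$.x.trend, tolerance = 1e-8)
  expect_equal(ours$se, em$SE, tolerance = 1e-8)
})

test_that("the Wald interaction test holds its nominal size under the null", {
  set.seed(404)
  d <- expand.grid(i = seq_len(30), j = seq_len(30))
  id1 <- paste0("a", d$i); id2 <- paste0("b", d$j)
  nrep <- 400
  rejected <- logical(nrep)
  for (r in seq_len(nrep)) {
    x <- rnorm(nrow(d))
    g <- sample(c("A", "B"), nrow(d), TRUE)
    y <- 0.3 * x + rnorm(30)[d$i] * 0.5 + rnorm(30)[d$j] * 0.5 + rnorm(nrow(d))
    fit <- fit_crossed_lmm(y, x, id1, id2, g = g)
    p <- fit$terms$p[fit$terms$term == ".x:.g"]
    rejected[r] <- p < 0.05
  }
  rate <- mean(rejected)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("tilde-notation model specs dispatch correctly", {
  set.seed(89)
  d <- expand.grid(s1 = paste0("a", 1:8), s2 = paste0("b", 1:8))
  d$ling <- rnorm(nrow(d))
  d$city <- sample(c("Berlin", "Milan"), nrow(d), TRUE)
  d$geo <- 2 + 0.5 * d$ling + rnorm(nrow(d))

  # field-style notation, typographic operators included
  f <- fit_model_spec(d, "geo ~ ling × city + (1∣s1) + (1∣s2)")
  expect_s3_class(f, "lingmap_fit")
  expect_identical(f$kind, "lmm")
  expect_setequal(f$varcomp$component, c("id1", "id2", "residual"))

  f2 <- fit_model_spec(d, "geo ~ ling * city")
  expect_identical(f2$kind, "lm")

  f3 <- fit_model_spec(d, "geo ~ ling + (1|s1) + (1|s2)")
  expect_false(".g" %in% names(f3$data))

  expect_error(fit_model_spec(d, "geo ~ nope * city"), "nope")
})
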