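test_that("ratio distribution divides, sorts, and guards x = 0", {
  panel <- toy_panel()
  panel$stunting_moderate <- c(0.2, 0.1, 0.3)
  panel$pou <- c(0.4, 0.5, 0.25)
  r <- ratio_distribution(panel, "moderate")
  expect_equal(as.numeric(r), sort(c(0.5, 0.2, 1.2)))
  panel$pou[3] <- 0
  r2 <- ratio_distribution(panel, 2)   # numeric level code
  expect_equal(as.numeric(r2), c(0.2, 0.5))
  expect_equal(attr(r2, "n_excluded"), 1L)
  panel$pou <- 0
  expect_error(ratio_distribution(panel, "moderate"), "zero undernourishment")
})

test_that("ratios concentrate near the generating slope when y = 0.3 x", {
  set.seed(21)
  n <- 400
  x <- runif(n, 0.2, 0.7)
  panel <- data.frame(stunting_moderate = pmax(0.3 * x + rnorm(n, 0, 0.005), 0),
                      stunting_severe = 0.1, pou = x)
  r <- ratio_distribution(panel, "moderate")
  expect_lt(abs(median(r) - 0.3), 0.02)
  expect_lt(abs(unname(quantile(r, 0.05, type = 6)) - 0.3), 0.05)
})

test_that("percentiles (0,0,0) reduce beta to the pure minimum", {
  b <- estimate_beta(c(0.5, 0.4, 0.3, 0.2, 0.6), percentiles = c(0, 0, 0))
  expect_equal(b$central, 0.2)
  expect_equal(b$low, 0.2)
  expect_equal(b$high, 0.2)
  expect_error(estimate_beta(0.5), "at least 2")
})

test_that("beta percentiles match a brute-force order-statistic oracle", {
  ratios <- seq(0.01, 1, by = 0.01)   # 100 evenly spaced ratios
  b <- estimate_beta(ratios, percentiles = c(1, 5, 10))
  # independent oracle for the declared rule: linear interpolation at
  # rank h = (n + 1) p between adjacent order statistics
  oracle <- function(sorted, p) {
    h <- (length(sorted) + 1) * p
    lo <- max(floor(h), 1)
    hi <- min(lo + 1, length(sorted))
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  expect_equal(b$low, oracle(ratios, 0.01), tolerance = 1e-12)
  expect_equal(b$central, oracle(ratios, 0.05), tolerance = 1e-12)
  expect_equal(b$high, oracle(ratios, 0.10), tolerance = 1e-12)
  expect_true(b$low <= b$central && b$central <= b$high)
  # oracle also pinned on irregular data
  set.seed(33)
  irregular <- sort(rlnorm(57, -1, 0.8))
  b2 <- estimate_beta(irregular)
  expect_equal(b2$central, oracle(irregular, 0.05), tolerance = 1e-12)
})

test_that("food attribution and the nonfood residual reconstruct y exactly", {
  expect_equal(attribute_food(0.35, 0.01), 0.0035)
  expect_equal(attribute_food(0.35, 0), 0)
  expect_equal(attribute_food(0.18, 0.5), 0.09)
  expect_equal(residual_nonfood(0.23, 0.077), 0.153)
  expect_equal(residual_nonfood(0.2, 0.2), 0)
  # stepwise identity r + s = y over a whole synthetic panel
  panel <- generate_panel(synth_config(seed = 13))$panel
  r <- attribute_food(0.35, panel$pou)
  s <- residual_nonfood(panel$stunting_moderate, pmin(r, 1))
  expect_equal(pmin(r, 1) + s, panel$stunting_moderate, tolerance = 1e-15)
})

test_that("about half or more of stunting is nonfood on a realistic panel", {
  gp <- generate_panel(synth_config(seed = 29))
  panel <- gp$panel
  r <- attribute_food(0.35, panel$pou)
  s <- panel$stunting_moderate - r
  nonfood_share <- mean(s) / mean(panel$stunting_moderate)
  # qualitative check of the attribution split; reported, not pinned
  expect_gt(nonfood_share, 0.2)
  expect_lt(nonfood_share, 0.9)
})

test_that("noiseless nonfood surfaces are recovered exactly", {
  cfg <- synth_config(residual_sd = c(moderate = 0, severe = 0), seed = 17)
  gp <- generate_panel(cfg)
  beta <- list(
    moderate = cfg$true_params$levels$moderate$beta,
    severe = cfg$true_params$levels$severe$beta
  )
  fit <- fit_nonfood(gp$panel, beta, anchors = gp$truth$anchors)
  for (lv in c("moderate", "severe")) {
    truth <- cfg$true_params$levels[[lv]]
    est <- fit$levels[[lv]]
    expect_equal(est$alpha[["estimate"]], truth$alpha[["estimate"]],
                 tolerance = 1e-10)
    expect_equal(est$gamma[["estimate"]], truth$gamma[["estimate"]],
                 tolerance = 1e-10)
    expect_equal(est$theta[["estimate"]], truth$theta[["estimate"]],
                 tolerance = 1e-10)
  }
})

test_that("fit_nonfood equals explicit normal equations on small designs", {
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    panel <- data.frame(
      pou = runif(n, 0.05, 0.7),
      gdp_pc = runif(n, 100, 5000),
      gini = runif(n, 0.2, 0.7),
      stunting_moderate = runif(n, 0.05, 0.4),
      stunting_severe = runif(n, 0.03, 0.3)
    )
    anchors <- dev_anchors(10000, 0.38, 30)
    beta <- list(moderate = list(low = 0.2, central = 0.35, high = 0.44),
                 severe = list(low = 0.11, central = 0.18, high = 0.28))
    fit <- fit_nonfood(panel, beta, anchors)
    w <- development_score(panel$gdp_pc, panel$gini, anchors)
    X <- cbind(1, w, panel$pou * w)
    s <- panel$stunting_moderate - 0.35 * panel$pou
    ref <- normal_equations_fit(X, s)
    est <- fit$levels$moderate
    expect_equal(unname(c(est$alpha[["estimate"]], est$gamma[["estimate"]],
                          est$theta[["estimate"]])),
                 unname(ref), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are fatal with a diagnostic", {
  panel <- toy_panel()
  panel$gdp_pc <- 20000   # saturated: w constant at 0 -> no slope information
  panel$gini <- 0.2
  panel <- panel[rep(1:3, 3), ]
  beta <- list(moderate = list(low = 0.1, central = 0.2, high = 0.3),
               severe = list(low = 0.1, central = 0.15, high = 0.2))
  expect_error(fit_nonfood(panel, beta, anchors = dev_anchors(10000, 0.38, 30)),
               "rank deficient")
})

test_that("the bilinear prediction reproduces the worked example", {
  p <- predict_stunting(default_params(), x = 0.2, w = 0.5)
  expect_equal(p$moderate, 0.182, tolerance = 1e-12)
  expect_equal(p$severe, 0.136, tolerance = 1e-12)
  expect_equal(p$nomild, 0.682, tolerance = 1e-12)
  # zero regressors return the intercepts
  p0 <- predict_stunting(default_params(), 0, 0)
  expect_equal(p0$moderate, 0.025)
  expect_equal(p0$severe, -0.052)
  # composition closes exactly for arbitrary inputs
  set.seed(2)
  x <- runif(50); w <- runif(50)
  pr <- predict_stunting(default_params(), x, w)
  expect_equal(pr$nomild + pr$moderate + pr$severe, rep(1, 50),
               tolerance = 1e-15)
})

test_that("raising the development score can trade moderate for severe stunting", {
  # on the published surface there are x regions where dy2/dw < 0 while
  # dy3/dw > 0 (children shifting from moderate to severe)
  params <- default_params()
  grid <- expand.grid(x = seq(0, 1, 0.05), w = seq(0, 0.95, 0.05))
  dw <- 0.05
  p1 <- predict_stunting(params, grid$x, grid$w)
  p2 <- predict_stunting(params, grid$x, grid$w + dw)
  shift <- p2$moderate < p1$moderate & p2$severe > p1$severe
  expect_true(any(shift))
  # and the region is the expected one: x above gamma2/|theta2| ~ 0.6
  expect_true(all(grid$x[shift] > 0.55))
})

test_that("holdout validation is perfect without noise and null when shuffled", {
  cfg <- synth_config(residual_sd = c(moderate = 0, severe = 0), seed = 23)
  gp <- generate_panel(cfg)
  fit <- stunting_fit(gp$panel, seed = 23, anchors = gp$truth$anchors)
  # with the generating parameters the holdout is reproduced exactly
  exact <- fit
  exact$params <- gp$truth$params
  expect_equal(unname(validate_model(exact)$correlations), rep(1, 3),
               tolerance = 1e-9)
  # the refitted model re-estimates beta from percentiles, which perturbs
  # the surface slightly; correlations stay near-perfect
  val <- validate_model(fit)
  expect_true(all(val$correlations > 0.98))

  # permutation oracle: predictions independent of observations
  noisy <- generate_panel(synth_config(seed = 24))
  fit2 <- stunting_fit(noisy$panel, seed = 24, anchors = noisy$truth$anchors)
  set.seed(77)
  null_r <- replicate(50, {
    hold <- fit2$holdout
    hold$stunting_moderate <- sample(hold$stunting_moderate)
    hold$stunting_severe <- sample(hold$stunting_severe)
    validate_model(fit2, hold)$correlations[["moderate"]]
  })
  expect_lt(abs(mean(null_r)), 0.15)
  expect_gt(mean(abs(null_r) < 0.4), 0.9)
})

test_that("with realistic noise, holdout correlations land in a plausible band", {
  gp <- generate_panel(synth_config(seed = 31))
  fit <- stunting_fit(gp$panel, seed = 31, anchors = gp$truth$anchors)
  val <- validate_model(fit)
  expect_true(all(val$correlations > 0.5 & val$correlations <= 1))
  expect_equal(nrow(val$scatter), 3 * nrow(fit$holdout))
})

test_that("zero-variance holdout levels flag an undefined correlation", {
  gp <- generate_panel(synth_config(seed = 37))
  fit <- stunting_fit(gp$panel, seed = 37)
  hold <- fit$holdout
  hold$stunting_severe <- 0.1
  expect_warning(val <- validate_model(fit, hold), "zero variance")
  expect_true(is.na(val$correlations[["severe"]]))
})

test_that("the fit object methods are coherent", {
  gp <- generate_panel(synth_config(seed = 41))
  fit <- stunting_fit(gp$panel, seed = 41)
  cf <- coef(fit)
  expect_equal(rownames(cf), c("moderate", "severe"))
  expect_equal(colnames(cf), c("alpha", "beta", "gamma", "theta"))
  pr <- predict(fit, newdata = fit$holdout)
  expect_equal(nrow(pr), nrow(fit$holdout))
  res <- residuals(fit, "moderate")
  expect_length(res, nrow(fit$train))
  expect_output(print(fit), "Bilinear stunting model")
  expect_output(print(summary(fit)), "Holdout validation")
  # parameter file round-trip
  path <- tempfile(fileext = ".json")
  write_params(fit$params, path)
  back <- read_params(path)
  expect_equal(as.data.frame(back), as.data.frame(fit$params),
               tolerance = 1e-12)
})
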