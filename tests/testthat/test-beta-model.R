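test_that("standardization hits mean 0, sd 1 and records its transforms", {
  set.seed(1)
  dat <- tibble::tibble(year = 1:50, a = rnorm(50, 3, 2), b = runif(50))
  z <- standardize_predictors(dat)
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(sd(z$b), 1, tolerance = 1e-12)
  tr <- attr(z, "standardization")
  expect_equal((dat$a - tr$center[tr$term == "a"]) / tr$scale[tr$term == "a"],
               z$a)
  expect_error(standardize_predictors(tibble::tibble(year = 1:5, c = rep(1, 5))),
               "constant column")
})

test_that("collinearity check flags perfectly opposed and duplicated pairs", {
  set.seed(2)
  x <- rnorm(100)
  dat <- tibble::tibble(a = x, b = -x, c = rnorm(100))
  rep <- collinearity_check(dat, c("a", "b", "c"))
  expect_true(rep$flagged[rep$term1 == "a" & rep$term2 == "b"])
  expect_equal(rep$r[rep$term1 == "a" & rep$term2 == "b"], -1)
  expect_equal(nrow(collinearity_check(dat, "a")), 0L)

  set.seed(3)
  big <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 4), 500, 4)))
  expect_false(any(collinearity_check(big, names(big))$flagged))
})

test_that("a balanced response gives a near-zero intercept", {
  set.seed(4)
  dat <- tibble::tibble(y = as.numeric(rescale_unit(0, n = 40)) +
                          rnorm(40, 0, 0.02))
  f <- fit_beta_regression(dat, "y", character(0))
  expect_lt(abs(f$beta[["(Intercept)"]]), 0.05)
})

test_that("the MLE recovers generating coefficients from the truth bundle", {
  cfg <- sim_config(n_years = 2000, n_regions = 4, series_per_region = 2,
                    precision_phi = 50, seed = 3)
  st <- simulate_mast_study(cfg)
  tab <- st$truth$components
  tab$y <- st$truth$m_latent
  tab$ar1_term <- st$truth$ar_series
  preds <- c("high_summer_Ym2", "high_winter_Ym1", "high_summer_Ym1",
             "high_spring_Ym", "low_winter", "ar1_term")
  f <- fit_beta_regression(tab, "y", preds, allow_collinear = TRUE)
  truth <- c(`(Intercept)` = 0, high_summer_Ym2 = -0.500,
             high_winter_Ym1 = 0.174, high_summer_Ym1 = 0.373,
             high_spring_Ym = 0.514, low_winter = 0.402, ar1_term = -0.633)
  expect_lt(max(abs(f$beta - truth)), 0.05)
  expect_lt(abs(f$phi - 50) / 50, 0.15)
  # score vanishes at the optimum
  g <- mastnao:::beta_negll_grad(c(f$beta, log(f$phi)), f$X, f$response)
  expect_lt(max(abs(g)), 1e-6)
  # refitting reproduces the AIC
  f2 <- fit_beta_regression(tab, "y", preds, allow_collinear = TRUE)
  expect_equal(f$aic, f2$aic, tolerance = 1e-8)
})

test_that("the collinearity gate blocks duplicated predictors", {
  set.seed(5)
  dat <- simulate_beta_response(60, c(x1 = 0.5), phi = 30)
  dat$x2 <- dat$x1
  expect_error(fit_beta_regression(dat, "y", c("x1", "x2")), "collinear")
  expect_s3_class(fit_beta_regression(dat, "y", c("x1", "x2"),
                                      allow_collinear = TRUE), "beta_fit")
})

test_that("pseudo-R2 equals the squared correlation it is defined as", {
  set.seed(6)
  dat <- simulate_beta_response(80, c(x1 = 0.6, x2 = -0.4), phi = 25)
  f <- fit_beta_regression(dat, "y", c("x1", "x2"))
  direct <- cor(f$linear_predictor, qlogis(dat$y))^2
  expect_equal(f$pseudo_r2, direct)
  # deterministic response: the formula returns exactly 1
  fake <- structure(list(linear_predictor = f$linear_predictor,
                         response = plogis(f$linear_predictor)),
                    class = "beta_fit")
  expect_equal(pseudo_r2(fake), 1)
  # intercept-only: zero-variance linear predictor -> 0 with a warning
  f0 <- fit_beta_regression(dat, "y", character(0))
  expect_warning(r0 <- pseudo_r2(f0), "zero-variance")
  expect_equal(r0, 0)
})

test_that("AIC importance is negative for strong predictors, with errors on absent terms", {
  strong_hits <- 0
  null_pos <- 0
  nsim <- 40
  for (i in seq_len(nsim)) {
    dat <- simulate_beta_response(64, c(x1 = 0.5, x0 = 0), phi = 20,
                                  seed = 1000 + i)
    f <- fit_beta_regression(dat, "y", c("x1", "x0"), allow_collinear = TRUE)
    if (delta_aic(f, "x1") < -5) strong_hits <- strong_hits + 1
    if (delta_aic(f, "x0") > 0) null_pos <- null_pos + 1
  }
  expect_gte(strong_hits / nsim, 0.9)
  expect_gt(null_pos / nsim, 0.5)
  dat <- simulate_beta_response(40, c(x1 = 0.5), phi = 20, seed = 99)
  f <- fit_beta_regression(dat, "y", "x1")
  expect_error(delta_aic(f, "nope"), "not in the model")
  imp <- importance_aic(f)
  expect_equal(imp$term, "x1")
})

test_that("interaction screening returns empty cleanly and respects candidates", {
  set.seed(7)
  dat <- simulate_beta_response(64, c(x1 = 0.4, x2 = 0.3), phi = 30)
  f <- fit_beta_regression(dat, "y", c("x1", "x2"))
  empty <- screen_interactions(f, candidates = list())
  expect_equal(nrow(empty), 0L)
  scr <- screen_interactions(f)
  expect_equal(scr$interaction, "x1:x2")
  expect_true(all(c("slope", "p_value", "selected") %in% names(scr)))
})

test_that("predictions reproduce the fit and invert to the index scale", {
  set.seed(8)
  dat <- simulate_beta_response(50, c(x1 = 0.5, x2 = -0.3), phi = 30)
  f <- fit_beta_regression(dat, "y", c("x1", "x2"))
  expect_equal(predict(f, newdata = dat), f$fitted_mean, tolerance = 1e-12)
  zero <- tibble::tibble(x1 = 0, x2 = 0)
  expect_equal(predict(f, newdata = zero),
               plogis(f$beta[["(Intercept)"]]), ignore_attr = TRUE)
  mu <- predict(f, newdata = dat)
  m <- predict(f, newdata = dat, scale = "m", index_n = 50)
  expect_equal(as.numeric(rescale_unit(m, n = 50)), unname(mu),
               tolerance = 1e-10)
  expect_error(predict(f, newdata = tibble::tibble(x1 = 0)), "lacks predictor")
})

test_that("LOOCV produces one out-of-sample prediction per year", {
  dat <- simulate_beta_response(30, c(x1 = 0.8), phi = 60, seed = 11)
  dat$year <- 1:30
  cv <- loocv_beta(dat, "y", "x1")
  expect_equal(nrow(cv$predictions), 30L)
  expect_true(all(cv$predictions$converged))
  expect_true(is.finite(cv$pearson_r))
  expect_error(loocv_beta(dat[1:5, ], "y", "x1"), "at least 10")
})

test_that("tidy and glance summarize a fit in broom style", {
  dat <- simulate_beta_response(40, c(x1 = 0.5), phi = 30, seed = 12)
  f <- fit_beta_regression(dat, "y", "x1")
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x1"))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  gl <- glance(f)
  expect_equal(gl$aic, 2 * 3 - 2 * gl$log_lik)
  expect_equal(gl$n, 40L)
})
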