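# Noise-free table where food Cd follows 10^(a + b*pH + c*log10(Cs)).
exact_table <- function(a, b, c, pH, cs, crop = "cabbage") {
  n <- length(pH)
  cf <- 10^(a + b * pH + c * log10(cs))
  filler <- function(v) rep(v, n)
  sample_table(tibble::tibble(
    site_id = sprintf("%s_%02d", crop, seq_len(n)), crop = crop, pH = pH,
    soil_Cd = cs, soil_Hg = filler(0.1), soil_As = filler(10),
    soil_Pb = filler(30), soil_Cr = filler(100),
    food_Cd = cf, food_Hg = filler(0.002), food_As = filler(0.005),
    food_Pb = filler(0.05), food_Cr = filler(0.04)
  ))
}

test_that("noise-free data generated from known coefficients refit exactly", {
  tab <- exact_table(-1.845, -0.039, 0.912,
                     pH = c(5.0, 6.1, 6.9, 7.5), cs = c(2, 8, 20, 55))
  fit <- suppressWarnings(fit_transfer(tab, "cabbage", "Cd", screen = FALSE))
  expect_equal(fit$a, -1.845, tolerance = 1e-9)
  expect_equal(fit$b, -0.039, tolerance = 1e-9)
  expect_equal(fit$c, 0.912, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$p, 1e-10)
})

test_that("OLS solution equals the pseudoinverse oracle on random instances", {
  set.seed(40)
  for (i in 1:10) {
    n <- 10
    pH <- stats::runif(n, 4.5, 8)
    cs <- stats::rlnorm(n, 1, 0.8)
    cf <- 10^(-1 - 0.1 * pH + 0.5 * log10(cs) + rnorm(n, 0, 0.3))
    tab <- exact_table(0, 0, 0, pH, cs)
    tab$food_Cd <- cf
    fit <- fit_transfer(tab, "cabbage", "Cd", screen = FALSE)
    beta <- oracle_ols(log10(cf), cbind(1, pH, log10(cs)))
    expect_equal(c(fit$a, fit$b, fit$c), unname(beta), tolerance = 1e-8)
  }
})

test_that("back-transformed prediction matches anchors and stays positive", {
  expect_equal(predict_transfer(c(-1.845, -0.039, 0.912), 6.13, 13.01),
               0.0855364, tolerance = 1e-6)
  expect_equal(predict_transfer(c(0.3, 0, 0), 7, 5), 10^0.3)
  expect_equal(predict_transfer(c(0, 0, 1), 7, 5), 5)
  set.seed(41)
  p <- predict_transfer(c(-2, -0.1, 0.9), stats::runif(50, 4, 8),
                        stats::rlnorm(50, 2, 1))
  expect_true(all(p > 0))
  # monotone in cs when c > 0
  cs <- sort(stats::rlnorm(20, 1, 1))
  expect_true(all(diff(predict_transfer(c(-1, -0.05, 0.8), 6, cs)) > 0))
  expect_error(predict_transfer(c(-1, 0, 1), 6, -3), "positive")
})

test_that("rescaling the soil concentration shifts only the intercept", {
  tab <- generate_dataset(default_generator_config(seed = 8))
  fit <- fit_transfer(tab, "maize", "Cd", screen = FALSE)
  k <- 1000  # e.g. mg/kg -> ug/kg
  tab2 <- tab
  tab2$soil_Cd <- k * tab$soil_Cd
  fit2 <- fit_transfer(tab2, "maize", "Cd", screen = FALSE)
  expect_equal(fit2$c, fit$c, tolerance = 1e-9)
  expect_equal(fit2$b, fit$b, tolerance = 1e-9)
  expect_equal(fit2$a, fit$a - fit$c * log10(k), tolerance = 1e-9)
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-12)
})

test_that("the outlier screen removes a planted high-soil/low-food point", {
  tab <- generate_dataset(default_generator_config(seed = 12))
  maize_ids <- tab$site_id[tab$crop == "maize"]
  planted <- maize_ids[50]
  tab <- plant_outlier(tab, planted, "Cd", soil = 15.5, food = 0.002)
  part <- screen_outliers(tab, "maize", "Cd")
  expect_equal(part$excluded, planted)
  fit <- fit_transfer(tab, "maize", "Cd")
  expect_equal(fit$n, 102L)
  expect_equal(fit$excluded, planted)
})

test_that("the screen is conservative on clean data and refuses mass removal", {
  # false positives need a low studentized residual AND a top-decile soil
  # concentration, so clean datasets are mostly left alone
  n_excluded <- vapply(1:20, function(s) {
    tab <- generate_dataset(default_generator_config(), seed = s)
    length(screen_outliers(tab, "maize", "Cd")$excluded)
  }, numeric(1))
  expect_lt(mean(n_excluded > 0), 0.3)
  expect_lt(max(n_excluded), 3)

  # identical points: zero residuals, nothing to flag
  tab <- exact_table(-1, 0, 0, pH = rep(6, 8), cs = rep(2, 8))
  expect_length(screen_outliers(tab, "cabbage", "Cd")$excluded, 0)

  # the removal guard refuses when flagged points reach max_frac
  tab2 <- generate_dataset(default_generator_config(), seed = 13)
  planted <- tab2$site_id[tab2$crop == "maize"][10]
  tab2 <- plant_outlier(tab2, planted, "Cd", soil = 15.5, food = 0.002)
  expect_error(screen_outliers(tab2, "maize", "Cd", max_frac = 0.005),
               "refusing")
})

test_that("degenerate designs and tiny samples raise clear errors", {
  tab <- exact_table(-1, 0.1, 0.5, pH = c(6, 6.5, 7, 7.5),
                     cs = 10^c(6, 6.5, 7, 7.5))  # log10(cs) == pH
  expect_error(fit_transfer(tab, "cabbage", "Cd", screen = FALSE),
               "collinear")
  tab2 <- exact_table(-1, 0.1, 0.5, pH = c(6, 7, 7.5), cs = c(1, 5, 9))
  expect_error(fit_transfer(tab2, "cabbage", "Cd", screen = FALSE),
               "at least 4")
  tab3 <- exact_table(-1, 0.1, 0.5, pH = stats::runif(10, 5, 8),
                      cs = stats::rlnorm(10))
  expect_error(screen_outliers(tab3[1:5, ], "cabbage", "Cd"), "at least 6")
})

test_that("a raw-concentration regressor is available for sensitivity checks", {
  set.seed(44)
  pH <- stats::runif(12, 5, 8)
  cs <- stats::rlnorm(12, 1, 0.5)
  cf <- 10^(-2 + 0.05 * pH + 0.08 * cs)
  tab <- exact_table(0, 0, 0, pH, cs)
  tab$food_Cd <- cf
  fit <- suppressWarnings(
    fit_transfer(tab, "cabbage", "Cd", screen = FALSE, log_soil = FALSE))
  expect_equal(c(fit$a, fit$b, fit$c), c(-2, 0.05, 0.08), tolerance = 1e-9)
  expect_equal(predict_transfer(fit, pH[1], cs[1]), cf[1], tolerance = 1e-9)
})
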