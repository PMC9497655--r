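# Soil-to-crop transfer regression:
#   log10(Cf) = a + b * pH + c * log10(Cs) + eps
# fitted per crop x metal by ordinary least squares on detected pairs,
# with a declared outlier screen and back-transformed prediction.

#' Screen soil-crop pairs for transfer-model outliers
#'
#' Field surveys occasionally contain sites with very high soil
#' concentrations but anomalously low edible-part concentrations
#' (mixed-in material, sampling artefacts); these leverage points
#' distort the transfer fit. The screen flags points that are *both*
#' strongly below the provisional regression (externally studentized
#' residual `< threshold`, default -2.5) *and* in the upper tail of the
#' crop's soil concentrations (above the `soil_quantile` quantile,
#' default 0.9). It refuses to drop 20% or more of the points, to guard
#' against silent data loss.
#'
#' @param table a [sample_table()].
#' @param crop,metal crop x metal pair to screen.
#' @param threshold studentized-residual cutoff (negative).
#' @param soil_quantile soil-concentration quantile a flagged point must
#'   exceed.
#' @param max_frac maximum tolerated excluded fraction (exclusive).
#' @return List with `kept` and `excluded` site_id vectors.
#' @export
screen_outliers <- function(table, crop, metal, threshold = -2.5,
                            soil_quantile = 0.9, max_frac = 0.2) {
  table <- sample_table(table)
  assert_crop(crop)
  assert_metal(metal)
  stopifnot(threshold < 0, soil_quantile > 0, soil_quantile < 1)
  sub <- table[table$crop == crop, ]
  nd <- sub[[paste0("food_", metal, "_nd")]]
  sub <- sub[!nd, ]
  if (nrow(sub) < 6) {
    stop("need at least 6 detected soil-food pairs to screen (got ",
         nrow(sub), ")", call. = FALSE)
  }
  cs <- sub[[paste0("soil_", metal)]]
  cf <- sub[[paste0("food_", metal)]]
  fit <- lm(log10(cf) ~ sub$pH + log10(cs))
  rs <- rstudent(fit)
  rs[!is.finite(rs)] <- 0  # zero-residual degenerate fits flag nothing
  flagged <- rs < threshold & cs > quantile(cs, soil_quantile, type = 7)
  if (sum(flagged) >= max_frac * nrow(sub)) {
    stop("outlier policy would remove ", sum(flagged), " of ", nrow(sub),
         " points (>= ", round(100 * max_frac), "%); refusing", call. = FALSE)
  }
  list(kept = sub$site_id[!flagged], excluded = sub$site_id[flagged])
}

#' Fit the soil-to-crop transfer regression for one crop and metal
#'
#' Ordinary least squares of `log10(Cf)` on an intercept, soil pH and
#' `log10(Cs)`, using detected (uncensored) pairs only, after the
#' outlier screen of [screen_outliers()]. Reports the coefficient
#' triple, R-squared, the overall F-test p-value (2 and n-3 degrees of
#' freedom), coefficient t-tests, and the residual standard deviation on
#' the log10 scale.
#'
#' Fits are attempted for any metal; for metals with heavy censoring or
#' no soil-plant coupling the result simply carries a low R2 / high p
#' and should be read with the `n`, `r2`, `p` diagnostics in hand.
#'
#' @param table a [sample_table()].
#' @param crop,metal crop x metal pair to fit.
#' @param screen apply the outlier screen first (default TRUE).
#' @param log_soil regress on `log10(Cs)` (default). `FALSE` uses raw
#'   `Cs` as the third regressor, for sensitivity checks only.
#' @param ... passed to [screen_outliers()].
#' @return Object of class `transfer_fit`: list with `crop`, `metal`,
#'   `a`, `b`, `c`, `n`, `r2`, `p`, `resid_sd`, `coef_tests` (tibble),
#'   `excluded` (site ids), `log_soil`.
#' @export
#' @examples
#' tab <- generate_dataset(default_generator_config(seed = 1))
#' fit_transfer(tab, "cabbage", "Cd")
fit_transfer <- function(table, crop, metal, screen = TRUE,
                         log_soil = TRUE, ...) {
  table <- sample_table(table)
  assert_crop(crop)
  assert_metal(metal)
  excluded <- character(0)
  if (screen) {
    part <- screen_outliers(table, crop, metal, ...)
    excluded <- part$excluded
  }
  sub <- table[table$crop == crop & !table$site_id %in% excluded, ]
  nd <- sub[[paste0("food_", metal, "_nd")]]
  sub <- sub[!nd, ]
  n <- nrow(sub)
  if (n < 4) {
    stop("need at least 4 detected pairs to fit (got ", n, ")",
         call. = FALSE)
  }
  cs <- sub[[paste0("soil_", metal)]]
  y <- log10(sub[[paste0("food_", metal)]])
  x_soil <- if (log_soil) log10(cs) else cs
  dat <- data.frame(y = y, pH = sub$pH, xs = x_soil)
  qrX <- qr(cbind(1, dat$pH, dat$xs))
  if (qrX$rank < 3) {
    stop("singular fit: pH and soil-concentration regressors are collinear",
         call. = FALSE)
  }
  fit <- lm(y ~ pH + xs, data = dat)
  sm <- summary(fit)
  cf <- coef(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  r2 <- sm$r.squared
  ct <- as.data.frame(sm$coefficients)
  coef_tests <- tibble::tibble(
    term = c("a", "b", "c"),
    estimate = ct$Estimate,
    se = ct$`Std. Error`,
    t = ct$`t value`,
    p = ct$`Pr(>|t|)`
  )
  structure(list(crop = crop, metal = metal,
                 a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
                 n = n, r2 = r2, p = p, resid_sd = sm$sigma,
                 coef_tests = coef_tests, excluded = excluded,
                 log_soil = log_soil),
            class = "transfer_fit")
}

#' Predict an edible-part concentration from soil pH and concentration
#'
#' Back-transformed prediction `Cf = 10^(a + b*pH + c*log10(Cs))`
#' (or `10^(a + b*pH + c*Cs)` for a raw-soil fit). Always positive;
#' increasing in `Cs` when `c > 0`.
#'
#' @param fit a `transfer_fit`, or a numeric triple `c(a, b, c)`.
#' @param pH soil pH value(s).
#' @param cs soil concentration(s), mg/kg, > 0.
#' @return Predicted edible-part concentration(s), mg/kg.
#' @export
#' @examples
#' predict_transfer(c(-1.845, -0.039, 0.912), pH = 6.13, cs = 13.01)
predict_transfer <- function(fit, pH, cs) {
  if (any(!is.finite(cs) | cs <= 0)) {
    stop("soil concentration must be positive and finite", call. = FALSE)
  }
  if (is.numeric(fit)) {
    stopifnot(length(fit) == 3)
    fit <- list(a = fit[[1]], b = fit[[2]], c = fit[[3]], log_soil = TRUE)
  }
  xs <- if (isTRUE(fit$log_soil)) log10(cs) else cs
  10^(fit$a + fit$b * pH + fit$c * xs)
}

#' @export
print.transfer_fit <- function(x, ...) {
  eq <- sprintf("log10(Cf) = %.4g + %.4g * pH + %.4g * %s", x$a, x$b, x$c,
                if (x$log_soil) "log10(Cs)" else "Cs")
  cat(sprintf("Transfer fit: %s %s (n = %d, %d excluded)\n", x$crop, x$metal,
              x$n, length(x$excluded)))
  cat("  ", eq, "\n", sep = "")
  cat(sprintf("  R2 = %.3f, overall F-test p = %.3g, residual SD = %.3f\n",
              x$r2, x$p, x$resid_sd))
  invisible(x)
}
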