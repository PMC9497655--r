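# Descriptive summaries of concentration data under one fixed set of
# spreadsheet-style estimator conventions, so summary tables are
# comparable across crops and against published survey tables.

#' Descriptive summary of a concentration sample
#'
#' Computes the column set of a conventional survey summary table:
#' n, min, max, mean, SD, CV, quartiles, median, skewness and kurtosis,
#' under fixed estimator conventions:
#'
#' * SD is the n-1 sample standard deviation; CV = SD/mean.
#' * Quartiles interpolate linearly at position `1 + (n-1)p`
#'   (the "inclusive" scheme, [stats::quantile()] type 7).
#' * Skewness is the adjusted Fisher-Pearson estimator
#'   `n/((n-1)(n-2)) * sum(((x - xbar)/s)^3)`.
#' * Kurtosis is adjusted *excess* kurtosis,
#'   `n(n+1)/((n-1)(n-2)(n-3)) * sum(((x - xbar)/s)^4) - 3(n-1)^2/((n-2)(n-3))`.
#'
#' Skewness needs at least 3 values and kurtosis at least 4; below those
#' sizes (or when s = 0) the statistic is reported as `NA`. Censored
#' entries, if a `sample_table` food column is summarised, should be
#' excluded before calling (see [detected_food()]); `n_censored` can be
#' passed through for bookkeeping.
#'
#' @param values numeric vector of detected values (length >= 2).
#' @param n_censored count of censored observations excluded upstream.
#' @return One-row tibble with columns `n`, `n_censored`, `min`, `max`,
#'   `mean`, `sd`, `cv`, `q1`, `median`, `q3`, `skewness`, `kurtosis`.
#' @export
#' @examples
#' describe(c(1, 2, 3, 4, 5))
describe <- function(values, n_censored = 0L) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    stop("need at least 2 detected values to summarise (got ", n, ")",
         call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  cv <- if (s == 0) 0 else if (m > 0) s / m else NA_real_
  z3 <- z4 <- NA_real_
  if (s > 0) {
    z <- (values - m) / s
    z3 <- sum(z^3)
    z4 <- sum(z^4)
  }
  skew <- if (n >= 3 && s > 0) n / ((n - 1) * (n - 2)) * z3 else NA_real_
  kurt <- if (n >= 4 && s > 0) {
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else {
    NA_real_
  }
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(
    n = n, n_censored = as.integer(n_censored),
    min = min(values), max = max(values), mean = m, sd = s, cv = cv,
    q1 = q[1], median = q[2], q3 = q[3], skewness = skew, kurtosis = kurt
  )
}

#' Classify a coefficient of variation
#'
#' Variability labels used when reading survey tables: CV below 0.5 is
#' low, above 1.0 strong; the closed interval `[0.5, 1.0]` is moderate.
#'
#' @param cv non-negative coefficient(s) of variation.
#' @return Character vector: `"low"`, `"moderate"` or `"strong"`.
#' @export
#' @examples
#' classify_cv(c(0.12, 0.5, 1.70))
classify_cv <- function(cv) {
  if (any(!is.finite(cv) | cv < 0)) {
    stop("cv must be finite and non-negative", call. = FALSE)
  }
  ifelse(cv < 0.5, "low", ifelse(cv <= 1.0, "moderate", "strong"))
}

#' Descriptive summary tables per crop, soil and food
#'
#' Applies [describe()] to soil pH, every soil metal, and every food
#' metal of each crop in a sample table. Food entries flagged as
#' non-detect are excluded from the statistics and counted in
#' `n_censored`; variables with fewer than 2 detected values are
#' reported with `NA` statistics.
#'
#' @param table a [sample_table()].
#' @return A tibble with columns `crop`, `matrix` (`"soil"`/`"food"`),
#'   `variable` (`"pH"` or a metal symbol) followed by the [describe()]
#'   columns.
#' @export
describe_table <- function(table) {
  table <- sample_table(table)
  rows <- list()
  for (crop in intersect(crop_types(), unique(table$crop))) {
    sub <- table[table$crop == crop, ]
    add <- function(matrix, variable, values, n_cens = 0L) {
      summ <- if (sum(!is.na(values)) >= 2) {
        describe(values, n_cens)
      } else {
        empty <- describe(c(0, 1))  # template for the column set
        empty[1, ] <- NA
        empty$n <- sum(!is.na(values))
        empty$n_censored <- as.integer(n_cens)
        empty
      }
      dplyr::bind_cols(tibble::tibble(crop = crop, matrix = matrix,
                                      variable = variable), summ)
    }
    rows[[length(rows) + 1]] <- add("soil", "pH", sub$pH)
    for (m in metal_ids()) {
      rows[[length(rows) + 1]] <- add("soil", m, sub[[paste0("soil_", m)]])
      nd <- sub[[paste0("food_", m, "_nd")]]
      rows[[length(rows) + 1]] <-
        add("food", m, sub[[paste0("food_", m)]][!nd], sum(nd))
    }
  }
  dplyr::bind_rows(rows)
}
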