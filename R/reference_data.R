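#' Recognized heavy metals
#'
#' The five metal(loid)s the pipeline handles, in canonical order:
#' cadmium, mercury, arsenic, lead and chromium.
#'
#' @return Character vector `c("Cd", "Hg", "As", "Pb", "Cr")`.
#' @export
metal_ids <- function() c("Cd", "Hg", "As", "Pb", "Cr")

#' Recognized crop types
#'
#' @return Character vector `c("rice", "maize", "cabbage")`.
#' @export
crop_types <- function() c("rice", "maize", "cabbage")

assert_metal <- function(metal) {
  if (!is.character(metal) || !all(metal %in% metal_ids())) {
    stop("unknown metal symbol: ",
         paste(setdiff(as.character(metal), metal_ids()), collapse = ", "),
         "; recognized metals are ", paste(metal_ids(), collapse = ", "),
         call. = FALSE)
  }
  metal
}

assert_crop <- function(crop) {
  if (!is.character(crop) || !all(crop %in% crop_types())) {
    stop("unknown crop type: ",
         paste(setdiff(as.character(crop), crop_types()), collapse = ", "),
         "; recognized crops are ", paste(crop_types(), collapse = ", "),
         call. = FALSE)
  }
  crop
}

#' Soil geochemical background concentrations
#'
#' Reference (background) concentrations used to normalise measured soil
#' concentrations in the geo-accumulation index and the Hakanson potential
#' ecological risk index. Two named sets are bundled:
#'
#' * `"provincial"` — Guizhou provincial soil background values
#'   (Cd 0.66, Hg 0.11, As 20.00, Pb 35.20, Cr 95.90 mg/kg).
#' * `"national"` — Chinese national soil background values
#'   (Cd 0.10, Hg 0.07, As 11.20, Pb 26.00, Cr 61.00 mg/kg).
#'
#' The choice of set changes every index value by a per-metal constant
#' factor, so it must be an explicit, logged decision in any analysis.
#'
#' @param name `"provincial"`, `"national"`, or a named numeric vector
#'   supplying a custom background (must cover all five metals, all > 0).
#' @return Object of class `background_set`: a list with `name` and
#'   `values` (named numeric, mg/kg).
#' @export
#' @examples
#' background_set("national")$values[["Cd"]]
background_set <- function(name = c("provincial", "national")) {
  if (is.numeric(name)) {
    values <- name
    name <- "custom"
  } else {
    name <- match.arg(name)
    values <- switch(name,
      provincial = c(Cd = 0.66, Hg = 0.11, As = 20.00, Pb = 35.20, Cr = 95.90),
      national   = c(Cd = 0.10, Hg = 0.07, As = 11.20, Pb = 26.00, Cr = 61.00)
    )
  }
  missing <- setdiff(metal_ids(), names(values))
  if (length(missing) > 0) {
    stop("background set is missing metals: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  values <- values[metal_ids()]
  if (any(!is.finite(values) | values <= 0)) {
    stop("background concentrations must be positive and finite", call. = FALSE)
  }
  structure(list(name = name, values = values), class = "background_set")
}

#' Toxicity constants: response factors, reference doses, slope factors
#'
#' Per-metal constants used by the ecological and dietary risk models:
#'
#' * `tf` — Hakanson toxic-response factors (Cd 30, Hg 40, As 10, Pb 5,
#'   Cr 2), dimensionless weights in the potential ecological risk index.
#' * `rfd` — oral reference doses in mg/(kg d): Cr 3e-3, As 3e-4,
#'   Cd 1e-3, Pb 3.5e-3. No RfD is provided for Hg, so Hg is excluded
#'   from hazard quotients unless the caller supplies one.
#' * `sf` — oral cancer slope factors in (mg/(kg d))^-1: Cr 0.50,
#'   As 1.50, Cd 0.0038, Pb 0.0085. No SF for Hg, same exclusion rule.
#'
#' @param rfd,sf optional named numeric overrides/extensions, e.g.
#'   `sf = c(Hg = ...)` to bring Hg into the carcinogenic assessment.
#' @return Object of class `toxicity_table`: list with named numeric
#'   vectors `tf`, `rfd`, `sf`.
#' @export
toxicity_table <- function(rfd = NULL, sf = NULL) {
  tab <- list(
    tf  = c(Cd = 30, Hg = 40, As = 10, Pb = 5, Cr = 2),
    rfd = c(Cr = 3e-3, As = 3e-4, Cd = 1e-3, Pb = 3.5e-3),
    sf  = c(Cr = 0.50, As = 1.50, Cd = 0.0038, Pb = 0.0085)
  )
  if (!is.null(rfd)) {
    assert_metal(names(rfd))
    tab$rfd[names(rfd)] <- rfd
  }
  if (!is.null(sf)) {
    assert_metal(names(sf))
    tab$sf[names(sf)] <- sf
  }
  stopifnot(all(tab$rfd > 0), all(tab$sf > 0))
  structure(tab, class = "toxicity_table")
}

#' Dietary exposure profiles for children and adults
#'
#' Exposure parameters for the two consumer populations of the study
#' region: body weight (children 16 kg, adults 61.75 kg), exposure
#' duration (10 / 30 years), exposure frequency 365 d/year, and per-crop
#' ingestion rates in kg/d (rice 0.14 / 0.32; maize and cabbage
#' 0.100 / 0.150 for children / adults). Averaging time is ED x 365 d,
#' so at the default EF the daily-intake kernel reduces to IR/BW.
#'
#' @param population `"child"` or `"adult"`.
#' @param bw,ed,ef,ir optional overrides (body weight kg, exposure
#'   duration years, exposure frequency d/year, named ingestion-rate
#'   vector kg/d over crops).
#' @return Object of class `exposure_profile`.
#' @export
#' @examples
#' exposure_profile("child")$ir[["rice"]]
exposure_profile <- function(population = c("child", "adult"),
                             bw = NULL, ed = NULL, ef = 365, ir = NULL) {
  population <- match.arg(population)
  defaults <- switch(population,
    child = list(bw = 16, ed = 10,
                 ir = c(rice = 0.14, maize = 0.100, cabbage = 0.100)),
    adult = list(bw = 61.75, ed = 30,
                 ir = c(rice = 0.32, maize = 0.150, cabbage = 0.150))
  )
  bw <- bw %||% defaults$bw
  ed <- ed %||% defaults$ed
  ir_full <- defaults$ir
  if (!is.null(ir)) {
    assert_crop(names(ir))
    ir_full[names(ir)] <- ir
  }
  stopifnot(bw > 0, ed > 0, ef > 0, all(ir_full > 0))
  structure(list(population = population, bw = bw, ed = ed, ef = ef,
                 ir = ir_full),
            class = "exposure_profile")
}

#' Survey-mean concentrations bundled as reference inputs
#'
#' Published per-crop mean concentrations from the karst farmland survey
#' the package models: soil means (with pH) and edible-part means, in
#' mg/kg dry weight. Food means are over detected samples only; `NA`
#' marks metals undetected in every sample of a crop (Hg in rice and
#' maize). These feed the desk-scale worked examples and the default
#' synthetic-data configuration.
#'
#' @return A tibble with columns `crop`, `matrix` (`"soil"` or `"food"`),
#'   `metal` (or `"pH"` for soil), and `mean`.
#' @export
reference_means <- function() {
  soil <- tibble::tribble(
    ~crop,     ~pH,  ~Cd,   ~Hg,  ~As,   ~Pb,    ~Cr,
    "rice",    6.05, 1.17,  0.11, 13.57, 39.01,  137.57,
    "maize",   6.35, 2.96,  0.25, 31.75, 71.69,  168.98,
    "cabbage", 6.13, 13.01, 0.14, 24.77, 320.60, 163.83
  )
  food <- tibble::tribble(
    ~crop,     ~Cd,   ~Hg,   ~As,   ~Pb,   ~Cr,
    "rice",    0.071, NA,    0.052, 0.020, 0.355,
    "maize",   0.032, NA,    0.003, 0.056, 0.070,
    "cabbage", 0.082, 0.002, 0.006, 0.141, 0.039
  )
  soil_long <- tidyr::pivot_longer(soil, -"crop", names_to = "metal",
                                   values_to = "mean")
  soil_long$matrix <- "soil"
  food_long <- tidyr::pivot_longer(food, -"crop", names_to = "metal",
                                   values_to = "mean")
  food_long$matrix <- "food"
  out <- dplyr::bind_rows(soil_long, food_long)
  out[, c("crop", "matrix", "metal", "mean")]
}

#' Mean food concentrations for one crop as a named vector
#'
#' Convenience accessor over [reference_means()]: detected-sample means
#' of the edible-part concentrations for `crop`, dropping metals that
#' were never detected.
#'
#' @param crop one of `"rice"`, `"maize"`, `"cabbage"`.
#' @return Named numeric vector (mg/kg) over the detected metals.
#' @export
reference_food_means <- function(crop) {
  assert_crop(crop)
  ref <- reference_means()
  ref <- ref[ref$crop == crop & ref$matrix == "food" & !is.na(ref$mean), ]
  stats::setNames(ref$mean, ref$metal)
}
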