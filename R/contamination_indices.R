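# Soil contamination scoring: geo-accumulation index (Igeo) with the
# seven-class scheme, and Hakanson potential ecological risk (single-metal
# Er and combined R) with grading.

igeo_labels <- c(
  "Uncontaminated",
  "Uncontaminated to moderately contaminated",
  "Moderately contaminated",
  "Moderately to heavily contaminated",
  "Heavily contaminated",
  "Heavily to extremely contaminated",
  "Extremely contaminated"
)

er_grade_labels <- c("slight", "moderate", "high", "very high",
                     "extremely high")

#' Geo-accumulation index
#'
#' `Igeo = log2(Cs / (1.5 * Bn))`: measured soil concentration against
#' 1.5 times a geochemical background. The factor 1.5 absorbs natural
#' lithogenic variation of the background.
#'
#' @param cs measured soil concentration(s), mg/kg, > 0.
#' @param bn background concentration(s), mg/kg, > 0.
#' @return Dimensionless index, vectorised over `cs`/`bn`.
#' @export
#' @examples
#' igeo(2.96, 0.66)
igeo <- function(cs, bn) {
  if (any(!is.finite(cs) | cs <= 0)) {
    stop("soil concentration must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(bn) | bn <= 0)) {
    stop("background concentration must be positive and finite", call. = FALSE)
  }
  log2(cs / (1.5 * bn))
}

#' Classify a geo-accumulation index value
#'
#' Seven classes: class 0 (`Igeo < 0`, uncontaminated) through class 6
#' (`Igeo >= 5`, extremely contaminated); classes 1-5 cover the unit
#' intervals `[k-1, k)`. Every finite value maps to exactly one class
#' (the half-open convention is carried through the top boundary, so
#' `Igeo = 5` falls in class 6).
#'
#' @param value finite Igeo value(s).
#' @return Tibble with columns `value`, `clazz` (integer 0-6), `label`.
#' @export
#' @examples
#' classify_igeo(c(-0.13, 0, 5.51))
classify_igeo <- function(value) {
  if (any(!is.finite(value))) {
    stop("Igeo value must be finite", call. = FALSE)
  }
  clazz <- pmin(pmax(floor(value) + 1L, 0L), 6L)
  tibble::tibble(value = value, clazz = as.integer(clazz),
                 label = igeo_labels[clazz + 1L])
}

#' Grade a single-metal potential ecological risk index
#'
#' Thresholds 40 / 80 / 160 / 320, closed on the left: `Er = 40` is
#' already moderate.
#'
#' @param er non-negative Er value(s).
#' @return Character vector of grades.
#' @export
grade_er <- function(er) {
  if (any(!is.finite(er) | er < 0)) {
    stop("Er must be finite and non-negative", call. = FALSE)
  }
  idx <- findInterval(er, c(40, 80, 160, 320)) + 1L
  er_grade_labels[idx]
}

#' Grade a combined potential ecological risk index
#'
#' Thresholds 150 / 300 / 600 / 1200, closed on the left.
#'
#' @param r non-negative R value(s).
#' @return Character vector of grades.
#' @export
grade_r <- function(r) {
  if (any(!is.finite(r) | r < 0)) {
    stop("R must be finite and non-negative", call. = FALSE)
  }
  idx <- findInterval(r, c(150, 300, 600, 1200)) + 1L
  er_grade_labels[idx]
}

#' Hakanson potential ecological risk for one soil sample (or mean)
#'
#' Single-metal index `Er = TF * Ci / CB` (toxic-response factor times
#' the contamination factor) and the combined index `R = sum(Er)` over
#' the included metals, with grades for both. Because Er is linear in
#' the measured concentration, the mean of per-sample Er equals the Er
#' of the mean concentration.
#'
#' @param soil named numeric vector of soil concentrations (mg/kg),
#'   values > 0; names are metal symbols.
#' @param background a [background_set()] (reference concentrations CB).
#'   National background values are the conventional reference; the
#'   choice rescales each Er by a constant and must be deliberate.
#' @param toxicity a [toxicity_table()] supplying TF.
#' @param metals metals to include in R (default: all metals present in
#'   `soil`).
#' @return Object of class `eco_risk`: list with `er`, `er_grade`
#'   (named over metals), `r`, `r_grade`, and `background` (set name).
#' @export
#' @examples
#' potential_ecological_risk(c(Cd = 13.01, Hg = 0.14, As = 24.77,
#'                             Pb = 320.6, Cr = 163.83),
#'                           background_set("national"))
potential_ecological_risk <- function(soil,
                                      background = background_set("national"),
                                      toxicity = toxicity_table(),
                                      metals = names(soil)) {
  assert_metal(names(soil))
  assert_metal(metals)
  if (any(!is.finite(soil) | soil <= 0)) {
    stop("soil concentrations must be positive and finite", call. = FALSE)
  }
  if (!inherits(background, "background_set")) background <- background_set(background)
  missing <- setdiff(metals, names(background$values))
  if (length(missing) > 0) {
    stop("background set lacks metal(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  soil <- soil[metals]
  er <- toxicity$tf[metals] * soil / background$values[metals]
  r <- sum(er)
  structure(list(er = er, er_grade = setNames(grade_er(er), metals),
                 r = r, r_grade = grade_r(r),
                 background = background$name),
            class = "eco_risk")
}

#' Per-sample contamination indices for a whole survey table
#'
#' Long-format Igeo and Er for every site and metal, plus per-site
#' combined risk R. Igeo conventionally uses the local (provincial)
#' background that describes the regional lithology, while Er uses the
#' national reference; both are explicit arguments because the choice
#' rescales every value.
#'
#' @param table a [sample_table()].
#' @param igeo_background,er_background [background_set()]s (or names).
#' @param toxicity a [toxicity_table()].
#' @return List with `by_metal` (tibble: site_id, crop, metal, igeo,
#'   igeo_class, igeo_label, er, er_grade) and `by_site` (tibble:
#'   site_id, crop, r, r_grade).
#' @export
contamination_table <- function(table,
                                igeo_background = background_set("provincial"),
                                er_background = background_set("national"),
                                toxicity = toxicity_table()) {
  table <- sample_table(table)
  if (!inherits(igeo_background, "background_set")) {
    igeo_background <- background_set(igeo_background)
  }
  if (!inherits(er_background, "background_set")) {
    er_background <- background_set(er_background)
  }
  long <- tidyr::pivot_longer(
    table[, c("site_id", "crop", soil_cols())],
    dplyr::all_of(soil_cols()),
    names_to = "metal", names_prefix = "soil_", values_to = "cs"
  )
  long$igeo <- unname(igeo(long$cs, igeo_background$values[long$metal]))
  cls <- classify_igeo(long$igeo)
  long$igeo_class <- cls$clazz
  long$igeo_label <- cls$label
  long$er <- unname(toxicity$tf[long$metal] * long$cs /
                      er_background$values[long$metal])
  long$er_grade <- grade_er(long$er)
  by_site <- long |>
    dplyr::group_by(.data$site_id, .data$crop) |>
    dplyr::summarise(r = sum(.data$er), .groups = "drop")
  by_site$r_grade <- grade_r(by_site$r)
  list(by_metal = long[, c("site_id", "crop", "metal", "igeo", "igeo_class",
                           "igeo_label", "er", "er_grade")],
       by_site = by_site)
}

#' Share of samples per contamination class
#'
#' Percentage of sites in each Igeo class (or Er grade) per crop and
#' metal — the tabular analogue of the stacked class-share figures used
#' to report contamination surveys.
#'
#' @param indices result of [contamination_table()].
#' @param which `"igeo"` or `"er"`.
#' @return Tibble: crop, metal, class/grade, n, share (fraction of the
#'   crop's samples).
#' @export
class_shares <- function(indices, which = c("igeo", "er")) {
  which <- match.arg(which)
  by_metal <- indices$by_metal
  key <- if (which == "igeo") "igeo_label" else "er_grade"
  by_metal |>
    dplyr::count(.data$crop, .data$metal, .data[[key]], name = "n") |>
    dplyr::group_by(.data$crop, .data$metal) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
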