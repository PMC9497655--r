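# Dietary exposure and risk from crop consumption: estimated daily
# intake (EDI), hazard quotients (HQ, THQ) against oral reference doses,
# and carcinogenic risk (CR, TCR) via cancer slope factors, for child
# and adult consumers.

#' Estimated daily intake of a metal via one crop
#'
#' `EDI = C * IR * EF * ED / (BW * AT)` with averaging time
#' `AT = ED * 365` d, so at the default exposure frequency of 365 d/year
#' the expression reduces exactly to `C * IR / BW`. Linear in both the
#' concentration and the ingestion rate.
#'
#' @param conc metal concentration in the edible part, mg/kg (>= 0);
#'   vectorised.
#' @param crop crop consumed (selects the ingestion rate).
#' @param profile an [exposure_profile()].
#' @return Daily intake, mg/(kg body weight x day).
#' @export
#' @examples
#' edi(0.071, "rice", exposure_profile("child"))
edi <- function(conc, crop, profile) {
  assert_crop(crop)
  if (any(!is.finite(conc) | conc < 0)) {
    stop("concentration must be finite and non-negative", call. = FALSE)
  }
  if (!crop %in% names(profile$ir)) {
    stop("exposure profile has no ingestion rate for crop '", crop, "'",
         call. = FALSE)
  }
  at <- profile$ed * 365
  conc * profile$ir[[crop]] * profile$ef * profile$ed / (profile$bw * at)
}

#' Non-carcinogenic hazard from consuming one crop
#'
#' Per-metal hazard quotient `HQ = EDI / RfD` and the total hazard
#' quotient `THQ = sum(HQ)`, with each metal's fractional contribution.
#' Metals without a reference dose (Hg by default) are dropped with a
#' warning; `HQ > 1` flags a non-negligible non-carcinogenic risk.
#'
#' @param food_means named numeric vector of edible-part concentrations
#'   (mg/kg) — typically detected-sample means, or one sample's values.
#' @param crop crop consumed.
#' @param profile an [exposure_profile()].
#' @param toxicity a [toxicity_table()].
#' @return Object of class `hazard_result`: list with `edi`, `hq`
#'   (named), `thq`, `shares` (named, summing to 1 when `thq > 0`),
#'   `exceeds` (named logical, HQ > 1), `population`, `crop`,
#'   `dropped` (metals without an RfD).
#' @export
#' @examples
#' hazard_assessment(reference_food_means("rice"), "rice",
#'                   exposure_profile("child"))
hazard_assessment <- function(food_means, crop, profile,
                              toxicity = toxicity_table()) {
  assert_metal(names(food_means))
  assert_crop(crop)
  dropped <- setdiff(names(food_means), names(toxicity$rfd))
  if (length(dropped) > 0) {
    warning("no reference dose for: ", paste(dropped, collapse = ", "),
            "; excluded from THQ", call. = FALSE)
  }
  metals <- intersect(names(food_means), names(toxicity$rfd))
  if (length(metals) == 0) {
    stop("no metals with a reference dose left to assess", call. = FALSE)
  }
  intake <- vapply(metals, function(m) edi(food_means[[m]], crop, profile),
                   numeric(1))
  hq <- intake / toxicity$rfd[metals]
  thq <- sum(hq)
  shares <- if (thq > 0) hq / thq else hq * NA_real_
  structure(list(edi = intake, hq = hq, thq = thq, shares = shares,
                 exceeds = hq > 1, population = profile$population,
                 crop = crop, dropped = dropped),
            class = "hazard_result")
}

#' Label a carcinogenic risk value
#'
#' Lifetime incremental cancer probability below 1e-6 is negligible,
#' above 1e-4 unacceptable, in between acceptable.
#'
#' @param cr non-negative CR value(s).
#' @return Character vector of labels.
#' @export
label_cr <- function(cr) {
  if (any(!is.finite(cr) | cr < 0)) {
    stop("CR must be finite and non-negative", call. = FALSE)
  }
  ifelse(cr < 1e-6, "negligible", ifelse(cr <= 1e-4, "acceptable",
                                         "unacceptable"))
}

#' Carcinogenic risk from consuming one crop
#'
#' Per-metal carcinogenic risk `CR = EDI * SF` and total `TCR = sum(CR)`
#' over metals with a slope factor, plus fractional contributions and
#' the negligible / acceptable / unacceptable label for each metal.
#'
#' @inheritParams hazard_assessment
#' @return Object of class `cancer_result`: list with `edi`, `cr`,
#'   `tcr`, `shares`, `label` (named), `population`, `crop`, `dropped`.
#' @export
#' @examples
#' carcinogenic_assessment(reference_food_means("rice"), "rice",
#'                         exposure_profile("child"))
carcinogenic_assessment <- function(food_means, crop, profile,
                                    toxicity = toxicity_table()) {
  assert_metal(names(food_means))
  assert_crop(crop)
  dropped <- setdiff(names(food_means), names(toxicity$sf))
  if (length(dropped) > 0) {
    warning("no slope factor for: ", paste(dropped, collapse = ", "),
            "; excluded from TCR", call. = FALSE)
  }
  metals <- intersect(names(food_means), names(toxicity$sf))
  if (length(metals) == 0) {
    stop("no metals with a slope factor left to assess", call. = FALSE)
  }
  intake <- vapply(metals, function(m) edi(food_means[[m]], crop, profile),
                   numeric(1))
  cr <- intake * toxicity$sf[metals]
  tcr <- sum(cr)
  shares <- if (tcr > 0) cr / tcr else cr * NA_real_
  structure(list(edi = intake, cr = cr, tcr = tcr, shares = shares,
                 label = setNames(label_cr(cr), metals),
                 population = profile$population, crop = crop,
                 dropped = dropped),
            class = "cancer_result")
}

#' Per-sample dietary risk across a survey table
#'
#' Runs the EDI/HQ/CR kernel on every site's detected edible-part
#' concentrations (censored entries are skipped), giving the population
#' distribution of risk rather than the risk of the mean. The same
#' kernel backs [hazard_assessment()] / [carcinogenic_assessment()] on
#' supplied means.
#'
#' @param table a [sample_table()].
#' @param profiles list of [exposure_profile()]s to evaluate (default:
#'   child and adult).
#' @param toxicity a [toxicity_table()].
#' @return List with `by_sample` (tibble: site_id, crop, population,
#'   metal, conc, edi, hq, cr) and `summary` (tibble per crop and
#'   population: thq_mean, tcr_mean, frac_thq_gt1, n).
#' @export
risk_by_sample <- function(table,
                           profiles = list(exposure_profile("child"),
                                           exposure_profile("adult")),
                           toxicity = toxicity_table()) {
  table <- sample_table(table)
  long <- tidyr::pivot_longer(
    table[, c("site_id", "crop", food_cols())],
    dplyr::all_of(food_cols()),
    names_to = "metal", names_prefix = "food_", values_to = "conc"
  )
  nd_long <- tidyr::pivot_longer(
    table[, c("site_id", nd_cols())],
    dplyr::all_of(nd_cols()),
    names_to = "metal", values_to = "nd"
  )
  nd_long$metal <- sub("^food_(.*)_nd$", "\\1", nd_long$metal)
  long <- dplyr::left_join(long[, c("site_id", "crop", "metal", "conc")],
                           nd_long, by = c("site_id", "metal"))
  long <- long[!long$nd, c("site_id", "crop", "metal", "conc")]

  per_pop <- lapply(profiles, function(profile) {
    out <- long
    out$population <- profile$population
    out$edi <- out$conc * unname(profile$ir[out$crop]) * profile$ef /
      (profile$bw * 365)
    out$hq <- out$edi / unname(toxicity$rfd[out$metal])
    out$cr <- out$edi * unname(toxicity$sf[out$metal])
    out
  })
  by_sample <- dplyr::bind_rows(per_pop)

  summary <- by_sample |>
    dplyr::group_by(.data$site_id, .data$crop, .data$population) |>
    dplyr::summarise(thq = sum(.data$hq, na.rm = TRUE),
                     tcr = sum(.data$cr, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::group_by(.data$crop, .data$population) |>
    dplyr::summarise(n = dplyr::n(),
                     thq_mean = mean(.data$thq),
                     tcr_mean = mean(.data$tcr),
                     frac_thq_gt1 = mean(.data$thq > 1),
                     .groups = "drop")
  list(by_sample = by_sample, summary = summary)
}
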