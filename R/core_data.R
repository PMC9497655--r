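# Paired soil-crop sample tables: construction, validation, CSV I/O,
# and non-detect (ND) bookkeeping.
#
# Internal layout: one row per monitoring site, columns
#   site_id, crop, pH,
#   soil_Cd .. soil_Cr   (numeric, mg/kg dry weight, never censored),
#   food_Cd .. food_Cr   (numeric, mg/kg dry weight, NA when censored),
#   food_Cd_nd .. food_Cr_nd (logical censoring flags).
# Unrecognized columns (e.g. coordinates) are carried through untouched.

soil_cols <- function() paste0("soil_", metal_ids())
food_cols <- function() paste0("food_", metal_ids())
nd_cols <- function() paste0("food_", metal_ids(), "_nd")

#' Construct and validate a paired soil-crop sample table
#'
#' Validates a data frame of paired soil and edible-part concentrations
#' against the pipeline's contract: known crops, pH within 0-14, soil
#' concentrations present and positive for all five metals, food
#' concentrations positive where detected and `NA` exactly where the
#' censoring flag is set, and unique site identifiers. Missing censoring
#' flag columns are created (all `FALSE`, except where the food value is
#' `NA`, which is rejected unless flagged).
#'
#' @param x data frame with columns `site_id`, `crop`, `pH`,
#'   `soil_Cd` .. `soil_Cr`, `food_Cd` .. `food_Cr` and optionally
#'   `food_*_nd` logical flags. Extra columns are passed through.
#' @return A `sample_table` (tibble subclass).
#' @export
sample_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("site_id", "crop", "pH", soil_cols(), food_cols())
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$site_id <- as.character(x$site_id)
  if (anyDuplicated(x$site_id)) {
    stop("site_id values must be unique; duplicated: ",
         paste(unique(x$site_id[duplicated(x$site_id)]), collapse = ", "),
         call. = FALSE)
  }
  assert_crop(as.character(x$crop))
  x$crop <- as.character(x$crop)
  if (any(!is.finite(x$pH) | x$pH < 0 | x$pH > 14)) {
    bad <- which(!is.finite(x$pH) | x$pH < 0 | x$pH > 14)
    stop("pH outside [0, 14] at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in nd_cols()) {
    if (!col %in% names(x)) {
      # absent flag column: treat NA food values as censored
      val_col <- sub("_nd$", "", col)
      x[[col]] <- is.na(x[[val_col]])
    }
    x[[col]] <- as.logical(x[[col]])
  }
  for (m in metal_ids()) {
    sc <- paste0("soil_", m)
    if (any(is.na(x[[sc]]))) {
      stop("soil concentrations may not be censored or missing (",
           sc, ", row(s) ", paste(which(is.na(x[[sc]])), collapse = ", "), ")",
           call. = FALSE)
    }
    if (any(x[[sc]] <= 0)) {
      stop("non-positive soil concentration in ", sc, " at row(s): ",
           paste(which(x[[sc]] <= 0), collapse = ", "), call. = FALSE)
    }
    fc <- paste0("food_", m)
    nd <- x[[paste0(fc, "_nd")]]
    if (any(is.na(nd))) {
      stop("censoring flags must be TRUE/FALSE (", fc, "_nd)", call. = FALSE)
    }
    if (any(nd & !is.na(x[[fc]]))) {
      bad <- which(nd & !is.na(x[[fc]]))
      stop("censored entries carry no numeric value (", fc, ", row(s) ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    if (any(!nd & is.na(x[[fc]]))) {
      bad <- which(!nd & is.na(x[[fc]]))
      stop("missing food concentration without ND flag (", fc, ", row(s) ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    detected <- !nd
    if (any(detected & x[[fc]] <= 0)) {
      bad <- which(detected & x[[fc]] <= 0)
      stop("non-positive food concentration in ", fc, " at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(x) <- c("sample_table", class(x))
  x
}

#' Read a paired soil-crop sample table from CSV
#'
#' Parses a UTF-8, dot-decimal CSV with one row per monitoring site.
#' Food-concentration cells equal to the non-detect token (default
#' `"ND"`) become censored entries: the numeric value is dropped and the
#' corresponding flag column is set. Soil cells must always be numeric.
#'
#' @param path path to the CSV file.
#' @param nd_token string marking a non-detect cell in food columns.
#' @return A validated [sample_table()].
#' @export
read_samples <- function(path, nd_token = "ND") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  attr(raw, "spec") <- NULL
  attr(raw, "problems") <- NULL
  required <- c("site_id", "crop", "pH", soil_cols(), food_cols())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    empty <- raw
    for (col in c("pH", soil_cols(), food_cols())) empty[[col]] <- numeric(0)
    for (col in nd_cols()) empty[[col]] <- logical(0)
    return(sample_table(empty))
  }
  parse_num <- function(chr, col) {
    out <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & is.na(out))
    if (length(bad) > 0) {
      stop("non-numeric value in column ", col, " at row(s): ",
           paste(bad, collapse = ", "), " (", paste(chr[bad], collapse = ", "),
           ")", call. = FALSE)
    }
    out
  }
  out <- raw
  out$pH <- parse_num(raw$pH, "pH")
  for (col in soil_cols()) {
    if (any(raw[[col]] == nd_token, na.rm = TRUE)) {
      stop("soil column ", col, " contains the ND token; ",
           "soil concentrations may not be censored", call. = FALSE)
    }
    out[[col]] <- parse_num(raw[[col]], col)
  }
  for (col in food_cols()) {
    nd <- !is.na(raw[[col]]) & raw[[col]] == nd_token
    vals <- raw[[col]]
    vals[nd] <- NA_character_
    out[[col]] <- parse_num(vals, col)
    out[[paste0(col, "_nd")]] <- nd
  }
  sample_table(out)
}

#' Write a sample table to CSV
#'
#' Inverse of [read_samples()]: censored food cells are emitted as the
#' ND token and numeric cells with enough digits to round-trip doubles
#' bit-for-bit.
#'
#' @param table a [sample_table()].
#' @param path output CSV path.
#' @param nd_token string to write for censored cells.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path, nd_token = "ND") {
  table <- sample_table(table)
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out <- table
  out$pH <- fmt(table$pH)
  for (col in soil_cols()) out[[col]] <- fmt(table[[col]])
  for (m in metal_ids()) {
    fc <- paste0("food_", m)
    nd <- table[[paste0(fc, "_nd")]]
    out[[fc]] <- ifelse(nd, nd_token, fmt(table[[fc]]))
  }
  out <- out[, setdiff(names(out), nd_cols())]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Count non-detects per metal for one crop
#'
#' @param table a [sample_table()].
#' @param crop crop to tabulate.
#' @return Named integer vector over the five metals: number of censored
#'   edible-part entries.
#' @export
#' @examples
#' tab <- generate_dataset(default_generator_config(seed = 1))
#' nd_counts(tab, "rice")
nd_counts <- function(table, crop) {
  table <- sample_table(table)
  assert_crop(crop)
  sub <- table[table$crop == crop, ]
  if (nrow(sub) == 0) {
    stop("no samples for crop '", crop, "' in table", call. = FALSE)
  }
  vapply(metal_ids(), function(m) sum(sub[[paste0("food_", m, "_nd")]]),
         integer(1))
}

#' Substitute non-detects by a fixed value (optional policy, off by default)
#'
#' Left-censored food entries are excluded from all statistics by
#' default, because detection limits are reported in digest-solution
#' units that cannot be converted to dry-weight concentrations without
#' unreported digestion masses. When an LOD in mg/kg *is* available,
#' this helper applies the conventional LOD/2 substitution so the
#' sensitivity of downstream results to the censoring policy can be
#' checked.
#'
#' @param table a [sample_table()].
#' @param lod named numeric vector, mg/kg, per metal to substitute.
#' @param fraction multiplier on the LOD (default 0.5).
#' @return A new `sample_table` with flagged entries replaced by
#'   `fraction * lod` and their censoring flags cleared.
#' @export
substitute_nd <- function(table, lod, fraction = 0.5) {
  table <- sample_table(table)
  assert_metal(names(lod))
  stopifnot(all(lod > 0), fraction > 0)
  for (m in names(lod)) {
    fc <- paste0("food_", m)
    nd <- table[[paste0(fc, "_nd")]]
    table[[fc]][nd] <- fraction * lod[[m]]
    table[[paste0(fc, "_nd")]][nd] <- FALSE
  }
  sample_table(table)
}

#' Detected food concentrations for one crop and metal
#'
#' @param table a [sample_table()].
#' @param crop,metal selection.
#' @return Numeric vector of detected (uncensored) edible-part
#'   concentrations.
#' @export
detected_food <- function(table, crop, metal) {
  table <- sample_table(table)
  assert_crop(crop)
  assert_metal(metal)
  sub <- table[table$crop == crop, ]
  sub[[paste0("food_", metal)]][!sub[[paste0("food_", metal, "_nd")]]]
}
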