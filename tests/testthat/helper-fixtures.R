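# Shared fixtures and independent oracles.

# A tiny hand-built paired-sample table: 2 rice, 1 maize, 1 cabbage.
tiny_table <- function() {
  sample_table(tibble::tibble(
    site_id = c("s1", "s2", "s3", "s4"),
    crop = c("rice", "rice", "maize", "cabbage"),
    pH = c(6.05, 5.47, 6.30, 6.12),
    soil_Cd = c(0.84, 1.63, 2.21, 6.78),
    soil_Hg = c(0.09, 0.13, 0.19, 0.12),
    soil_As = c(7.74, 12.70, 22.50, 19.90),
    soil_Pb = c(29.30, 39.20, 47.80, 196.00),
    soil_Cr = c(131.00, 198.00, 137.00, 168.00),
    food_Cd = c(0.034, 0.080, 0.021, 0.054),
    food_Hg = c(NA, NA, NA, 0.002),
    food_As = c(0.051, 0.082, 0.003, 0.004),
    food_Pb = c(0.013, NA, 0.014, 0.064),
    food_Cr = c(0.143, 0.568, 0.050, 0.037)
  ))
}

# CSV text for the same table, with ND tokens, for parser tests.
tiny_csv <- function(path) {
  writeLines(c(
    "site_id,crop,pH,soil_Cd,soil_Hg,soil_As,soil_Pb,soil_Cr,food_Cd,food_Hg,food_As,food_Pb,food_Cr",
    "s1,rice,6.05,0.84,0.09,7.74,29.30,131.00,0.034,ND,0.051,0.013,0.143",
    "s2,rice,5.47,1.63,0.13,12.70,39.20,198.00,0.080,ND,0.082,ND,0.568",
    "s3,maize,6.30,2.21,0.19,22.50,47.80,137.00,0.021,ND,0.003,0.014,0.050",
    "s4,cabbage,6.12,6.78,0.12,19.90,196.00,168.00,0.054,0.002,0.004,0.064,0.037"
  ), path)
  path
}

# Brute-force quartile oracle: sort and interpolate at position 1+(n-1)p.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- 1 + (length(x) - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent OLS oracle via the Moore-Penrose pseudoinverse.
oracle_ols <- function(y, X) {
  s <- svd(X)
  drop(s$v %*% ((t(s$u) %*% y) / s$d))
}

# Plant one high-soil / low-food point into a sample table.
plant_outlier <- function(tab, site_id, metal, soil, food) {
  tab[tab$site_id == site_id, paste0("soil_", metal)] <- soil
  tab[tab$site_id == site_id, paste0("food_", metal)] <- food
  tab[tab$site_id == site_id, paste0("food_", metal, "_nd")] <- FALSE
  sample_table(tab)
}
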