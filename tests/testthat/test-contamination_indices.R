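test_that("geo-accumulation index matches closed-form anchor points", {
  expect_equal(igeo(1.5 * 0.66, 0.66), 0)
  expect_equal(igeo(3 * 0.66, 0.66), 1)
  # log2(2.96 / (1.5 * 0.66)) = log2(2.96 / 0.99)
  expect_equal(igeo(2.96, 0.66), log(2.96 / 0.99, 2))
  expect_equal(round(igeo(2.96, 0.66), 3), 1.580)
  expect_error(igeo(0, 1), "positive")
  expect_error(igeo(1, -2), "positive")
})

test_that("doubling the soil concentration raises Igeo by exactly 1", {
  set.seed(10)
  cs <- stats::rlnorm(50, 0, 1.5)
  bn <- stats::runif(50, 0.05, 100)
  expect_equal(igeo(2 * cs, bn), igeo(cs, bn) + 1)
  # monotonicity in both arguments
  expect_true(all(igeo(cs * 1.01, bn) > igeo(cs, bn)))
  expect_true(all(igeo(cs, bn * 1.01) < igeo(cs, bn)))
})

test_that("Igeo classification is total, gap-free, and matches anchors", {
  expect_equal(classify_igeo(-0.13)$clazz, 0L)
  expect_equal(classify_igeo(-0.13)$label, "Uncontaminated")
  expect_equal(classify_igeo(0)$clazz, 1L)
  expect_equal(classify_igeo(5.51)$clazz, 6L)
  expect_equal(classify_igeo(5.51)$label, "Extremely contaminated")
  # boundary at exactly 5 continues the half-open convention
  expect_equal(classify_igeo(5)$clazz, 6L)
  # every finite value maps to exactly one class, step function is monotone
  grid <- sort(c(seq(-3, 8, by = 0.01), 0:6, (0:6) - 1e-9))
  cls <- classify_igeo(grid)$clazz
  expect_true(all(cls %in% 0:6))
  expect_true(all(diff(cls) >= 0))
  expect_error(classify_igeo(Inf), "finite")
})

test_that("Er and R grade thresholds are closed on the left", {
  expect_equal(grade_er(c(39.99, 40, 80, 160, 320, 5000)),
               c("slight", "moderate", "high", "very high",
                 "extremely high", "extremely high"))
  expect_equal(grade_r(c(104.44, 150, 300, 600, 1200)),
               c("slight", "moderate", "high", "very high",
                 "extremely high"))
  # total and gap-free over a fine grid
  g <- grade_er(seq(0, 400, by = 0.25))
  expect_true(all(g %in% c("slight", "moderate", "high", "very high",
                           "extremely high")))
  expect_error(grade_er(-1), "non-negative")
})

test_that("potential ecological risk reproduces the survey-mean anchors", {
  soil_means <- c(Cd = 13.01, Hg = 0.14, As = 24.77, Pb = 320.60, Cr = 163.83)
  res <- potential_ecological_risk(soil_means, background_set("national"))
  # cabbage-soil Cd: 30 * 13.01 / 0.10
  expect_equal(unname(res$er[["Cd"]]), 3903.0)
  expect_equal(unname(res$er_grade[["Cd"]]), "extremely high")
  expect_equal(res$r, sum(res$er))
  expect_equal(res$r_grade, "extremely high")

  # CF = 1 gives Er = TF
  bg <- background_set("national")
  res2 <- potential_ecological_risk(bg$values, bg)
  expect_equal(res2$er, toxicity_table()$tf)

  # rice-soil means against the provincial reference: Cd anchor and a
  # slight combined risk (grade matches the survey's published grading)
  rice <- c(Cd = 1.17, Hg = 0.11, As = 13.57, Pb = 39.01, Cr = 137.57)
  res3 <- potential_ecological_risk(rice, background_set("provincial"))
  expect_equal(unname(res3$er[["Cd"]]), 30 * 1.17 / 0.66)
  expect_lt(abs(res3$er[["Cd"]] - 52.98) / 52.98, 0.01)
  expect_equal(grade_r(104.44), "slight")
  expect_equal(res3$r_grade, "slight")
})

test_that("Er is linear in the concentration and R sums the included metals", {
  set.seed(20)
  bg <- background_set("national")
  for (i in 1:10) {
    soil <- setNames(stats::rlnorm(5, 1, 1), metal_ids())
    k <- stats::runif(1, 0.1, 20)
    r1 <- potential_ecological_risk(soil, bg)
    rk <- potential_ecological_risk(k * soil, bg)
    expect_equal(rk$er, k * r1$er)
    expect_equal(r1$r, sum(r1$er))
  }
  # metal exclusion shrinks R accordingly
  soil <- setNames(rep(1, 5), metal_ids())
  part <- potential_ecological_risk(soil, bg, metals = c("Cd", "Hg"))
  expect_equal(part$r, sum(part$er[c("Cd", "Hg")]))
})

test_that("custom background sets must cover all five metals and be positive", {
  expect_error(background_set(c(Cd = 0.1, Hg = 0.07)), "missing metals")
  expect_error(background_set(c(Cd = 0.1, Hg = 0.07, As = 11.2, Pb = 26,
                                Cr = -1)), "positive")
})

test_that("contamination_table is internally consistent and shares sum to 1", {
  tab <- generate_dataset(default_generator_config(seed = 9))
  idx <- contamination_table(tab)
  # per-site R equals the sum of that site's five Er values
  er_sums <- tapply(idx$by_metal$er, idx$by_metal$site_id, sum)
  expect_equal(as.numeric(er_sums[idx$by_site$site_id]), idx$by_site$r)
  sh <- class_shares(idx, "igeo")
  tot <- tapply(sh$share, paste(sh$crop, sh$metal), sum)
  expect_equal(as.numeric(tot), rep(1, length(tot)))
  # swapping the Er background rescales every Er by a per-metal constant
  idx2 <- contamination_table(tab, er_background = background_set("provincial"))
  ratio <- idx$by_metal$er / idx2$by_metal$er
  bgp <- background_set("provincial")$values
  bgn <- background_set("national")$values
  expect_equal(ratio, unname((bgp / bgn)[idx$by_metal$metal]))
})
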