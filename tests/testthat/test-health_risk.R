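test_that("daily intake reduces to conc * IR / BW at EF = 365", {
  child <- exposure_profile("child")
  # 0.071 * 0.14 / 16
  expect_equal(edi(0.071, "rice", child), 6.2125e-4)
  expect_equal(edi(0, "rice", child), 0)
  # linear in the ingestion rate
  double_ir <- exposure_profile("child", ir = c(rice = 0.28))
  expect_equal(edi(0.071, "rice", double_ir), 2 * edi(0.071, "rice", child))
  # ED cancels against AT = ED * 365
  long <- exposure_profile("child", ed = 70)
  expect_equal(edi(0.071, "rice", long), edi(0.071, "rice", child))
  expect_error(edi(-1, "rice", child), "non-negative")
  expect_error(edi(1, "potato", child), "unknown crop")
})

test_that("hazard quotients reproduce the published rice and maize THQ", {
  rice <- c(Cd = 0.071, As = 0.052, Pb = 0.020, Cr = 0.355)
  h_child <- hazard_assessment(rice, "rice", exposure_profile("child"))
  expect_equal(round(h_child$thq, 2), 3.22)
  expect_equal(unname(round(h_child$hq[c("Cd", "As", "Pb", "Cr")], 3)),
               c(0.621, 1.517, 0.050, 1.035))
  expect_equal(unname(h_child$exceeds[c("Cd", "As", "Pb", "Cr")]),
               c(FALSE, TRUE, FALSE, TRUE))
  h_adult <- hazard_assessment(rice, "rice", exposure_profile("adult"))
  expect_equal(round(h_adult$thq, 2), 1.91)

  maize <- c(Cd = 0.032, As = 0.003, Pb = 0.056, Cr = 0.070)
  expect_equal(round(hazard_assessment(maize, "maize",
                                       exposure_profile("child"))$thq, 2),
               0.51)
  expect_equal(round(hazard_assessment(maize, "maize",
                                       exposure_profile("adult"))$thq, 1),
               0.2)
})

test_that("a concentration of RfD * BW / IR gives HQ = 1 exactly", {
  child <- exposure_profile("child")
  conc <- toxicity_table()$rfd[["Cd"]] * child$bw / child$ir[["rice"]]
  h <- hazard_assessment(c(Cd = conc), "rice", child)
  expect_equal(unname(h$hq[["Cd"]]), 1)
})

test_that("metals without toxicity constants are dropped with a warning", {
  means <- c(Cd = 0.082, Hg = 0.002, As = 0.006)
  expect_warning(h <- hazard_assessment(means, "cabbage",
                                        exposure_profile("child")),
                 "Hg")
  expect_equal(h$dropped, "Hg")
  expect_setequal(names(h$hq), c("Cd", "As"))
  expect_error(
    suppressWarnings(hazard_assessment(c(Hg = 0.002), "cabbage",
                                       exposure_profile("child"))),
    "no metals")
  # a supplied Hg RfD brings it back in
  tox <- toxicity_table(rfd = c(Hg = 3e-4))
  h2 <- hazard_assessment(means, "cabbage", exposure_profile("child"), tox)
  expect_true("Hg" %in% names(h2$hq))
})

test_that("carcinogenic risk matches hand-computed anchors and labels", {
  child <- exposure_profile("child")
  cr_as <- carcinogenic_assessment(c(As = 0.052), "rice", child)
  # 0.00875 * 0.052 * 1.5
  expect_equal(unname(cr_as$cr[["As"]]), 6.825e-4)
  expect_equal(unname(cr_as$label[["As"]]), "unacceptable")
  cr_pb <- carcinogenic_assessment(c(Pb = 0.020), "rice", child)
  expect_equal(unname(cr_pb$cr[["Pb"]]), 0.00875 * 0.020 * 0.0085)
  expect_equal(unname(cr_pb$label[["Pb"]]), "acceptable")
  expect_equal(unname(carcinogenic_assessment(c(Cd = 0), "rice",
                                              child)$label[["Cd"]]),
               "negligible")
  expect_equal(label_cr(c(9.9e-7, 1e-6, 1e-4, 1.1e-4)),
               c("negligible", "acceptable", "acceptable", "unacceptable"))
})

test_that("THQ and TCR are additive over metals and linear in concentration", {
  set.seed(30)
  child <- exposure_profile("child")
  for (i in 1:10) {
    means <- setNames(stats::rlnorm(4, -3, 1), c("Cd", "As", "Pb", "Cr"))
    h <- hazard_assessment(means, "maize", child)
    cc <- carcinogenic_assessment(means, "maize", child)
    expect_equal(h$thq, sum(h$hq))
    expect_equal(cc$tcr, sum(cc$cr))
    expect_equal(sum(h$shares), 1, tolerance = 1e-12)
    expect_equal(sum(cc$shares), 1, tolerance = 1e-12)
    k <- stats::runif(1, 0.5, 4)
    expect_equal(hazard_assessment(k * means, "maize", child)$thq, k * h$thq)
    expect_equal(carcinogenic_assessment(k * means, "maize", child)$tcr,
                 k * cc$tcr)
  }
})

test_that("children carry higher risk than adults for every crop and metal", {
  set.seed(31)
  child <- exposure_profile("child")
  adult <- exposure_profile("adult")
  for (crop in crop_types()) {
    means <- setNames(stats::rlnorm(4, -3, 1), c("Cd", "As", "Pb", "Cr"))
    hc <- hazard_assessment(means, crop, child)
    ha <- hazard_assessment(means, crop, adult)
    expect_true(all(hc$hq > ha$hq))
    cc <- carcinogenic_assessment(means, crop, child)
    ca <- carcinogenic_assessment(means, crop, adult)
    expect_true(all(cc$cr > ca$cr))
  }
})

test_that("per-sample risk agrees with the means kernel and summarises", {
  tab <- tiny_table()
  res <- risk_by_sample(tab)
  # one site, one metal, by hand: s1 rice Cd, child
  row <- res$by_sample[res$by_sample$site_id == "s1" &
                         res$by_sample$metal == "Cd" &
                         res$by_sample$population == "child", ]
  expect_equal(row$edi, 0.034 * 0.14 / 16)
  expect_equal(row$hq, 0.034 * 0.14 / 16 / 1e-3)
  expect_equal(row$cr, 0.034 * 0.14 / 16 * 0.0038)
  # censored cells never enter
  expect_false(any(res$by_sample$metal == "Hg" &
                     res$by_sample$crop %in% c("rice", "maize")))
  summ <- res$summary
  expect_true(all(summ$frac_thq_gt1 >= 0 & summ$frac_thq_gt1 <= 1))
  expect_setequal(unique(summ$population), c("child", "adult"))
})
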