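test_that("packaged fixture reproduces the published parameter values", {
  p <- default_parameters()
  # onset schedule endpoints (annual probabilities, decade bands)
  b <- p$onset$breast
  expect_equal(b$p_first[b$age_start == 30], 0.0106)
  expect_equal(b$p_last[b$age_start == 30], 0.0185)
  expect_equal(b$p_first[b$age_start == 70], 0.0666)
  o <- p$onset$ovarian
  expect_equal(o$p_first[o$age_start == 20], 0.000015)
  expect_equal(o$p_last[o$age_start == 60], 0.0433)
  # progression and symptomatic detection
  expect_equal(p$progression$breast, c(0.205, 0.25, 0.60))
  expect_equal(p$progression$ovarian, c(0.70, 0.93, 0.99))
  expect_equal(p$detection$breast, c(0.23, 0.55, 0.60, 1.00))
  expect_equal(p$detection$ovarian, c(0.15, 0.15, 0.72, 0.95))
  # five-year survival and effect measures
  expect_equal(p$surv5$breast, c(0.993, 0.876, 0.595, 0.262))
  expect_equal(p$surv5$ovarian, c(0.871, 0.704, 0.350, 0.155))
  expect_equal(p$effects$rr_breast_pbm, 0.070)
  expect_equal(p$effects$rr_breast_both, 0.039)
  expect_equal(p$effects$rr_ovarian_pbso, 0.038)
  expect_equal(p$effects$rr_ovarian_pbm, 1)
  expect_equal(p$effects$rr_ovarian_both, p$effects$rr_ovarian_pbso)
  # utilities
  expect_equal(p$utilities$well, 0.92)
  expect_equal(p$utilities$detected$breast, c(0.68, 0.61, 0.56, 0.42))
  expect_equal(p$utilities$detected$ovarian, c(0.81, 0.72, 0.63, 0.55))
  expect_equal(unname(p$utilities$surgery), c(0.88, 0.95, 0.84))
  # undetected utilities default to the detected-stage values
  expect_equal(p$utilities$undetected, p$utilities$detected)
  # costs (2022 EUR)
  expect_equal(p$costs$surveillance, 608)
  expect_equal(unname(p$costs$surgery), c(9032, 3099, 12131))
  expect_equal(p$costs$surgery[["both"]],
               p$costs$surgery[["pbm"]] + p$costs$surgery[["pbso"]])
  expect_equal(p$costs$initial$breast["early", "none"], 20092)
  expect_equal(p$costs$initial$breast["metastatic", "pbm"], 24865)
  expect_equal(p$costs$initial$ovarian["nonadvanced", "pbso"], 11280)
  expect_equal(p$costs$initial$ovarian["advanced", "none"], 35052)
  expect_equal(p$costs$followup$breast["s2", "pbm"], 500)
  expect_equal(p$costs$followup$ovarian["advanced", "both"], 1942)
  expect_equal(unname(p$costs$palliative), c(12103, 12103))
  expect_equal(unname(p$costs$followup_years), c(10, 5))
  expect_equal(p$analysis$discount_rate, 0.03)
  expect_equal(p$analysis$wtp, 90000)
})

test_that("parameter files round-trip through the writer and reader", {
  p <- default_parameters()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_parameters(p, tmp)
  p2 <- read_parameters(tmp, mortality = p$mortality)
  for (comp in c("onset", "progression", "detection", "surv5", "surv_annual",
                 "effects", "utilities", "costs", "analysis"))
    expect_equal(p2[[comp]], p[[comp]], info = comp)
})

test_that("onset interpolation is linear within bands and exact at endpoints", {
  p <- default_parameters()
  sch <- p$onset$breast
  expect_equal(interpolate_onset(sch, 30), 0.0106)
  expect_equal(interpolate_onset(sch, 39), 0.0185)
  expect_equal(interpolate_onset(sch, 34), 0.0106 + (4 / 9) * (0.0185 - 0.0106))
  # continuity within a band: consecutive ages differ by the constant slope
  vals <- interpolate_onset(sch, 40:49)
  expect_equal(diff(vals), rep((0.0688 - 0.0326) / 9, 9))
  # every band endpoint is reproduced exactly
  expect_equal(interpolate_onset(sch, sch$age_start), sch$p_first)
  expect_equal(interpolate_onset(sch, sch$age_end), sch$p_last)
  expect_error(interpolate_onset(sch, 19), "outside")
  expect_error(interpolate_onset(sch, 100), "outside")
})

test_that("five-year survival converts to a constant annual rate", {
  expect_equal(annual_survival_from_5yr(1), 1)
  expect_equal(annual_survival_from_5yr(0.993), exp(log(0.993) / 5))
  # round trip: the five-fold self-product recovers the input
  expect_equal(annual_survival_from_5yr(0.155)^5, 0.155, tolerance = 1e-12)
  expect_error(annual_survival_from_5yr(0), "in \\(0,1\\]")
  r <- survival_vector_from_range(0.735, 0.874)
  expect_length(r, 10)
  expect_equal(r[1], 0.735)
  expect_equal(r[10], 0.874)
})

test_that("background mortality removes the cancer component on the rate scale", {
  m <- data.frame(age = 50:53,
                  q_all = c(0.01, 0.005, 0.010, 0.02),
                  q_cancer = c(0, 0.005, 0.002, 0.004))
  expect_equal(background_mortality(m, 50), 0.01)
  expect_equal(background_mortality(m, 51), 0)
  # independent rate-scale arithmetic
  expect_equal(background_mortality(m, 52),
               1 - (1 - 0.010) / (1 - 0.002))
  # monotone increasing in q_all, decreasing in q_cancer
  grid <- expand.grid(qa = seq(0.002, 0.2, length.out = 12),
                      qc = seq(0, 0.002, length.out = 6))
  qo <- 1 - exp(-(-log1p(-grid$qa) + log1p(-grid$qc)))
  for (qc in unique(grid$qc))
    expect_true(all(diff(qo[grid$qc == qc]) > 0))
  for (qa in unique(grid$qa))
    expect_true(all(diff(qo[grid$qa == qa]) < 0))
  expect_error(background_mortality(
    data.frame(age = 1, q_all = 0.001, q_cancer = 0.002), 1), "exceeds")
  expect_error(background_mortality(m, 99), "not defined")
})

test_that("validation rejects malformed parameter sets", {
  p <- default_parameters()
  bad <- p
  bad$onset$breast$age_start[3] <- 41 # gap at 40
  expect_error(validate_params(bad), "contiguous")
  bad <- p
  bad$effects$rr_breast_pbm <- 0
  expect_error(validate_params(bad), "relative risks")
  bad <- p
  bad$mortality$q_cancer[5] <- bad$mortality$q_all[5] + 0.01
  expect_error(validate_params(bad), "exceeds")
  bad <- p
  bad$costs$surgery[["both"]] <- 1
  expect_error(validate_params(bad), "combined surgery")
  bad <- p
  bad$utilities$detected$breast <- c(0.5, 0.6, 0.4, 0.3) # increasing at s2
  expect_error(validate_params(bad), "non-increasing")
})
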