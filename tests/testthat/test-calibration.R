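test_that("predicted stage distribution collapses under immediate detection", {
  p <- default_parameters()
  p$detection$breast <- c(1, 1, 1, 1)
  p$detection$ovarian <- c(1, 1, 1, 1)
  pt <- predict_targets(p)
  expect_equal(pt$stages$value[pt$stages$stage == 1], c(1, 1))
  expect_equal(sum(pt$stages$value), 2)
  # progression zero: all diagnoses at stage 1 whatever the detection
  p2 <- default_parameters()
  p2$progression$breast <- c(0, 0, 0)
  p2$progression$ovarian <- c(0, 0, 0)
  pt2 <- predict_targets(p2)
  expect_equal(pt2$stages$value[pt2$stages$stage == 1], c(1, 1))
})

test_that("predicted band incidence matches a hand-built single-band toy", {
  # constant onset 0.01 in the 30-39 band only, immediate detection, no
  # deaths: diagnoses at age a equal the undetected pool, which is the
  # previous year's onset; person-years at risk = well + undetected
  p <- default_parameters(mortality = flat_mortality(0))
  p <- set_onset_const(p, breast = 0, ovarian = 0)
  p$onset$breast$p_first[p$onset$breast$age_start == 30] <- 0.01
  p$onset$breast$p_last[p$onset$breast$age_start == 30] <- 0.01
  p$detection$breast <- c(1, 1, 1, 1)
  pt <- predict_targets(p)
  b <- pt$incidence[pt$incidence$cancer == "breast" &
                      pt$incidence$age_start == 30, ]
  well <- cumprod(c(1, rep(0.99, 9)))        # well mass at ages 30..39
  onset <- 0.01 * well                        # onset flow in cycles 30..39
  diag <- c(0, onset[1:9])                    # detected one cycle later
  at_risk <- well + c(0, onset[1:9])          # well + undetected pool
  expect_equal(b$value, sum(diag) / sum(at_risk), tolerance = 1e-12)
})

test_that("targets generated from the truth are a calibration fixed point", {
  p <- default_parameters()
  targets <- make_calibration_targets(p, noise_sd = 0)
  res <- calibrate_model(targets, p,
                         control = list(max_outer = 1, pf_iters = 1,
                                        maxit_stage = 20))
  expect_lt(res$objective, 1e-12)
  expect_true(all(unlist(res$onset_scales) > 0.999 &
                    unlist(res$onset_scales) < 1.001))
})

test_that("the objective history is non-increasing", {
  p <- default_parameters()
  targets <- make_calibration_targets(p, noise_sd = 0)
  init <- p
  init$onset$breast$p_first <- init$onset$breast$p_first * 1.15
  init$onset$breast$p_last <- init$onset$breast$p_last * 1.15
  res <- calibrate_model(targets, init,
                         control = list(max_outer = 2, maxit_stage = 40))
  expect_true(all(diff(res$history) <= 1e-12))
  expect_gte(res$objective, 0)
})

test_that("the reported objective is reproducible from the fitted parameters", {
  p <- default_parameters()
  targets <- make_calibration_targets(p, noise_sd = 0)
  init <- p
  init$detection$breast <- init$detection$breast * 0.85
  res <- calibrate_model(targets, init,
                         control = list(max_outer = 1, maxit_stage = 60))
  bands <- unique(targets$incidence[c("age_start", "age_end")])
  pred <- predict_targets(res$params, bands = bands)
  expect_equal(bocprev:::calibration_objective(pred, targets), res$objective,
               tolerance = 1e-12)
  # residual bookkeeping agrees with the objective's ingredients
  expect_equal(
    sum(res$residuals$incidence$weight * res$residuals$incidence$residual^2) +
      sum(res$residuals$stages$weight * res$residuals$stages$residual^2),
    res$objective, tolerance = 1e-12)
})

test_that("calibration targets round-trip through CSV", {
  p <- default_parameters()
  targets <- make_calibration_targets(p, noise_sd = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  d <- rbind(
    data.frame(cancer = targets$incidence$cancer, type = "incidence",
               band_or_stage = paste0(targets$incidence$age_start, "_",
                                      targets$incidence$age_end),
               value = targets$incidence$value,
               weight = targets$incidence$weight),
    data.frame(cancer = targets$stages$cancer, type = "stage",
               band_or_stage = targets$stages$stage,
               value = targets$stages$value,
               weight = targets$stages$weight))
  utils::write.csv(d, tmp, row.names = FALSE)
  t2 <- read_calibration_targets(tmp)
  expect_equal(t2$incidence$value, targets$incidence$value)
  expect_equal(t2$stages$value, targets$stages$value)
  expect_equal(t2$incidence$weight, targets$incidence$weight)
})

test_that("malformed targets are rejected", {
  expect_error(calibration_targets(
    data.frame(cancer = "breast", age_start = 30, age_end = 39, value = 0.01),
    data.frame(cancer = "breast", stage = 1:4, value = c(0.5, 0.2, 0.2, 0.2))),
    "sum to 1")
  expect_error(calibration_targets(
    data.frame(cancer = "breast", age_start = 30, age_end = 39, value = 1.2),
    data.frame(cancer = "breast", stage = 1:4, value = c(0.4, 0.3, 0.2, 0.1))),
    "probabilities")
})
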