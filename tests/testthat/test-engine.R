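test_that("the state space has the expected structure", {
  st <- state_table()
  expect_equal(nrow(st), 96)
  expect_equal(sum(st$kind == "tunnel"), 80)
  expect_equal(sum(st$kind == "undetected"), 8)
  expect_equal(sum(st$kind %in% c("cancer_death", "other_death")), 3)
})

test_that("occupancy is conserved and death states are absorbing", {
  p <- default_parameters()
  for (id in c(1, 8, 12, 16)) {
    tr <- run_cohort(get_strategy(id), p)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(tr$occupancy >= -1e-12))
    for (d in c("death_breast", "death_ovarian", "death_other"))
      expect_true(all(diff(tr$occupancy[, d]) >= -1e-12),
                  info = sprintf("strategy %d, %s", id, d))
  }
})

test_that("with all hazards zero the cohort never leaves the well state", {
  p <- toy_immortal_params()
  tr <- run_cohort(get_strategy(1), p)
  expect_equal(unname(tr$occupancy[, "well"]), rep(1, length(tr$ages)))
  expect_equal(sum(tr$flows[-1]), 0)
})

test_that("undetected stages are detected first, then progress", {
  # unit mass in undetected FIGO III, no background mortality:
  # detection 0.72; of the 0.28 remainder, 0.99 progresses to FIGO IV
  p <- default_parameters(mortality = flat_mortality(0))
  st <- state_table()
  init <- numeric(nrow(st))
  init[st$name == "und_ovarian_FIGO_III"] <- 1
  tr <- run_cohort(get_strategy(1), p, init = init)
  nxt <- tr$occupancy[2, ]
  expect_equal(unname(nxt[["det_ovarian_FIGO_III_y1"]]), 0.72)
  expect_equal(unname(nxt[["und_ovarian_FIGO_IV"]]), 0.28 * 0.99)
  expect_equal(unname(nxt[["und_ovarian_FIGO_III"]]), 0.28 * 0.01)
  # undetected pT4 is always detected within the cycle
  init <- numeric(nrow(st))
  init[st$name == "und_breast_pT4"] <- 1
  tr <- run_cohort(get_strategy(1), p, init = init)
  expect_equal(unname(tr$occupancy[2, "det_breast_pT4_y1"]), 1)
})

test_that("with onset disabled, LY equals the life-table expectation", {
  mort <- make_life_table()
  p <- default_parameters(mortality = mort)
  p <- set_onset_const(p, breast = 0, ovarian = 0)
  tr <- run_cohort(get_strategy(1), p)
  o <- lifetime_outcomes(tr, p)
  # direct survival-curve sum over the same ages (reward at cycle start)
  q <- background_mortality(mort, 30:99)
  ly_direct <- 1 + sum(cumprod(1 - q))
  expect_equal(o$ly, ly_direct, tolerance = 1e-10)
})

test_that("engine LY matches the matrix-power expectation on the collapsed chain", {
  p_onset <- 0.05; q <- 0.02; s <- 0.9
  p <- toy_chain_params(p_onset, q, s)
  tr <- run_cohort(get_strategy(1), p)
  o <- lifetime_outcomes(tr, p)
  ly_oracle <- toy_chain_ly(p_onset, q, s, n_cycles = 71)
  expect_equal(o$ly, ly_oracle, tolerance = 1e-8)
})

test_that("discounting follows the closed-form geometric sum", {
  p <- toy_immortal_params(end_age = 99) # 70 annual cycles, utility 1
  tr <- run_cohort(get_strategy(1), p)
  o <- lifetime_outcomes(tr, p)
  expect_equal(o$qaly_disc, sum((1.03)^-(0:69)), tolerance = 1e-10)
  expect_equal(o$ly, 70)
  # r = 0: discounted equals undiscounted exactly
  p0 <- p
  p0$analysis$discount_rate <- 0
  o0 <- lifetime_outcomes(run_cohort(get_strategy(1), p0), p0)
  expect_identical(o0$ly, o0$ly_disc)
  expect_identical(o0$qaly, o0$qaly_disc)
  expect_identical(o0$cost_undisc, o0$cost_disc)
})

test_that("an immortal well cohort accrues exactly the surveillance cost", {
  p <- toy_immortal_params(end_age = 99)
  p$costs$surveillance <- 608
  o <- lifetime_outcomes(run_cohort(get_strategy(1), p), p)
  expect_equal(o$cost_undisc, 608 * 70, tolerance = 1e-10)
})

test_that("surgery events charge their one-time cost and one-cycle disutility", {
  p <- toy_immortal_params(end_age = 99)
  p$costs$surgery <- c(pbm = 9032, pbso = 3099, both = 12131)
  p$utilities$well <- 0.92
  o1 <- lifetime_outcomes(run_cohort(get_strategy(1), p), p)
  o2 <- lifetime_outcomes(run_cohort(get_strategy(2), p), p) # PBM at 30
  expect_equal(o2$cost_undisc, 9032, tolerance = 1e-10)
  expect_equal(o2$cost_disc, 9032, tolerance = 1e-10) # fires at the anchor age
  # one cycle at u_well * (u_pbm / u_well) = 0.88 instead of 0.92
  expect_equal(o1$qaly - o2$qaly, 0.92 - 0.88, tolerance = 1e-10)
  o7 <- lifetime_outcomes(run_cohort(get_strategy(7), p), p) # PBSO at 40
  expect_equal(o7$cost_disc, 3099 * 1.03^-10, tolerance = 1e-10)
})

test_that("cumulative risk matches the closed form for a single-band schedule", {
  p <- default_parameters(mortality = flat_mortality(0))
  p <- set_onset_const(p, breast = 0, ovarian = 0)
  p$onset$breast$p_first[p$onset$breast$age_start == 30] <- 0.01
  p$onset$breast$p_last[p$onset$breast$age_start == 30] <- 0.01
  tr <- run_cohort(get_strategy(1), p)
  expect_equal(cumulative_risk_by_age(tr, "breast", 40), 1 - 0.99^10,
               tolerance = 1e-12)
  expect_equal(cumulative_risk_by_age(tr, "ovarian", 100), 0)
  # additivity under mutual exclusivity
  tr2 <- run_cohort(get_strategy(1), default_parameters())
  expect_equal(cumulative_risk_by_age(tr2, "any", 100),
               cumulative_risk_by_age(tr2, "breast", 100) +
                 cumulative_risk_by_age(tr2, "ovarian", 100))
  expect_error(cumulative_risk_by_age(tr2, "breast", 101), "horizon")
})

test_that("stronger onset suppression empties the undetected states", {
  p <- default_parameters()
  tr1 <- run_cohort(get_strategy(1), p)
  tr8 <- run_cohort(get_strategy(8), p)
  st <- state_table()
  und <- st$name[st$kind == "undetected"]
  expect_lt(sum(tr8$occupancy["60", und]), sum(tr1$occupancy["60", und]))
})

test_that("reruns are bit-identical", {
  p <- default_parameters()
  tr_a <- run_cohort(get_strategy(11), p)
  tr_b <- run_cohort(get_strategy(11), p)
  expect_identical(tr_a$occupancy, tr_b$occupancy)
  expect_identical(tr_a$flows, tr_b$flows)
})

test_that("trace exports tidily", {
  p <- default_parameters()
  tr <- run_cohort(get_strategy(1), p)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), length(tr$ages) * ncol(tr$occupancy))
  expect_equal(sum(df$occupancy), sum(tr$occupancy))
})
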