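test_that("icer computes the incremental ratio and rejects equal effects", {
  expect_equal(icer(list(effect = 1, cost = 100),
                    list(effect = 1.1, cost = 300)), 2000)
  expect_equal(icer(list(effect = 1, cost = 100),
                    list(effect = 2, cost = 100)), 0)
  expect_error(icer(list(effect = 1, cost = 0), list(effect = 1, cost = 5)),
               "larger effect")
})

test_that("frontier classifies strong and extended dominance", {
  # second point has more effect for less cost
  f <- efficiency_frontier(data.frame(id = 1:2, effect = c(1, 2),
                                      cost = c(10, 5)))
  expect_equal(f$points$classification, c("strongly-dominated", "on-frontier"))
  expect_equal(f$reference_id, 2)
  # middle point broken by a mix of the outer two (ICER chain 100 then 10)
  f <- efficiency_frontier(data.frame(id = 1:3, effect = 1:3,
                                      cost = c(0, 100, 110)))
  expect_equal(f$points$classification,
               c("on-frontier", "extended-dominated", "on-frontier"))
  expect_equal(f$chain$id, c(1, 3))
  expect_equal(f$chain$step_icer, c(NA, 55))
  # duplicated point: lower id retained
  f <- efficiency_frontier(data.frame(id = c(4, 2), effect = c(1, 1),
                                      cost = c(5, 5)))
  expect_equal(f$points$classification[f$points$id == 2], "on-frontier")
  expect_equal(f$points$classification[f$points$id == 4], "strongly-dominated")
})

test_that("frontier equals the brute-force convex-hull oracle on random clouds", {
  set.seed(20260924)
  for (rep in 1:200) {
    pts <- data.frame(id = 1:16, effect = runif(16, 10, 30),
                      cost = runif(16, 0, 50000))
    f <- efficiency_frontier(pts)
    expect_equal(sort(f$chain$id), frontier_oracle(pts),
                 info = paste("cloud", rep))
    expect_true(all(diff(f$chain$effect) > 0))
    steps <- f$chain$step_icer[-1]
    expect_true(all(steps > 0))
    if (length(steps) > 1) expect_true(all(diff(steps) > 0))
  }
})

test_that("scaling all costs scales every stepwise ratio linearly", {
  set.seed(7)
  pts <- data.frame(id = 1:16, effect = runif(16, 10, 30),
                    cost = runif(16, 0, 50000))
  f1 <- efficiency_frontier(pts)
  k <- 3.5
  pts2 <- pts
  pts2$cost <- pts2$cost * k
  f2 <- efficiency_frontier(pts2)
  expect_equal(f2$chain$id, f1$chain$id)
  expect_equal(f2$chain$step_icer[-1], k * f1$chain$step_icer[-1])
})

test_that("adding a strongly dominated point never changes the chain", {
  set.seed(11)
  for (rep in 1:25) {
    pts <- data.frame(id = 1:10, effect = runif(10), cost = runif(10))
    f1 <- efficiency_frontier(pts)
    worst <- data.frame(id = 99, effect = min(pts$effect) - 0.1,
                        cost = max(pts$cost) + 0.1)
    f2 <- efficiency_frontier(rbind(pts, worst))
    expect_equal(f2$chain$id, f1$chain$id)
    expect_equal(f2$chain$step_icer, f1$chain$step_icer)
  }
})

test_that("incremental comparison versus the reference follows the definitions", {
  fake <- data.frame(
    strategy_id = 1:2, label = c("ref", "half"),
    ly = c(40, 42), qaly = c(35, 38),
    ly_disc = c(25, 26), qaly_disc = c(22, 23),
    cost_undisc = c(1e4, 9e3), cost_disc = c(8e3, 7e3),
    incidence_breast = c(0.8, 0.4), incidence_ovarian = c(0.2, 0.2),
    mortality_breast = c(0.3, 0.15), mortality_ovarian = c(0.1, 0.05))
  tab <- compare_to_reference(fake, 1)
  expect_equal(tab$d_ly, c(0, 2))
  expect_equal(tab$d_qaly, c(0, 3))
  expect_equal(tab$rrr_incidence_breast, c(0, 50))
  expect_equal(tab$rrr_mortality_ovarian, c(0, 50))
  expect_equal(tab$rrr_incidence_ovarian, c(0, 0))
  expect_error(compare_to_reference(fake, 3), "not in outcomes")
})
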