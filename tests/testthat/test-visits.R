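test_that("visit probabilities follow attractiveness-weighted abundance", {
  p <- decept_params(a_M = 1, a_F = 1)
  ## only female insects present
  expect_equal(visit_probabilities(system_state(0, 0, 0, 0, 5), p),
               c(p_M = 0, p_F = 0, p_Y = 1))
  ## full symmetry
  expect_equal(visit_probabilities(system_state(0, 1, 1, 0, 1), p),
               c(p_M = 1, p_F = 1, p_Y = 1) / 3)
  ## empty world: juveniles are not visit targets
  expect_equal(visit_probabilities(system_state(3, 0, 0, 7, 0), p),
               c(p_M = 0, p_F = 0, p_Y = 0))
  ## hand evaluation at a = 0.4, X_M = 6, X_F = 1.5, Y_F = 7.5
  pr <- visit_probabilities(system_state(0, 6, 1.5, 0, 7.5),
                            decept_params(a_M = 0.4, a_F = 0.4))
  expect_equal(pr[["p_M"]], 2.4 / 10.5, tolerance = 1e-12)
  expect_equal(pr[["p_F"]], 0.6 / 10.5, tolerance = 1e-12)
  expect_equal(pr[["p_Y"]], 7.5 / 10.5, tolerance = 1e-12)
})

test_that("visit probabilities conserve total probability", {
  set.seed(11)
  p <- decept_params(a_M = 0.3, a_F = 0.9)
  for (i in 1:50) {
    pr <- visit_probabilities(random_state(), p)
    expect_true(abs(sum(pr) - 1) < 1e-12 || all(pr == 0))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("combinatorial visit statistics match hand-derived cases", {
  ## no female plants: the insect is never trapped; copulations are a
  ## binomial mean N * p_Y
  v <- visit_stats_combinatorial(c(0.7, 0, 0.3), 10)
  expect_equal(v, c(Q1 = 0, Q2 = 3, P = 0), tolerance = 1e-12)
  ## a single visit leaves no room for prior male-plant visits
  v1 <- visit_stats_combinatorial(c(0.2, 0.1, 0.7), 1)
  expect_equal(v1[["Q1"]], 0)
  expect_equal(v1[["Q2"]], 0.7, tolerance = 1e-12)
  ## geometric trap probability
  v2 <- visit_stats_combinatorial(c(0.5, 0.1, 0.4), 10)
  expect_equal(v2[["P"]], 1 - 0.9^10, tolerance = 1e-12)
  ## certain first-visit trapping
  v3 <- visit_stats_combinatorial(c(0, 1, 0), 10)
  expect_equal(v3, c(Q1 = 0, Q2 = 0, P = 1))
  ## N = 2, p = (0.5, 0.5, 0): enumerate sequences by hand.
  ## F (prob .5): Q1 = 0. M F (.25): Q1 = 1. M M (.25): Q1 = 0 (no trap).
  v4 <- visit_stats_combinatorial(c(0.5, 0.5, 0), 2)
  expect_equal(v4[["Q1"]], 0.25, tolerance = 1e-12)
  expect_equal(v4[["Q2"]], 0)
  expect_equal(v4[["P"]], 0.75, tolerance = 1e-12)
})

test_that("closed-form and combinatorial statistics agree to 1e-12", {
  set.seed(7)
  for (i in 1:40) {
    pr <- random_probs()
    N <- sample(1:20, 1)
    expect_equal(visit_stats_closed_form(pr, N),
                 visit_stats_combinatorial(pr, N), tolerance = 1e-13)
  }
  ## degenerate corners
  for (pr in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
    expect_equal(visit_stats_closed_form(pr, 5),
                 visit_stats_combinatorial(pr, 5), tolerance = 1e-13)
})

test_that("visit statistics respect their structural bounds", {
  set.seed(21)
  for (i in 1:40) {
    N <- sample(1:20, 1)
    v <- visit_stats_closed_form(random_probs(), N)
    expect_gte(v[["Q1"]], 0)
    expect_lte(v[["Q1"]], N - 1)
    expect_gte(v[["Q2"]], 0)
    expect_lte(v[["Q2"]], N)
    expect_gte(v[["P"]], 0)
    expect_lte(v[["P"]], 1)
  }
})

test_that("invalid inputs to visit statistics are rejected", {
  expect_error(visit_stats_closed_form(c(0.5, 0.2, 0.3), 0), "N must")
  expect_error(visit_stats_combinatorial(c(0.5, 0.2, 0.3), 2.5),
               "N must")
  expect_error(visit_stats_closed_form(c(0.9, 0.3, 0.3), 5), "sum")
  expect_error(visit_stats_closed_form(c(-0.1, 0.6, 0.5), 5), "0, 1")
})

test_that("attractiveness raises pollination at the insects' expense", {
  ## static composition: plant male ratio 0.8, Y_F = K_Y / 2
  tab <- behaviour_response(decept_params(), "attractiveness",
                            grid = seq(0, 2, by = 0.05), N_list = 10)
  expect_true(all(diff(tab$Q1) >= -1e-12))
  expect_true(all(diff(tab$P) >= -1e-12))
  expect_true(all(diff(tab$Q2) <= 1e-12))
})

test_that("pollination success peaks at a male-biased plant sex ratio", {
  tab <- behaviour_response(decept_params(), "male_ratio",
                            grid = seq(0, 1, by = 0.01), N_list = 10)
  ## Q1 unimodal: rises then falls
  d <- diff(tab$Q1)
  sign_changes <- sum(diff(sign(d[abs(d) > 1e-14])) != 0)
  expect_lte(sign_changes, 1)
  expect_true(all(diff(tab$Q2) >= -1e-12))
  expect_true(all(diff(tab$P) <= 1e-12))
})

test_that("the male-biased Q1 peak is robust to the assumed plant total", {
  ## the static-composition convention fixes adult plants at K_X / 2;
  ## the qualitative peak location must not hinge on that choice
  p <- decept_params()
  m <- seq(0, 1, by = 0.01)
  for (total in c(p$K_X / 4, p$K_X / 2, p$K_X)) {
    q1 <- vapply(m, function(mm) {
      st <- system_state(0, total * mm, total * (1 - mm), 0, p$K_Y / 2)
      visit_stats_closed_form(visit_probabilities(st, p), 10)[["Q1"]]
    }, numeric(1))
    argmax <- m[which.max(q1)]
    expect_gte(argmax, 0.6)
    expect_lte(argmax, 0.8)
    d <- diff(q1)
    expect_lte(sum(diff(sign(d[abs(d) > 1e-14])) != 0), 1)  # unimodal
  }
})

test_that("success fractions saturate in Holling type-II form", {
  expect_identical(pollination_success(0, 5, 1), 0)
  expect_equal(pollination_success(1, 1, 1), 0.5)
  expect_equal(pollination_success(1e12, 1, 1), 1, tolerance = 1e-9)
  expect_identical(mating_success(3, 0, 10), 0)
  expect_equal(mating_success(2, 5, 10), 0.5)
  expect_identical(pollination_success(0, 0, 0), 0)
})
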