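test_that("the default initial state is a juvenile colonist in an insect world", {
  init <- default_initial_state(decept_params())
  expect_equal(unname(init), c(1, 0, 0, 7.5, 7.5))
  init2 <- default_initial_state(decept_params(K_Y = 2))
  expect_equal(unname(init2), c(1, 0, 0, 1, 1))
  expect_silent(as_system_state <- system_state(init2[1], init2[2],
                                                init2[3], init2[4],
                                                init2[5]))
})

test_that("window means reproduce analytic averages", {
  p <- decept_params()
  times <- seq(0, 100, by = 0.5)
  ## constant trajectory
  const <- matrix(rep(c(1, 2, 1, 3, 4), each = length(times)),
                  ncol = 5, dimnames = list(NULL, names(system_state())))
  s <- steady_state(synthetic_sim(times, const), 0.25)
  expect_equal(c(s$mean_X_J, s$mean_X_M, s$mean_X_F, s$mean_Y_M,
                 s$mean_Y_F), c(1, 2, 1, 3, 4), tolerance = 1e-12)
  expect_equal(s$plant_male_ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(s$window, c(t_start = 75, t_end = 100))
  ## sinusoid around a known mean: average of 2 + sin over full periods
  states <- const
  states[, "X_J"] <- 2 + sin(2 * pi * times / 10)
  s2 <- steady_state(synthetic_sim(times, states), 0.2)  # window = 2 periods
  expect_equal(s2$mean_X_J, 2, tolerance = 1e-3)
})

test_that("outcome classification applies the extinction threshold", {
  expect_identical(classify_outcome(synthetic_steady()), "CO_EXTINCT")
  expect_identical(classify_outcome(synthetic_steady(X_J = 5,
                                                     Y_F = 0.0005)),
                   "PLANT_ONLY")
  expect_identical(classify_outcome(synthetic_steady(X_J = 0.0009,
                                                     Y_M = 4)),
                   "INSECT_ONLY")
  expect_identical(classify_outcome(synthetic_steady(X_J = 1, Y_M = 1)),
                   "COEXIST")
  ## boundary value counts as extant
  expect_identical(classify_outcome(synthetic_steady(X_J = 0.001)),
                   "PLANT_ONLY")
})

test_that("sterile insects decay to the clamp and the event is recorded", {
  p <- update_params(decept_params(), f = 0)
  sim <- simulate_dynamics(p, t_end = 2000)
  expect_true(any(sim$events$population == "insect"))
  n <- nrow(sim$states)
  expect_identical(unname(sim$states[n, c("Y_M", "Y_F")]), c(0, 0))
  ## plant carries on vegetatively (persistence index 1.54 > 1)
  expect_gt(sum(sim$states[n, 1:3]), 0.001)
})

test_that("plant-only fate brackets the analytic persistence boundary", {
  plant_init <- system_state(1, 0, 0, 0, 0)
  below <- decept_params(r_VM = 0.012, r_VF = 0.012)
  above <- decept_params(r_VM = 0.014, r_VF = 0.014)
  out_below <- run_to_outcome(below, init = plant_init, t_end = 50000)
  out_above <- run_to_outcome(above, init = plant_init, t_end = 50000)
  expect_identical(out_below$outcome, "CO_EXTINCT")
  expect_identical(out_above$outcome, "PLANT_ONLY")
})

test_that("unattractive plants leave the insect sexes symmetric", {
  p <- decept_params(a_M = 0, a_F = 0)
  sim <- simulate_dynamics(p, t_end = 5000)
  expect_lt(max(abs(sim$states[, "Y_M"] - sim$states[, "Y_F"])), 1e-8)
})

test_that("trajectories stay non-negative and below capacity", {
  set.seed(31)
  for (i in 1:4) {
    p <- decept_params(a_M = stats::runif(1, 0, 1),
                       a_F = stats::runif(1, 0, 1),
                       r_VM = stats::runif(1, 0, 0.05),
                       r_VF = stats::runif(1, 0, 0.05),
                       g_MF = stats::runif(1, 0.001, 0.05))
    sim <- simulate_dynamics(p, t_end = 5000)
    expect_true(all(sim$states >= 0))
    plant_tot <- rowSums(sim$states[, 1:3])
    insect_tot <- rowSums(sim$states[, 4:5])
    expect_lte(max(plant_tot), max(plant_tot[1], p$K_X) + 1e-6)
    expect_lte(max(insect_tot), max(insect_tot[1], p$K_Y) + 1e-6)
  }
})

test_that("the trivial equilibrium is stationary under integration", {
  sim <- simulate_dynamics(decept_params(), init = system_state(),
                           t_end = 1000)
  expect_lt(max(abs(sim$states)), 1e-9)
})

test_that("undefined sex ratios are reported as missing", {
  s <- synthetic_steady(X_J = 5)
  expect_true(is.na(s$plant_male_ratio))
  expect_true(is.na(s$insect_male_ratio))
})

test_that("bistability probing reruns the protocol per initial state", {
  p <- decept_params()
  init <- default_initial_state(p)
  out <- bistability_probe(p, list(init, init), t_end = 2000)
  expect_identical(out[1], out[2])
  expect_false(attr(out, "bistable"))
  expect_error(bistability_probe(p, list(init)), "length")
})

test_that("simulation accessors expose the trajectory faithfully", {
  p <- decept_params()
  sim <- simulate_dynamics(p, t_end = 500)
  df <- as.data.frame(sim)
  expect_identical(names(df), c("t", "X_J", "X_M", "X_F", "Y_M", "Y_F"))
  expect_identical(df$t[1], 0)
  expect_equal(unname(unlist(df[1, -1])),
               unname(default_initial_state(p)))
  expect_true(all(diff(df$t) > 0))
})
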