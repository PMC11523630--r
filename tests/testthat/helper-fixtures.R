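## Shared fixtures for the suite.

## random valid probability triple (p_M, p_F, p_Y) summing to 1
random_probs <- function() {
  u <- stats::runif(3)
  u / sum(u)
}

## random valid state with abundances in [0, 15]
random_state <- function() {
  system_state(stats::runif(1, 0, 15), stats::runif(1, 0, 15),
               stats::runif(1, 0, 15), stats::runif(1, 0, 15),
               stats::runif(1, 0, 15))
}

## hand-built decept_sim from an analytic trajectory, for summary tests
synthetic_sim <- function(times, states, params = decept_params()) {
  structure(list(times = times, states = states, params = params,
                 events = data.frame(time = numeric(),
                                     population = character(),
                                     action = character()),
                 control = sim_control()),
            class = "decept_sim")
}

## hand-built steady-state summary, for classification tests
synthetic_steady <- function(X_J = 0, X_M = 0, X_F = 0,
                             Y_M = 0, Y_F = 0) {
  ratio <- function(a, b) if (a + b < 1e-12) NA_real_ else a / (a + b)
  structure(list(mean_X_J = X_J, mean_X_M = X_M, mean_X_F = X_F,
                 mean_Y_M = Y_M, mean_Y_F = Y_F,
                 plant_male_ratio = ratio(X_M, X_F),
                 insect_male_ratio = ratio(Y_M, Y_F),
                 window = c(t_start = 0, t_end = 1)),
            class = "decept_steady")
}
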