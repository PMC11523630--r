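#' Default initial state of the simulation protocol
#'
#' Juvenile plants colonising a plant-free insect steady state: one
#' juvenile plant, no adults, and the insect population at half its
#' recruitment capacity split evenly between the sexes:
#' `(X_J, X_M, X_F, Y_M, Y_F) = (1, 0, 0, K_Y/2, K_Y/2)`.
#'
#' @param params a `decept_params` object.
#' @return A system state vector.
#' @examples
#' default_initial_state(decept_params())
#' @export
default_initial_state <- function(params) {
  stopifnot(is.decept_params(params))
  system_state(1, 0, 0, params$K_Y / 2, params$K_Y / 2)
}

#' Solver settings for the dynamics
#'
#' @param rtol,atol relative and absolute integration tolerances.
#' @param threshold extinction-clamp threshold: whenever total plant or
#'   total insect abundance falls below this value during integration,
#'   the corresponding components are set to zero and integration
#'   continues (the same threshold is re-applied to window means at
#'   classification).
#' @param t_step spacing of saved output points; `NULL` chooses
#'   `t_end / 2000`.
#' @param method a `deSolve` integration method; the default `"lsoda"`
#'   switches automatically between stiff and non-stiff steppers.
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(rtol = 1e-8, atol = 1e-10, threshold = 0.001,
                        t_step = NULL, method = "lsoda") {
  stopifnot(rtol > 0, atol > 0, threshold > 0)
  structure(list(rtol = rtol, atol = atol, threshold = threshold,
                 t_step = t_step, method = method),
            class = "sim_control")
}

#' Integrate the coupled plant-insect dynamics
#'
#' Solves the five-compartment system with an adaptive (stiff-capable)
#' integrator. Whenever total plant or total insect abundance crosses the
#' extinction threshold from above, an event zeroes that group and the
#' integration continues; every such clamp is recorded. Output states are
#' clipped at zero (clips are bounded by the absolute tolerance).
#'
#' @param params a `decept_params` object.
#' @param init initial system state; defaults to
#'   [default_initial_state()].
#' @param t_end final time (> 0); the protocol value is 50000.
#' @param control a [sim_control()] list.
#' @return An object of class `decept_sim`: list with `times`, `states`
#'   (matrix with columns `X_J ... Y_F`), `params`, `events`
#'   (data.frame of extinction clamps), `control`.
#' @examples
#' sim <- simulate_dynamics(decept_params(), t_end = 2000)
#' summary(sim)
#' @export
simulate_dynamics <- function(params, init = NULL, t_end = 50000,
                              control = sim_control()) {
  stopifnot(is.decept_params(params), t_end > 0,
            inherits(control, "sim_control"))
  if (is.null(init)) init <- default_initial_state(params)
  init <- as_system_state(init)
  t_step <- if (is.null(control$t_step)) t_end / 2000 else control$t_step
  times <- unique(c(seq(0, t_end, by = t_step), t_end))
  thr <- control$threshold

  event_log <- new.env(parent = emptyenv())
  event_log$rows <- list()
  rootfun <- function(t, y, p)
    c(y[1] + y[2] + y[3] - thr, y[4] + y[5] - thr)
  eventfun <- function(t, y, p) {
    if (y[1] + y[2] + y[3] <= thr) {
      y[1:3] <- 0
      event_log$rows[[length(event_log$rows) + 1L]] <-
        data.frame(time = t, population = "plant", action = "zeroed")
    }
    if (y[4] + y[5] <= thr) {
      y[4:5] <- 0
      event_log$rows[[length(event_log$rows) + 1L]] <-
        data.frame(time = t, population = "insect", action = "zeroed")
    }
    y
  }
  deriv <- function(t, y, p) list(rhs_core(y, p))

  out <- deSolve::ode(y = init, times = times, func = deriv,
                      parms = params, method = control$method,
                      rtol = control$rtol, atol = control$atol,
                      rootfunc = rootfun,
                      events = list(func = eventfun, root = TRUE))
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop("integration failed near t = ", max(out[, 1]))
  if (nrow(out) < length(times))
    stop("integration stopped early at t = ", max(out[, 1]))
  states <- pmax(unclass(out)[, state_names(), drop = FALSE], 0)
  events <- if (length(event_log$rows) > 0)
    do.call(rbind, event_log$rows)
  else data.frame(time = numeric(), population = character(),
                  action = character())
  structure(list(times = out[, 1], states = states, params = params,
                 events = events, control = control),
            class = "decept_sim")
}

#' @export
print.decept_sim <- function(x, ...) {
  cat(sprintf("Plant-insect simulation: t in [%g, %g], %d saved states\n",
              min(x$times), max(x$times), length(x$times)))
  if (nrow(x$events) > 0) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  extinction clamp: %s zeroed at t = %g\n",
                  x$events$population[i], x$events$time[i]))
  }
  fin <- x$states[nrow(x$states), ]
  cat("  final state:", paste(sprintf("%s = %.4g", names(fin), fin),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.decept_sim <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
plot.decept_sim <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    col = c("darkgreen", "forestgreen", "olivedrab",
                            "navy", "steelblue"),
                    xlab = "time", ylab = "abundance", ...)
  graphics::legend("topright", colnames(x$states), lty = 1,
                   col = c("darkgreen", "forestgreen", "olivedrab",
                           "navy", "steelblue"), bty = "n")
  invisible(x)
}

## trapezoid time average of each column over [t0, t1], interpolating
## the window endpoints linearly
window_means <- function(times, states, t0, t1) {
  if (t1 <= t0) stop("empty averaging window")
  inside <- times > t0 & times < t1
  tt <- c(t0, times[inside], t1)
  interp <- function(col) {
    y <- c(stats::approx(times, col, xout = t0)$y, col[inside],
           stats::approx(times, col, xout = t1)$y)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
      (t1 - t0)
  }
  apply(states, 2, interp)
}

#' Steady-state summary over the final averaging window
#'
#' Time-weighted mean abundances over the last `window_fraction` of the
#' simulated period (protocol: the last 10%, i.e. t = 45000-50000 for
#' t_end = 50000), plus sex ratios computed from the window means
#' (ratio of means, which stays stable when one sex is nearly absent).
#' Ratios whose denominator means are below 1e-12 are reported as `NA`.
#'
#' @param sim a `decept_sim` object.
#' @param window_fraction fraction of the period to average over, in
#'   `(0, 1]`.
#' @return An object of class `decept_steady`: list with the five mean
#'   abundances (`mean_X_J`, ...), `plant_male_ratio`,
#'   `insect_male_ratio`, and `window = c(t_start, t_end)`.
#' @examples
#' steady_state(simulate_dynamics(decept_params(), t_end = 2000))
#' @export
steady_state <- function(sim, window_fraction = 0.1) {
  stopifnot(inherits(sim, "decept_sim"),
            window_fraction > 0, window_fraction <= 1)
  t_end <- max(sim$times)
  t0 <- t_end * (1 - window_fraction)
  m <- window_means(sim$times, sim$states, t0, t_end)
  ratio <- function(a, b) if (a + b < 1e-12) NA_real_ else a / (a + b)
  structure(list(mean_X_J = m[["X_J"]], mean_X_M = m[["X_M"]],
                 mean_X_F = m[["X_F"]], mean_Y_M = m[["Y_M"]],
                 mean_Y_F = m[["Y_F"]],
                 plant_male_ratio = ratio(m[["X_M"]], m[["X_F"]]),
                 insect_male_ratio = ratio(m[["Y_M"]], m[["Y_F"]]),
                 window = c(t_start = t0, t_end = t_end)),
            class = "decept_steady")
}

#' @export
summary.decept_sim <- function(object, window_fraction = 0.1, ...) {
  steady_state(object, window_fraction)
}

#' @export
print.decept_steady <- function(x, ...) {
  cat(sprintf("Steady-state window means (t = %g-%g)\n",
              x$window[["t_start"]], x$window[["t_end"]]))
  cat(sprintf("  plant:  X_J = %.4g, X_M = %.4g, X_F = %.4g (male ratio %s)\n",
              x$mean_X_J, x$mean_X_M, x$mean_X_F,
              if (is.na(x$plant_male_ratio)) "undefined"
              else sprintf("%.3f", x$plant_male_ratio)))
  cat(sprintf("  insect: Y_M = %.4g, Y_F = %.4g (male ratio %s)\n",
              x$mean_Y_M, x$mean_Y_F,
              if (is.na(x$insect_male_ratio)) "undefined"
              else sprintf("%.3f", x$insect_male_ratio)))
  invisible(x)
}

#' Four-way steady-state outcome
#'
#' A population counts as extant when its summed window-mean abundance
#' is at least `threshold` (protocol value 0.001).
#'
#' @param steady a `decept_steady` summary.
#' @param threshold extinction threshold (> 0).
#' @return One of `"COEXIST"`, `"PLANT_ONLY"`, `"INSECT_ONLY"`,
#'   `"CO_EXTINCT"`.
#' @examples
#' classify_outcome(steady_state(simulate_dynamics(decept_params(),
#'                                                 t_end = 2000)))
#' @export
classify_outcome <- function(steady, threshold = 0.001) {
  stopifnot(inherits(steady, "decept_steady"), threshold > 0)
  plant <- steady$mean_X_J + steady$mean_X_M + steady$mean_X_F >= threshold
  insect <- steady$mean_Y_M + steady$mean_Y_F >= threshold
  if (plant && insect) "COEXIST"
  else if (plant) "PLANT_ONLY"
  else if (insect) "INSECT_ONLY"
  else "CO_EXTINCT"
}

#' Run the full simulation protocol for one parameter set
#'
#' Convenience composition: integrate to `t_end`, average over the final
#' window, classify at the extinction threshold.
#'
#' @inheritParams simulate_dynamics
#' @param window_fraction averaging window (fraction of the period).
#' @param threshold extinction threshold for classification.
#' @return A list with elements `steady` (a `decept_steady`) and
#'   `outcome` (character).
#' @examples
#' run_to_outcome(decept_params(), t_end = 2000)$outcome
#' @export
run_to_outcome <- function(params, init = NULL, t_end = 50000,
                           window_fraction = 0.1, threshold = 0.001,
                           control = sim_control(threshold = threshold)) {
  sim <- simulate_dynamics(params, init = init, t_end = t_end,
                           control = control)
  steady <- steady_state(sim, window_fraction)
  list(steady = steady, outcome = classify_outcome(steady, threshold))
}

#' Probe for alternative stable states
#'
#' Runs the protocol from each supplied initial state; differing
#' outcomes at identical parameters indicate bistability (e.g.
#' pollination-maintained coexistence that collapses when the insect is
#' absent initially).
#'
#' @param params a `decept_params` object.
#' @param inits list of at least two initial system states.
#' @param ... passed to [run_to_outcome()].
#' @return Character vector of outcomes, one per initial state, with
#'   attribute `bistable` (logical).
#' @examples
#' p <- decept_params(a_M = 0.2, a_F = 0.2, r_VM = 0.01, r_VF = 0.01)
#' inits <- list(default_initial_state(p), system_state(1, 0, 0, 0, 0))
#' bistability_probe(p, inits, t_end = 2000)
#' @export
bistability_probe <- function(params, inits, ...) {
  stopifnot(is.list(inits), length(inits) >= 2)
  out <- vapply(inits,
                function(y0) run_to_outcome(params, init = y0, ...)$outcome,
                character(1))
  attr(out, "bistable") <- length(unique(out)) > 1
  out
}
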