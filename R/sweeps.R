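#' Sweep axis specification
#'
#' Describes a linearly spaced sweep over one model parameter. Two
#' linked names are understood in addition to the plain parameter
#' symbols: `"r_V"` sets `r_VM = r_VF` jointly and `"a"` sets
#' `a_M = a_F` jointly, matching how the sweeps are reported.
#'
#' @param name parameter symbol, or `"r_V"` / `"a"`.
#' @param min,max axis range (`min < max`).
#' @param n number of grid points (integer >= 2).
#' @return A list of class `axis_spec` with a `values` vector.
#' @examples
#' axis_spec("g_MF", 0, 0.05, 11)
#' @export
axis_spec <- function(name, min, max, n = 21) {
  resolve_axis_param(name)
  stopifnot(is.numeric(min), is.numeric(max), min < max,
            n >= 2, n == round(n))
  structure(list(name = name, min = min, max = max, n = as.integer(n),
                 values = seq(min, max, length.out = n)),
            class = "axis_spec")
}

resolve_axis_param <- function(name) {
  if (identical(name, "r_V")) return(c("r_VM", "r_VF"))
  if (identical(name, "a")) return(c("a_M", "a_F"))
  if (name %in% param_names()) return(name)
  stop("cannot resolve sweep parameter: ", name)
}

set_axis_param <- function(params, name, value) {
  fields <- resolve_axis_param(name)
  ov <- stats::setNames(as.list(rep(value, length(fields))), fields)
  update_params(params, ov)
}

#' Regime map over a two-parameter grid
#'
#' Runs the full simulation protocol from the default initial state for
#' every cell of the grid spanned by two axes and classifies the
#' steady-state outcome (coexistence / plant only / insect only /
#' co-extinction). When one axis is the joint vegetative rate `r_V` and
#' the other is `g_MF`, the analytic plant-persistence boundary `r*` is
#' attached along the `g_MF` axis.
#'
#' @param base parameters common to every cell.
#' @param axis1,axis2 [axis_spec()] objects naming distinct parameters.
#' @param ... passed to [run_to_outcome()] (e.g. `t_end`).
#' @return An object of class `decept_regime`: list with `axis1`,
#'   `axis2`, `outcomes` (n1 x n2 character matrix, axis1 on rows),
#'   `summaries` (long data.frame), `boundary` (data.frame or `NULL`),
#'   `base`.
#' @examples
#' rm <- regime_map(decept_params(a_M = 0.2, a_F = 0.2),
#'                  axis_spec("g_MF", 0.005, 0.05, 2),
#'                  axis_spec("r_V", 0, 0.05, 2), t_end = 2000)
#' rm$outcomes
#' @export
regime_map <- function(base, axis1, axis2, ...) {
  stopifnot(is.decept_params(base), inherits(axis1, "axis_spec"),
            inherits(axis2, "axis_spec"))
  if (length(intersect(resolve_axis_param(axis1$name),
                       resolve_axis_param(axis2$name))) > 0)
    stop("sweep axes must name distinct parameters")
  n1 <- axis1$n; n2 <- axis2$n
  outcomes <- matrix(NA_character_, n1, n2,
                     dimnames = list(format(axis1$values, trim = TRUE),
                                     format(axis2$values, trim = TRUE)))
  rows <- vector("list", n1 * n2)
  for (i in seq_len(n1)) {
    p_i <- set_axis_param(base, axis1$name, axis1$values[i])
    for (j in seq_len(n2)) {
      p <- set_axis_param(p_i, axis2$name, axis2$values[j])
      res <- run_to_outcome(p, ...)
      outcomes[i, j] <- res$outcome
      s <- res$steady
      rows[[(i - 1) * n2 + j]] <- data.frame(
        axis1_value = axis1$values[i], axis2_value = axis2$values[j],
        outcome = res$outcome,
        mean_X_J = s$mean_X_J, mean_X_M = s$mean_X_M,
        mean_X_F = s$mean_X_F, mean_Y_M = s$mean_Y_M,
        mean_Y_F = s$mean_Y_F,
        plant_male_ratio = s$plant_male_ratio,
        insect_male_ratio = s$insect_male_ratio)
    }
  }
  axes <- c(axis1$name, axis2$name)
  boundary <- NULL
  if ("r_V" %in% axes && "g_MF" %in% axes) {
    g_axis <- if (axis1$name == "g_MF") axis1 else axis2
    boundary <- data.frame(
      g_MF = g_axis$values,
      r_star = vapply(g_axis$values, function(g)
        persistence_boundary_r(update_params(base, g_MF = g)),
        numeric(1)))
  }
  structure(list(axis1 = axis1, axis2 = axis2, outcomes = outcomes,
                 summaries = do.call(rbind, rows), boundary = boundary,
                 base = base),
            class = "decept_regime")
}

#' @export
print.decept_regime <- function(x, ...) {
  cat(sprintf("Regime map: %s (%d) x %s (%d)\n", x$axis1$name, x$axis1$n,
              x$axis2$name, x$axis2$n))
  print(table(factor(x$outcomes,
                     c("COEXIST", "PLANT_ONLY", "INSECT_ONLY",
                       "CO_EXTINCT"))))
  invisible(x)
}

#' @export
plot.decept_regime <- function(x, ...) {
  lev <- c("COEXIST", "PLANT_ONLY", "INSECT_ONLY", "CO_EXTINCT")
  cols <- c(COEXIST = "white", PLANT_ONLY = "palegreen3",
            INSECT_ONLY = "steelblue", CO_EXTINCT = "black")
  z <- matrix(match(x$outcomes, lev), x$axis1$n, x$axis2$n)
  graphics::image(x$axis1$values, x$axis2$values, z, zlim = c(1, 4),
                  col = cols, xlab = x$axis1$name, ylab = x$axis2$name,
                  ...)
  if (!is.null(x$boundary)) {
    if (x$axis1$name == "g_MF")
      graphics::lines(x$boundary$g_MF, x$boundary$r_star)
    else graphics::lines(x$boundary$r_star, x$boundary$g_MF)
  }
  invisible(x)
}

#' Population response to floral attractiveness
#'
#' For each sex-generic attractiveness value (`a_M = a_F = a`) under a
#' scenario preset, runs the simulation protocol and reports relative
#' abundances (plant total / `K_X`, insect total / `K_Y`) and the two
#' male ratios at steady state.
#'
#' @param base base parameters.
#' @param scenario `"first"` or `"second"` (see [scenario_params()]).
#' @param a_grid attractiveness values (>= 0).
#' @param ... passed to [run_to_outcome()].
#' @return A data.frame with columns `a`, `plant_rel`, `insect_rel`,
#'   `plant_male_ratio`, `insect_male_ratio`, `outcome`.
#' @examples
#' attractiveness_response(decept_params(), "second", c(0, 0.4),
#'                         t_end = 2000)
#' @export
attractiveness_response <- function(base = decept_params(),
                                    scenario = c("second", "first"),
                                    a_grid, ...) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(a_grid), all(a_grid >= 0))
  p0 <- scenario_params(scenario, base = base)
  rows <- lapply(a_grid, function(a) {
    res <- run_to_outcome(update_params(p0, a_M = a, a_F = a), ...)
    s <- res$steady
    data.frame(a = a,
               plant_rel = (s$mean_X_J + s$mean_X_M + s$mean_X_F) /
                 p0$K_X,
               insect_rel = (s$mean_Y_M + s$mean_Y_F) / p0$K_Y,
               plant_male_ratio = s$plant_male_ratio,
               insect_male_ratio = s$insect_male_ratio,
               outcome = res$outcome)
  })
  do.call(rbind, rows)
}

#' Visiting-behaviour response curves
#'
#' Lifetime visit statistics (`Q1`, `Q2`, `P`) of a male insect against
#' either sex-generic floral attractiveness or the plant male sex ratio,
#' over a fixed static community composition: female insects at
#' `Y_F = K_Y / 2` and total adult plant abundance `K_X / 2` split by
#' the plant male ratio (juveniles are not visited and are excluded).
#' In `"attractiveness"` mode the plant male ratio is held at
#' `male_ratio` (default 0.8, the observed field bias); in
#' `"male_ratio"` mode attractiveness is held at `a` (default 0.4).
#'
#' @param params a `decept_params` object supplying `K_X`, `K_Y`.
#' @param mode `"attractiveness"` or `"male_ratio"`.
#' @param grid swept values: attractiveness (>= 0) or male ratio in
#'   `[0, 1]`.
#' @param N_list lifetime visit numbers to evaluate (default
#'   `c(5, 10, 20)`).
#' @param male_ratio fixed plant male ratio for attractiveness mode.
#' @param a fixed attractiveness for male-ratio mode.
#' @return A data.frame with columns `value`, `N`, `Q1`, `Q2`, `P`, and
#'   attribute `q1_argmax`: for each `N` the smallest grid value
#'   maximising `Q1`.
#' @examples
#' br <- behaviour_response(decept_params(), "male_ratio",
#'                          seq(0, 1, 0.01), N_list = 10)
#' attr(br, "q1_argmax")
#' @export
behaviour_response <- function(params = decept_params(),
                               mode = c("attractiveness", "male_ratio"),
                               grid, N_list = c(5, 10, 20),
                               male_ratio = 0.8, a = 0.4) {
  mode <- match.arg(mode)
  stopifnot(is.decept_params(params), is.numeric(grid),
            length(grid) >= 1)
  if (mode == "male_ratio" && (any(grid < 0) || any(grid > 1)))
    stop("male-ratio grid must lie in [0, 1]")
  if (mode == "attractiveness" && any(grid < 0))
    stop("attractiveness grid must be non-negative")
  N_list <- vapply(N_list, check_N, integer(1))
  Y_F <- params$K_Y / 2
  total <- params$K_X / 2
  rows <- vector("list", length(grid) * length(N_list))
  idx <- 1
  for (g in grid) {
    if (mode == "attractiveness") {
      p <- update_params(params, a_M = g, a_F = g)
      m <- male_ratio
    } else {
      p <- update_params(params, a_M = a, a_F = a)
      m <- g
    }
    st <- system_state(0, total * m, total * (1 - m), 0, Y_F)
    probs <- visit_probabilities(st, p)
    for (N in N_list) {
      v <- visit_stats_closed_form(probs, N)
      rows[[idx]] <- data.frame(value = g, N = N, Q1 = v[["Q1"]],
                                Q2 = v[["Q2"]], P = v[["P"]])
      idx <- idx + 1
    }
  }
  tab <- do.call(rbind, rows)
  argmax <- vapply(N_list, function(N) {
    sub <- tab[tab$N == N, ]
    sub$value[which.max(sub$Q1)]  # which.max takes the first: smallest
  }, numeric(1))
  attr(tab, "q1_argmax") <- stats::setNames(argmax, N_list)
  tab
}

#' One-at-a-time sensitivity scan
#'
#' Varies a single parameter (or linked pair) over supplied values while
#' holding everything else at `base`, running the simulation protocol at
#' each value.
#'
#' @param base base parameters.
#' @param parameter parameter symbol, or `"r_V"` / `"a"`.
#' @param values numeric values to scan.
#' @param ... passed to [run_to_outcome()].
#' @return A data.frame with one row per value: the window-mean
#'   abundances, sex ratios and outcome.
#' @examples
#' sensitivity_scan(decept_params(), "d_Y", c(0.05, 0.1), t_end = 2000)
#' @export
sensitivity_scan <- function(base, parameter, values, ...) {
  stopifnot(is.decept_params(base), is.numeric(values),
            length(values) >= 1)
  rows <- lapply(values, function(v) {
    res <- run_to_outcome(set_axis_param(base, parameter, v), ...)
    s <- res$steady
    data.frame(value = v, mean_X_J = s$mean_X_J, mean_X_M = s$mean_X_M,
               mean_X_F = s$mean_X_F, mean_Y_M = s$mean_Y_M,
               mean_Y_F = s$mean_Y_F,
               plant_male_ratio = s$plant_male_ratio,
               insect_male_ratio = s$insect_male_ratio,
               outcome = res$outcome)
  })
  out <- do.call(rbind, rows)
  out$parameter <- parameter
  out[, c("parameter", setdiff(names(out), "parameter"))]
}
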