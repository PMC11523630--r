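#' Time derivatives of the full plant-insect system
#'
#' Right-hand side of the coupled five-compartment model. Juvenile plants
#' are produced vegetatively by both adult sexes and sexually by
#' pollinated females, throttled by the logistic recruitment factor
#' `1 - (X_J + X_M + X_F) / K_X`; they mature into males (`g_JM`), males
#' change sex to female (`g_MF`), and females revert to male in
#' proportion to their pollination success (`g_FM * Phi_X`). Insects
#' recruit from mated females under the factor `1 - (Y_M + Y_F) / K_Y`
#' with male birth ratio `s`; male insects suffer the extra trap
#' mortality `q * P` on top of the natural death rate `d_Y`.
#'
#' @param state a system state (see [system_state()]).
#' @param params a `decept_params` object.
#' @return Named numeric vector of the five time derivatives
#'   `c(X_J, X_M, X_F, Y_M, Y_F)`.
#' @examples
#' state_derivatives(system_state(1, 2, 1, 3, 4), decept_params())
#' @export
state_derivatives <- function(state, params) {
  state <- as_system_state(state)
  stopifnot(is.decept_params(params))
  rhs_core(state, params)
}

## unchecked kernel; also the deSolve right-hand side (states are clipped
## at zero so adaptive steps cannot probe negative abundances)
rhs_core <- function(y, p) {
  y <- pmax(y, 0)
  X_J <- y[[1]]; X_M <- y[[2]]; X_F <- y[[3]]
  Y_M <- y[[4]]; Y_F <- y[[5]]
  D <- p$a_M * X_M + p$a_F * X_F + Y_F
  if (D > 0) {
    v <- visit_stats_fast(p$a_M * X_M / D, p$a_F * X_F / D, Y_F / D, p$N)
  } else {
    v <- c(0, 0, 0)
  }
  Q1 <- v[[1]]; Q2 <- v[[2]]; P <- v[[3]]
  u1 <- Y_M * Q1
  phi_X <- if (u1 > 0) u1 / (p$A_X + u1) else 0
  u2 <- Y_M * Q2
  phi_Y <- if (u2 > 0) u2 / (p$A_Y + u2) else 0
  crowd_X <- 1 - (X_J + X_M + X_F) / p$K_X
  crowd_Y <- 1 - (Y_M + Y_F) / p$K_Y
  c(X_J = (p$r_VM * X_M + (p$r_VF + p$r_P * phi_X) * X_F) * crowd_X -
      p$g_JM * X_J - p$d_J * X_J,
    X_M = p$g_JM * X_J - p$g_MF * X_M + p$g_FM * phi_X * X_F -
      p$d_M * X_M,
    X_F = p$g_MF * X_M - p$g_FM * phi_X * X_F - p$d_F * X_F,
    Y_M = p$s * p$f * phi_Y * crowd_Y * Y_F - (p$d_Y + p$q * P) * Y_M,
    Y_F = (1 - p$s) * p$f * phi_Y * crowd_Y * Y_F - p$d_Y * Y_F)
}

#' Time derivatives of the insect-free plant subsystem
#'
#' With no insects there is no pollination and no sex reversal: juvenile
#' production is vegetative only, and the female equation loses the
#' `g_FM` flux.
#'
#' @param X_J,X_M,X_F plant abundances (>= 0).
#' @param params a `decept_params` object.
#' @return Named numeric vector `c(X_J, X_M, X_F)` of derivatives.
#' @examples
#' plant_only_derivatives(1, 2, 1, decept_params())
#' @export
plant_only_derivatives <- function(X_J, X_M, X_F, params) {
  stopifnot(is.decept_params(params))
  p <- params
  crowd_X <- 1 - (X_J + X_M + X_F) / p$K_X
  c(X_J = (p$r_VM * X_M + p$r_VF * X_F) * crowd_X -
      p$g_JM * X_J - p$d_J * X_J,
    X_M = p$g_JM * X_J - p$g_MF * X_M - p$d_M * X_M,
    X_F = p$g_MF * X_M - p$d_F * X_F)
}

#' Plant persistence index (lifetime fitness without pollinators)
#'
#' The plant persists alone iff the product of (i) the probability that a
#' juvenile survives to the adult male stage, `g_JM / (g_JM + d_J)`, and
#' (ii) the expected lifetime juvenile production of an adult,
#' `r_VM / (g_MF + d_M) + (g_MF / (g_MF + d_M)) * r_VF / d_F`, exceeds 1.
#' This is the invasion criterion of the plant-only subsystem at the
#' trivial equilibrium.
#'
#' @param params a `decept_params` object with `g_JM + d_J`, `g_MF + d_M`
#'   and `d_F` strictly positive.
#' @return The index value; persistence corresponds to a value > 1.
#' @examples
#' persistence_index(decept_params(r_VM = 0.013, r_VF = 0.013))
#' @export
persistence_index <- function(params) {
  stopifnot(is.decept_params(params))
  p <- params
  if (p$g_JM + p$d_J <= 0)
    stop("persistence index undefined: g_JM + d_J must be positive")
  if (p$g_MF + p$d_M <= 0)
    stop("persistence index undefined: g_MF + d_M must be positive")
  if (p$d_F <= 0)
    stop("persistence index undefined: d_F must be positive")
  (p$g_JM / (p$g_JM + p$d_J)) *
    (p$r_VM / (p$g_MF + p$d_M) +
       (p$g_MF / (p$g_MF + p$d_M)) * p$r_VF / p$d_F)
}

#' Vegetative reproduction rate on the persistence boundary
#'
#' Solves `persistence_index = 1` for the common vegetative reproduction
#' rate under the constraint `r_VM = r_VF = r`:
#' `r* = ((g_JM + d_J) / g_JM) / (1 / (g_MF + d_M) +
#' g_MF / ((g_MF + d_M) d_F))`. This is the curve separating plant-only
#' persistence from dependence on pollination in sweeps over `r_V`.
#'
#' @inheritParams persistence_index
#' @return The boundary rate `r*`.
#' @examples
#' persistence_boundary_r(decept_params(g_MF = 0.01))  # 0.013
#' @export
persistence_boundary_r <- function(params) {
  stopifnot(is.decept_params(params))
  p <- params
  if (p$g_JM <= 0)
    stop("persistence boundary undefined: g_JM must be positive")
  if (p$g_MF + p$d_M <= 0)
    stop("persistence boundary undefined: g_MF + d_M must be positive")
  if (p$d_F <= 0)
    stop("persistence boundary undefined: d_F must be positive")
  ((p$g_JM + p$d_J) / p$g_JM) /
    (1 / (p$g_MF + p$d_M) + p$g_MF / ((p$g_MF + p$d_M) * p$d_F))
}
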