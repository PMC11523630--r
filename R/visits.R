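#' System state vector
#'
#' The five abundances of the model at one time point: juvenile, adult
#' male and adult female plants (`X_J`, `X_M`, `X_F`, counted at the
#' flower scale) and male and female insects (`Y_M`, `Y_F`).
#'
#' @param X_J,X_M,X_F plant abundances (>= 0, finite).
#' @param Y_M,Y_F insect abundances (>= 0, finite).
#' @return A named numeric vector of length 5.
#' @examples
#' system_state(1, 0, 0, 7.5, 7.5)
#' @export
system_state <- function(X_J = 0, X_M = 0, X_F = 0, Y_M = 0, Y_F = 0) {
  s <- c(X_J = X_J, X_M = X_M, X_F = X_F, Y_M = Y_M, Y_F = Y_F)
  if (!all(is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be non-negative")
  s
}

state_names <- function() c("X_J", "X_M", "X_F", "Y_M", "Y_F")

as_system_state <- function(x) {
  if (length(x) != 5) stop("a system state has 5 components")
  if (is.null(names(x))) names(x) <- state_names()
  system_state(x[["X_J"]], x[["X_M"]], x[["X_F"]],
               x[["Y_M"]], x[["Y_F"]])
}

#' Per-visit choice probabilities of a male insect
#'
#' A searching male insect encounters male plants, female plants and
#' female insects in proportion to their abundance weighted by
#' attractiveness: `p_M = a_M X_M / D`, `p_F = a_F X_F / D`,
#' `p_Y = Y_F / D` with `D = a_M X_M + a_F X_F + Y_F`. When no target
#' exists (`D = 0`) all three probabilities are 0 by convention.
#'
#' @param state a system state (see [system_state()]); only `X_M`, `X_F`
#'   and `Y_F` enter.
#' @param params a `decept_params` object.
#' @return Named numeric vector `c(p_M, p_F, p_Y)` summing to 1 (or all
#'   zero).
#' @examples
#' visit_probabilities(system_state(0, 6, 1.5, 0, 7.5),
#'                     decept_params(a_M = 0.4, a_F = 0.4))
#' @export
visit_probabilities <- function(state, params) {
  state <- as_system_state(state)
  stopifnot(is.decept_params(params))
  D <- params$a_M * state[["X_M"]] + params$a_F * state[["X_F"]] +
    state[["Y_F"]]
  if (D <= 0) return(c(p_M = 0, p_F = 0, p_Y = 0))
  c(p_M = params$a_M * state[["X_M"]] / D,
    p_F = params$a_F * state[["X_F"]] / D,
    p_Y = state[["Y_F"]] / D)
}

check_probs <- function(probs) {
  if (length(probs) != 3) stop("probs must have 3 components (p_M, p_F, p_Y)")
  probs <- as.numeric(probs)
  if (!all(is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  tot <- sum(probs)
  if (tot != 0 && abs(tot - 1) > 1e-9)
    stop("probabilities must sum to 1 (or be all zero)")
  names(probs) <- c("p_M", "p_F", "p_Y")
  probs
}

check_N <- function(N) {
  if (length(N) != 1 || !is.finite(N) || N < 1 || N != round(N))
    stop("N must be a single integer >= 1")
  as.integer(N)
}

#' Lifetime visit statistics of a male insect (double-sum form)
#'
#' Expected lifetime visit counts of a male insect that makes at most
#' `N` visits and dies (is trapped) at its first female-plant visit:
#' `Q1`, the expected number of male-plant visits made before dying at a
#' female plant (pollen-carrying visits); `Q2`, the expected number of
#' female-insect visits (copulations); and `P`, the probability of ever
#' being trapped. This form evaluates the defining double sums over
#' visit-sequence compositions literally, with exact binomial
#' coefficients; [visit_stats_closed_form()] is the algebraically
#' simplified equivalent.
#'
#' @param probs per-visit probabilities `c(p_M, p_F, p_Y)` as returned by
#'   [visit_probabilities()] (summing to 1, or all zero).
#' @param N maximum lifetime number of visits, integer >= 1.
#' @return Named numeric vector `c(Q1, Q2, P)`.
#' @examples
#' visit_stats_combinatorial(c(0.22857143, 0.05714286, 0.71428571), 10)
#' @export
visit_stats_combinatorial <- function(probs, N) {
  probs <- check_probs(probs)
  N <- check_N(N)
  if (sum(probs) == 0) return(c(Q1 = 0, Q2 = 0, P = 0))
  p_M <- probs[["p_M"]]; p_F <- probs[["p_F"]]; p_Y <- probs[["p_Y"]]
  Q1 <- 0; Q2 <- 0
  for (j in 0:(N - 1)) {
    k <- 0:j
    cjk <- choose(j, k)
    Q1 <- Q1 + sum(k * cjk * p_M^k * p_Y^(j - k))
    Q2 <- Q2 + sum(k * cjk * p_Y^k * p_M^(j - k))
  }
  Q1 <- p_F * Q1
  k <- 0:N
  Q2 <- p_F * Q2 + sum(k * choose(N, k) * p_Y^k * p_M^(N - k))
  P <- sum(p_F * (1 - p_F)^(0:(N - 1)))
  c(Q1 = Q1, Q2 = Q2, P = P)
}

#' Lifetime visit statistics of a male insect (simplified form)
#'
#' Algebraic simplification of [visit_stats_combinatorial()] via the
#' binomial theorem: with `x = 1 - p_F` and
#' `S = sum_{j=1}^{N-1} j x^(j-1)`,
#' `Q1 = p_F p_M S`, `Q2 = p_F p_Y S + N p_Y x^(N-1)`, and
#' `P = 1 - x^N`. Agrees with the double-sum form to near machine
#' precision and is the form used inside the dynamics.
#'
#' @inheritParams visit_stats_combinatorial
#' @return Named numeric vector `c(Q1, Q2, P)`.
#' @examples
#' visit_stats_closed_form(c(0.5, 0.1, 0.4), 10)
#' @export
visit_stats_closed_form <- function(probs, N) {
  probs <- check_probs(probs)
  N <- check_N(N)
  if (sum(probs) == 0) return(c(Q1 = 0, Q2 = 0, P = 0))
  visit_stats_fast(probs[["p_M"]], probs[["p_F"]], probs[["p_Y"]], N)
}

## unchecked kernel shared with the ODE right-hand side
visit_stats_fast <- function(p_M, p_F, p_Y, N) {
  x <- 1 - p_F
  S <- if (N >= 2) {
    j <- seq_len(N - 1)
    sum(j * x^(j - 1))
  } else 0
  c(Q1 = p_F * p_M * S,
    Q2 = p_F * p_Y * S + N * p_Y * x^(N - 1),
    P = 1 - x^N)
}

#' Saturating pollination and mating success
#'
#' Holling type-II success fractions. Pollination success of female
#' plants is `Y_M Q1 / (A_X + Y_M Q1)`: it rises with the pool of
#' pollen-carrying male insects and saturates at 1. Mating success of
#' female insects is `Y_M Q2 / (A_Y + Y_M Q2)`.
#'
#' @param Y_M male insect abundance (>= 0).
#' @param Q1,Q2 expected lifetime visit counts (see
#'   [visit_stats_closed_form()]).
#' @param A_X,A_Y half-saturation coefficients.
#' @return A fraction in `[0, 1]`; 0 when the product `Y_M * Q` is 0.
#' @examples
#' pollination_success(1, 1, 1)  # half-saturation
#' @export
pollination_success <- function(Y_M, Q1, A_X) {
  stopifnot(Y_M >= 0, Q1 >= 0, A_X >= 0)
  v <- Y_M * Q1
  if (v == 0) return(0)
  v / (A_X + v)
}

#' @rdname pollination_success
#' @export
mating_success <- function(Y_M, Q2, A_Y) {
  stopifnot(Y_M >= 0, Q2 >= 0, A_Y >= 0)
  v <- Y_M * Q2
  if (v == 0) return(0)
  v / (A_Y + v)
}
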