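#' Monte Carlo simulation of individual visit sequences
#'
#' Independent stochastic check on the lifetime visit statistics: each
#' trial draws up to `N` visit events with categorical probabilities
#' `(p_M, p_F, p_Y)`. In lethal mode the sequence stops at the first
#' female-plant visit (the insect is trapped); `Q1` counts male-plant
#' visits strictly before that event, `Q2` counts female-insect visits
#' strictly before it (or over all `N` visits if no female plant is
#' ever hit), and `P` indicates whether a female-plant visit occurred.
#' In non-lethal mode all `N` visits are realised: `Q1` still counts
#' male-plant (pollen-carrying) visits before the first female-plant
#' visit, while `Q2` counts every female-insect visit.
#'
#' The RNG state is seeded locally and restored on exit, so calls are
#' reproducible without disturbing the caller's random stream.
#'
#' @param probs per-visit probabilities `c(p_M, p_F, p_Y)` summing to 1,
#'   or all zero (in which case every estimate is 0).
#' @param N maximum number of visits, integer >= 1.
#' @param n_trials number of simulated insects (>= 1).
#' @param seed integer seed.
#' @param lethal logical; `FALSE` selects the non-lethal variant.
#' @return A list of class `oracle_estimate` with elements `Q1_hat`,
#'   `Q2_hat`, `P_hat`, their standard errors `se_Q1`, `se_Q2`, `se_P`,
#'   and `n_trials`, `seed`, `lethal`.
#' @examples
#' simulate_visit_sequences(c(0.2, 0.1, 0.7), N = 10,
#'                          n_trials = 1000, seed = 1)
#' @export
simulate_visit_sequences <- function(probs, N, n_trials, seed,
                                     lethal = TRUE) {
  probs <- check_probs(probs)
  N <- check_N(N)
  if (length(n_trials) != 1 || !is.finite(n_trials) || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("n_trials must be a single integer >= 1")
  n_trials <- as.integer(n_trials)
  stopifnot(length(seed) == 1, is.finite(seed))

  if (sum(probs) == 0) {
    q1 <- q2 <- pp <- numeric(n_trials)
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    p_M <- probs[["p_M"]]; p_F <- probs[["p_F"]]
    u <- matrix(stats::runif(n_trials * N), n_trials, N)
    ## event codes: 1 male plant, 2 female plant, 3 female insect
    cat_m <- 1L * (u < p_M) + 2L * (u >= p_M & u < p_M + p_F) +
      3L * (u >= p_M + p_F)
    isF <- cat_m == 2L
    hitF <- rowSums(isF) > 0
    firstF <- max.col(isF, ties.method = "first")  # 1 when no hit; masked below
    firstF[!hitF] <- N + 1L
    before <- matrix(firstF, n_trials, N) > col(cat_m)
    malesBefore <- rowSums((cat_m == 1L) & before)
    gnatsBefore <- rowSums((cat_m == 3L) & before)
    gnatsAll <- rowSums(cat_m == 3L)
    if (lethal) {
      q1 <- ifelse(hitF, malesBefore, 0)
      q2 <- ifelse(hitF, gnatsBefore, gnatsAll)
    } else {
      q1 <- ifelse(hitF, malesBefore, 0)
      q2 <- gnatsAll
    }
    pp <- as.numeric(hitF)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(Q1_hat = mean(q1), Q2_hat = mean(q2), P_hat = mean(pp),
                 se_Q1 = se(q1), se_Q2 = se(q2), se_P = se(pp),
                 n_trials = n_trials, seed = seed, lethal = lethal),
            class = "oracle_estimate")
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat(sprintf("Visit-sequence Monte Carlo (%s mode, %d trials, seed %s)\n",
              if (x$lethal) "lethal" else "non-lethal",
              x$n_trials, format(x$seed)))
  cat(sprintf("  Q1 = %.5f (se %.5f)\n", x$Q1_hat, x$se_Q1))
  cat(sprintf("  Q2 = %.5f (se %.5f)\n", x$Q2_hat, x$se_Q2))
  cat(sprintf("  P  = %.5f (se %.5f)\n", x$P_hat, x$se_P))
  invisible(x)
}
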