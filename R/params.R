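#' Model parameters for a lethal deceptive pollination system
#'
#' Constructs and validates the full parameter vector of the plant-insect
#' model. Defaults are the calibrated values used throughout the package:
#' the fixed life-history rates, capacities and interaction coefficients,
#' plus the "varied" parameters (attractiveness, vegetative reproduction,
#' male-to-female transition) set to the vegetatively reproducing scenario
#' (`r_VM = r_VF = 0.02`, `g_MF = 0.01`, `a_M = a_F = 0.4`); use
#' [scenario_params()] to switch between the two study scenarios.
#'
#' @param a_M,a_F Attractiveness of male/female plants to male insects,
#'   relative to a female insect (dimensionless, >= 0).
#' @param r_VM,r_VF Vegetative (cormlet) reproduction rates of male and
#'   female plants (per unit time, >= 0).
#' @param r_P Sexual reproduction rate via pollination (per unit time).
#' @param K_X,K_Y Recruitment capacities of plant and insect (> 0).
#' @param g_JM,g_MF,g_FM Transition rates: juvenile to male (net
#'   maturation), male to female (sex change), female to male (sex
#'   reversal, realised in proportion to pollination success).
#' @param d_J,d_M,d_F Plant death rates (juvenile, adult male, adult
#'   female).
#' @param s Male birth ratio of the insect, in `[0, 1]`.
#' @param f Female-offspring production coefficient of the insect.
#' @param d_Y Insect natural death rate.
#' @param A_X,A_Y Half-saturation coefficients of pollination and mating
#'   success.
#' @param q Scaling of the lifetime trap probability P to a per-unit-time
#'   death rate.
#' @param N Maximum lifetime number of visits by a male insect (integer
#'   >= 1).
#'
#' @return An object of class `decept_params`: a named list of validated
#'   parameter values.
#' @examples
#' p <- decept_params()
#' p$K_X
#' p2 <- decept_params(a_M = 0.8, a_F = 0.8)
#' @export
decept_params <- function(a_M = 0.4, a_F = 0.4,
                          r_VM = 0.02, r_VF = 0.02,
                          r_P = 1,
                          K_X = 15, K_Y = 15,
                          g_JM = 0.05, g_MF = 0.01, g_FM = 0.01,
                          d_J = 0.015, d_M = 0.01, d_F = 0.01,
                          s = 0.5, f = 2, d_Y = 0.1,
                          A_X = 1, A_Y = 10,
                          q = 0.5, N = 10) {
  p <- list(a_M = a_M, a_F = a_F, r_VM = r_VM, r_VF = r_VF, r_P = r_P,
            K_X = K_X, K_Y = K_Y, g_JM = g_JM, g_MF = g_MF, g_FM = g_FM,
            d_J = d_J, d_M = d_M, d_F = d_F, s = s, f = f, d_Y = d_Y,
            A_X = A_X, A_Y = A_Y, q = q, N = N)
  validate_params(p)
}

#' @rdname decept_params
#' @param x object to test or print.
#' @export
is.decept_params <- function(x) inherits(x, "decept_params")

param_names <- function() {
  c("a_M", "a_F", "r_VM", "r_VF", "r_P", "K_X", "K_Y",
    "g_JM", "g_MF", "g_FM", "d_J", "d_M", "d_F",
    "s", "f", "d_Y", "A_X", "A_Y", "q", "N")
}

## single validation pass at construction; downstream code assumes a
## validated object (class marker carries that guarantee)
validate_params <- function(p) {
  stopifnot(is.list(p))
  unknown <- setdiff(names(p), param_names())
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(param_names(), names(p))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  for (nm in param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
  }
  nonneg <- setdiff(param_names(), c("K_X", "K_Y", "N", "s"))
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter ", nm, " must be non-negative")
  if (p$K_X <= 0) stop("parameter K_X must be strictly positive")
  if (p$K_Y <= 0) stop("parameter K_Y must be strictly positive")
  if (p$s < 0 || p$s > 1) stop("parameter s must lie in [0, 1]")
  if (p$N < 1 || p$N != round(p$N))
    stop("parameter N must be an integer >= 1")
  p$N <- as.integer(p$N)
  p <- p[param_names()]
  structure(p, class = "decept_params")
}

#' Update parameters with named overrides
#'
#' @param params a `decept_params` object.
#' @param ... named scalar overrides (unknown names are an error), or a
#'   single named list of such overrides.
#' @return A validated `decept_params` object.
#' @examples
#' p <- update_params(decept_params(), g_MF = 0.02)
#' @export
update_params <- function(params, ...) {
  stopifnot(is.decept_params(params))
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  if (length(ov) == 0) return(params)
  if (is.null(names(ov)) || any(names(ov) == ""))
    stop("overrides must be named")
  p <- unclass(params)
  for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  validate_params(p)
}

#' Scenario presets for the two study parameterisations
#'
#' The two empirical scenarios of the system: `"first"` describes species
#' without vegetative reproduction and with slow male-to-female sex
#' change (`r_VM = r_VF = 0`, `g_MF = 0.005`); `"second"` describes
#' species with cormlet production and faster sex change
#' (`r_VM = r_VF = 0.02`, `g_MF = 0.01`).
#'
#' @param name `"first"` or `"second"`.
#' @param base parameters to start from; defaults to [decept_params()].
#' @param ... further overrides applied after the preset (e.g. `a_M`).
#' @return A `decept_params` object.
#' @examples
#' scenario_params("first", a_M = 0.6, a_F = 0.6)
#' @export
scenario_params <- function(name = c("first", "second"),
                            base = decept_params(), ...) {
  name <- match.arg(name)
  ov <- switch(name,
               first  = list(r_VM = 0, r_VF = 0, g_MF = 0.005),
               second = list(r_VM = 0.02, r_VF = 0.02, g_MF = 0.01))
  update_params(update_params(base, ov), ...)
}

#' @export
print.decept_params <- function(x, ...) {
  cat("Lethal deceptive pollination model parameters\n")
  v <- unlist(unclass(x))
  cat("  attractiveness   a_M =", v["a_M"], " a_F =", v["a_F"], "\n")
  cat("  reproduction     r_VM =", v["r_VM"], " r_VF =", v["r_VF"],
      " r_P =", v["r_P"], "\n")
  cat("  capacities       K_X =", v["K_X"], " K_Y =", v["K_Y"], "\n")
  cat("  transitions      g_JM =", v["g_JM"], " g_MF =", v["g_MF"],
      " g_FM =", v["g_FM"], "\n")
  cat("  plant deaths     d_J =", v["d_J"], " d_M =", v["d_M"],
      " d_F =", v["d_F"], "\n")
  cat("  insect           s =", v["s"], " f =", v["f"],
      " d_Y =", v["d_Y"], "\n")
  cat("  saturation       A_X =", v["A_X"], " A_Y =", v["A_Y"], "\n")
  cat("  visits           q =", v["q"], " N =", v["N"], "\n")
  invisible(x)
}

#' @export
as.list.decept_params <- function(x, ...) unclass(x)

#' Read and write parameter sets as flat JSON
#'
#' Parameter files are a flat JSON object keyed by the model symbol names
#' (`"a_M"`, `"g_MF"`, ...). The round trip is loss-free.
#'
#' @param params a `decept_params` object.
#' @param path file path.
#' @return `read_params` returns a validated `decept_params`;
#'   `write_params` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_params(decept_params(), f)
#' read_params(f)
#' @export
write_params <- function(params, path) {
  stopifnot(is.decept_params(params))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_params(lapply(as.list(p), as.numeric))
}
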