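#' Write a trajectory as CSV
#'
#' Columns `t, X_J, X_M, X_F, Y_M, Y_F`, RFC-4180 dialect with a header
#' row.
#'
#' @param sim a `decept_sim` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "decept_sim"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Write a steady-state summary as JSON
#'
#' The record carries the window means, sex ratios, window, outcome,
#' any extinction-clamp events, and a verbatim echo of the effective
#' parameter set so the run can be reproduced from the file alone.
#'
#' @param steady a `decept_steady` summary.
#' @param outcome the outcome string from [classify_outcome()].
#' @param params the `decept_params` used.
#' @param path output file path.
#' @param events optional data.frame of extinction-clamp events.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(steady, outcome, params, path,
                               events = NULL) {
  stopifnot(inherits(steady, "decept_steady"), is.decept_params(params))
  rec <- list(
    summary = list(mean_X_J = steady$mean_X_J,
                   mean_X_M = steady$mean_X_M,
                   mean_X_F = steady$mean_X_F,
                   mean_Y_M = steady$mean_Y_M,
                   mean_Y_F = steady$mean_Y_F,
                   plant_male_ratio = steady$plant_male_ratio,
                   insect_male_ratio = steady$insect_male_ratio,
                   window = as.list(steady$window)),
    outcome = outcome,
    parameters = unclass(params))
  if (!is.null(events) && nrow(events) > 0)
    rec$events <- events
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a regime map as long-format CSV plus JSON metadata
#'
#' The CSV holds one row per grid cell (axis values, outcome, window
#' means, ratios). The JSON sidecar (`<path>.meta.json`) echoes the
#' axes, the base parameter set and, when present, the analytic
#' persistence boundary.
#'
#' @param map a `decept_regime` object.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  stopifnot(inherits(map, "decept_regime"))
  utils::write.csv(map$summaries, path, row.names = FALSE)
  meta <- list(
    axis1 = map$axis1[c("name", "min", "max", "n")],
    axis2 = map$axis2[c("name", "min", "max", "n")],
    parameters = unclass(map$base))
  if (!is.null(map$boundary)) meta$boundary <- map$boundary
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
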