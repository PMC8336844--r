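# JSON (de)serialisation of model configurations. A config document maps
# fate-group names to model parameter blocks and optionally carries a
# "fixtures" block for the parametric input distributions. Presets
# round-trip through this format with the printed parameter values verbatim.

schedule_to_breakpoints <- function(sched) {
  lapply(seq_along(sched$times), function(i) {
    list(time_h = sched$times[i], value = sched$values[i])
  })
}

breakpoints_to_schedule <- function(bp) {
  if (is.numeric(bp) && length(bp) == 1L) return(make_schedule(bp))
  mat <- do.call(rbind, lapply(bp, function(b) c(b$time_h, b$value)))
  make_schedule(mat)
}

#' Serialise a model set to a config list
#'
#' @param model A single \code{\link{model_spec}} or a named per-fate list.
#' @param fixtures Optional \code{\link{fixture_config}} to embed.
#' @return A list ready for \code{jsonlite::write_json}.
#' @export
model_config <- function(model, fixtures = NULL) {
  if (inherits(model, "model_spec")) model <- list(all = model)
  groups <- lapply(model, function(spec) {
    out <- list(
      model = spec$model,
      r_breakpoints = schedule_to_breakpoints(spec$r),
      K_breakpoints = schedule_to_breakpoints(spec$K),
      sigmaA_breakpoints = schedule_to_breakpoints(spec$sigma_A),
      sigmaM_breakpoints = schedule_to_breakpoints(spec$sigma_M),
      hurst = spec$hurst
    )
    if (!is.null(spec$allee_A)) {
      out$allee_A <- spec$allee_A
      out$allee_on_time_h <- spec$allee_on_time
    }
    if (!is.null(spec$boundary)) {
      out$boundary <- list(kind = spec$boundary$kind,
                           low = spec$boundary$low, high = spec$boundary$high)
    }
    out
  })
  cfg <- list(groups = groups)
  if (!is.null(fixtures)) {
    cfg$fixtures <- list(
      cycle_mean = fixtures$cycle_mean, cycle_sd = fixtures$cycle_sd,
      cycle_range = fixtures$cycle_range,
      oct4_init_median = fixtures$oct4_init_median,
      oct4_init_cv = fixtures$oct4_init_cv, seed = fixtures$seed
    )
  }
  cfg
}

#' Write a model config to JSON
#'
#' @param model A \code{\link{model_spec}} or named per-fate list.
#' @param path Output path.
#' @param fixtures Optional \code{\link{fixture_config}}.
#' @return \code{path}, invisibly.
#' @export
write_model_config <- function(model, path, fixtures = NULL) {
  jsonlite::write_json(model_config(model, fixtures), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model config from JSON
#'
#' @param path JSON file written by \code{\link{write_model_config}} (or
#'   hand-authored in the same layout).
#' @return List with \code{model} (named per-fate list of
#'   \code{\link{model_spec}}) and \code{fixtures} (a
#'   \code{\link{fixture_config}} or \code{NULL}).
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  if (is.null(cfg$groups) || length(cfg$groups) == 0L) {
    stop("config has no `groups` entry", call. = FALSE)
  }
  model <- lapply(cfg$groups, function(g) {
    for (field in c("model", "r_breakpoints", "K_breakpoints",
                    "sigmaA_breakpoints", "sigmaM_breakpoints", "hurst")) {
      if (is.null(g[[field]])) {
        stop("config group is missing field `", field, "`", call. = FALSE)
      }
    }
    model_spec(
      model = g$model,
      r = breakpoints_to_schedule(g$r_breakpoints),
      K = breakpoints_to_schedule(g$K_breakpoints),
      sigma_A = breakpoints_to_schedule(g$sigmaA_breakpoints),
      sigma_M = breakpoints_to_schedule(g$sigmaM_breakpoints),
      hurst = g$hurst,
      allee_A = g$allee_A,
      allee_on_time = g$allee_on_time_h,
      boundary = if (!is.null(g$boundary)) {
        boundary_spec(g$boundary$kind, g$boundary$low, g$boundary$high)
      }
    )
  })
  fixtures <- if (!is.null(cfg$fixtures)) {
    f <- cfg$fixtures
    fixture_config(cycle_mean = f$cycle_mean, cycle_sd = f$cycle_sd,
                   cycle_range = unlist(f$cycle_range),
                   oct4_init_median = f$oct4_init_median,
                   oct4_init_cv = f$oct4_init_cv,
                   seed = if (is.null(f$seed)) 1L else f$seed)
  }
  list(model = model, fixtures = fixtures)
}
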