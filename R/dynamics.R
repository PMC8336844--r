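#' OCT4 dynamics models
#'
#' The per-cell OCT4 series is generated, one Euler step per 5-minute frame,
#' by one of six models:
#' \describe{
#'   \item{FBM_WALK}{pure fractional Brownian motion,
#'     \eqn{O(t) = O(0) + \sigma_A B_H(t)}, optionally with absorbing or
#'     reflecting boundaries;}
#'   \item{SLE_ADDITIVE}{the stochastic logistic equation with additive
#'     (state-independent) noise, integrated in O-space with an absorbing
#'     floor at zero;}
#'   \item{SLE_MULTIPLICATIVE}{the logistic equation in log-space
#'     \eqn{X = \ln O} with noise added to \eqn{dX/dt}, so the effective
#'     amplitude in O scales with O;}
#'   \item{SLE_COMBINED}{both noise terms at once in log-space (the additive
#'     term enters as \eqn{\sigma_A e^{-X}\xi_1});}
#'   \item{SLE_TIME_K}{the combined form with a time-dependent carrying
#'     capacity \eqn{K(t)};}
#'   \item{SLE_ALLEE}{the combined form whose deterministic drift gains the
#'     Allee factor \eqn{(O - A)/K} from \code{allee_on_time} onward,
#'     creating an unstable threshold at \eqn{O = A} below which expression
#'     collapses to zero.}
#' }
#' All rates are per 5-minute frame; schedules are functions of hours.
#'
#' @param model One of \code{"FBM_WALK"}, \code{"SLE_ADDITIVE"},
#'   \code{"SLE_MULTIPLICATIVE"}, \code{"SLE_COMBINED"}, \code{"SLE_TIME_K"},
#'   \code{"SLE_ALLEE"}.
#' @param r Growth/regulation rate per frame; a constant or schedule
#'   breakpoints (see \code{\link{make_schedule}}).
#' @param K Carrying capacity in a.f.u.; constant or schedule breakpoints.
#' @param sigma_A Additive noise scale in a.f.u. per frame; constant or
#'   schedule breakpoints.
#' @param sigma_M Multiplicative (log-space) noise scale, dimensionless;
#'   constant or schedule breakpoints.
#' @param hurst Hurst exponent of the driving fractional Gaussian noise.
#' @param allee_A Allee critical point in a.f.u. (SLE_ALLEE only).
#' @param allee_on_time Hour at which the Allee term switches on
#'   (SLE_ALLEE only).
#' @param boundary Optional \code{\link{boundary_spec}} (FBM_WALK only).
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(model = c("FBM_WALK", "SLE_ADDITIVE", "SLE_MULTIPLICATIVE",
                                 "SLE_COMBINED", "SLE_TIME_K", "SLE_ALLEE"),
                       r = 0, K = 1290, sigma_A = 0, sigma_M = 0,
                       hurst = 0.38, allee_A = NULL, allee_on_time = NULL,
                       boundary = NULL) {
  model <- match.arg(model)
  check_hurst(hurst)
  spec <- structure(list(
    model = model,
    r = make_schedule(r),
    K = make_schedule(K),
    sigma_A = make_schedule(sigma_A),
    sigma_M = make_schedule(sigma_M),
    hurst = hurst,
    allee_A = allee_A,
    allee_on_time = allee_on_time,
    boundary = boundary
  ), class = "model_spec")
  if (any(spec$K$values <= 0)) stop("carrying capacity must be positive", call. = FALSE)
  if (any(spec$r$values < 0) || any(spec$sigma_A$values < 0) ||
      any(spec$sigma_M$values < 0)) {
    stop("r, sigma_A and sigma_M must be non-negative", call. = FALSE)
  }
  if (model == "SLE_ALLEE") {
    if (is.null(allee_A) || is.null(allee_on_time)) {
      stop("SLE_ALLEE requires `allee_A` and `allee_on_time`", call. = FALSE)
    }
    if (allee_A < 0) stop("`allee_A` must be >= 0", call. = FALSE)
  }
  if (!is.null(boundary) && !inherits(boundary, "boundary_spec")) {
    stop("`boundary` must be a boundary_spec", call. = FALSE)
  }
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, H = %.3f\n", x$model, x$hurst))
  for (nm in c("r", "K", "sigma_A", "sigma_M")) {
    cat(" ", nm, ": ", paste(sprintf("%g h -> %g", x[[nm]]$times, x[[nm]]$values),
                             collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$allee_A)) {
    cat(sprintf("  Allee: A = %g a.f.u. from %g h\n", x$allee_A, x$allee_on_time))
  }
  invisible(x)
}

#' Boundary specification for the pure fBm walk
#'
#' @param kind \code{"absorbing"} (the series stops at the first crossing)
#'   or \code{"reflecting"} (the value is folded back into the interior,
#'   v -> 2*bound - v, iterated until interior).
#' @param low Lower bound in a.f.u. (default 0, expression cannot be negative).
#' @param high Upper bound in a.f.u. (default 2500, covering 99.9\% of the
#'   experimental values this package was built against).
#' @return A \code{boundary_spec} object.
#' @export
boundary_spec <- function(kind = c("absorbing", "reflecting"),
                          low = 0, high = 2500) {
  kind <- match.arg(kind)
  if (!(low < high)) stop("`low` must be below `high`", call. = FALSE)
  structure(list(kind = kind, low = low, high = high), class = "boundary_spec")
}

# Expression floor for the log-space models, in a.f.u.: a step landing at or
# below it is clamped here (0.01 a.f.u. is indistinguishable from zero on
# the measurement scale). The clamp does not fix the cell's future: under an
# armed Allee term the drift below A is negative, so a collapsed cell stays
# at the floor; under plain logistic regulation the drift is positive and
# the cell recovers towards K.
SLE_FLOOR <- 1e-2
# Overflow guard: X = ln(O) is capped at ln(1e6) a.f.u.; reaching it
# indicates a runaway parameterisation and is reported, never silent.
SLE_CEILING_LOG <- log(1e6)

#' Simulate a pure fractional Brownian OCT4 walk
#'
#' One cell's series as \code{start + sigma_A * cumsum(fGn)}, optionally
#' constrained by a boundary. Absorbing boundaries end the series at the
#' first crossing (the value is recorded at the bound); reflecting
#' boundaries fold crossing values back into the interior,
#' \code{v -> 2*bound - v}, iterated until interior.
#'
#' @param start Starting OCT4 value in a.f.u.; must lie strictly inside any
#'   boundary.
#' @param spec A \code{\link{model_spec}} with \code{model = "FBM_WALK"};
#'   its \code{sigma_A} schedule sets the per-frame noise scale.
#' @param n_frames Number of 5-minute steps to simulate.
#' @param noise A \code{noise_pack} with at least \code{n_frames} increments.
#' @param t0_hours Absolute start time, used to evaluate the
#'   \code{sigma_A} schedule.
#' @return List with \code{values} (length \code{n_frames + 1} unless
#'   absorbed earlier) and \code{status} (\code{"completed"},
#'   \code{"absorbed_low"} or \code{"absorbed_high"}).
#' @export
simulate_fbm_walk <- function(start, spec, n_frames, noise, t0_hours = 0) {
  stopifnot(inherits(spec, "model_spec"), inherits(noise, "noise_pack"))
  if (spec$model != "FBM_WALK") stop("spec$model must be FBM_WALK", call. = FALSE)
  if (noise$length < n_frames) stop("noise pack too short", call. = FALSE)
  b <- spec$boundary
  if (!is.null(b) && (start <= b$low || start >= b$high)) {
    stop("`start` must lie strictly inside the boundary", call. = FALSE)
  }
  t_h <- t0_hours + seq_len(n_frames) * FRAME_HOURS
  steps <- schedule_value(spec$sigma_A, t_h) * noise$increments[seq_len(n_frames)]

  if (is.null(b)) {
    return(list(values = c(start, start + cumsum(steps)), status = "completed"))
  }
  values <- numeric(n_frames + 1L)
  values[1L] <- start
  v <- start
  if (b$kind == "absorbing") {
    for (i in seq_len(n_frames)) {
      v <- v + steps[i]
      if (v <= b$low) {
        values[i + 1L] <- b$low
        return(list(values = values[seq_len(i + 1L)], status = "absorbed_low"))
      }
      if (v >= b$high) {
        values[i + 1L] <- b$high
        return(list(values = values[seq_len(i + 1L)], status = "absorbed_high"))
      }
      values[i + 1L] <- v
    }
  } else {
    for (i in seq_len(n_frames)) {
      v <- v + steps[i]
      while (v < b$low || v > b$high) {
        if (v < b$low) v <- 2 * b$low - v
        if (v > b$high) v <- 2 * b$high - v
      }
      values[i + 1L] <- v
    }
  }
  list(values = values, status = "completed")
}

#' Integrate the stochastic logistic equation for one cell
#'
#' Explicit Euler-Maruyama at one 5-minute frame per step. The additive-noise
#' model is integrated in O-space,
#' \deqn{O_{t+1} = O_t + r O_t (1 - O_t/K) + \sigma_A \xi_t,}
#' with an absorbing floor at zero (once the noise drives O below zero the
#' deterministic drift is also negative and O would run away to minus
#' infinity). All other logistic variants are integrated in log-space
#' \eqn{X = \ln O}: drift and multiplicative noise advance X,
#' \deqn{\tilde X = X_t + r (1 - e^{X_t}/K(t)) g_t + \sigma_M(t) \xi^{(2)}_t,}
#' and the additive (state-independent) noise is then applied in level
#' space, \eqn{O_{t+1} = e^{\tilde X} + \sigma_A(t) \xi^{(1)}_t}. To first
#' order this is the log-space term \eqn{\sigma_A e^{-X}\xi^{(1)}}, but it
#' remains stable when expression collapses towards zero, where the
#' linearised factor \eqn{e^{-X}} diverges. \eqn{g_t = 1} except for the
#' Allee model, which uses \eqn{g_t = (e^{X_t} - A)/K(t)} once
#' \eqn{t \ge} \code{allee_on_time}. A step landing at or below the
#' expression floor of 0.01 a.f.u. is clamped there; whether the cell stays
#' is left to the dynamics (an armed Allee term holds it down, plain
#' logistic regulation lifts it back). X is capped at ln(1e6) with a
#' warning, never silently.
#'
#' @param start Positive starting OCT4 value in a.f.u.
#' @param spec A \code{\link{model_spec}} with one of the SLE models.
#' @param n_frames Number of 5-minute steps.
#' @param noise1 \code{noise_pack} driving the additive term.
#' @param noise2 \code{noise_pack} driving the multiplicative term (may be
#'   omitted when \code{sigma_M} is identically zero).
#' @param t0_hours Absolute start time in hours; schedules and the Allee
#'   switch are evaluated in absolute time.
#' @return List with \code{values} (a.f.u., length \code{n_frames + 1}
#'   unless absorbed earlier) and \code{status}.
#' @export
integrate_sle <- function(start, spec, n_frames, noise1 = NULL, noise2 = NULL,
                          t0_hours = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$model %in% c("SLE_ADDITIVE", "SLE_MULTIPLICATIVE", "SLE_COMBINED",
                         "SLE_TIME_K", "SLE_ALLEE")) {
    stop("spec$model must be one of the SLE variants", call. = FALSE)
  }
  if (start <= 0) stop("`start` must be positive for the logistic models",
                       call. = FALSE)
  n_frames <- as.integer(n_frames)
  t_h <- t0_hours + seq_len(n_frames) * FRAME_HOURS   # time at end of each step
  t_eval <- t0_hours + (seq_len(n_frames) - 1L) * FRAME_HOURS  # schedule time
  r <- schedule_value(spec$r, t_eval)
  K <- schedule_value(spec$K, t_eval)
  sA <- schedule_value(spec$sigma_A, t_eval)
  sM <- schedule_value(spec$sigma_M, t_eval)
  if (spec$model == "SLE_MULTIPLICATIVE") sA[] <- 0   # purely multiplicative
  xi1 <- noise_increments(noise1, n_frames, need = any(sA > 0))
  xi2 <- noise_increments(noise2, n_frames, need = any(sM > 0))

  if (spec$model == "SLE_ADDITIVE") {
    values <- numeric(n_frames + 1L)
    values[1L] <- v <- start
    for (i in seq_len(n_frames)) {
      v <- v + r[i] * v * (1 - v / K[i]) + sA[i] * xi1[i]
      if (v <= 0) {
        values[i + 1L] <- 0
        return(list(values = values[seq_len(i + 1L)], status = "absorbed_low"))
      }
      values[i + 1L] <- v
    }
    return(list(values = values, status = "completed"))
  }

  allee_active <- if (spec$model == "SLE_ALLEE") {
    t_eval >= spec$allee_on_time
  } else rep(FALSE, n_frames)

  x_floor <- log(SLE_FLOOR)
  x <- numeric(n_frames + 1L)
  x[1L] <- max(log(start), x_floor)
  capped <- FALSE
  for (i in seq_len(n_frames)) {
    o <- exp(x[i])
    g <- if (allee_active[i]) (o - spec$allee_A) / K[i] else 1
    # drift and multiplicative noise advance X; the additive (state-
    # independent) kick is applied in level space, the stable form of the
    # first-order term sigma_A * exp(-X) * xi
    xdrift <- x[i] + r[i] * (1 - o / K[i]) * g + sM[i] * xi2[i]
    if (xdrift > SLE_CEILING_LOG) {
      xdrift <- SLE_CEILING_LOG
      capped <- TRUE
    }
    onew <- exp(xdrift) + sA[i] * xi1[i]
    # clamp at the expression floor; whether the cell stays there is decided
    # by the dynamics (negative Allee drift keeps it down, logistic
    # regulation lifts a non-Allee cell back towards K)
    x[i + 1L] <- if (onew <= SLE_FLOOR) x_floor else log(onew)
  }
  if (capped) {
    warning("integrate_sle: log-expression hit the overflow cap ln(1e6); ",
            "the parameterisation is running away", call. = FALSE)
  }
  list(values = exp(x), status = "completed")
}

noise_increments <- function(noise, n_frames, need) {
  if (!need) return(numeric(n_frames))
  if (is.null(noise)) stop("a noise pack is required for a non-zero noise term",
                           call. = FALSE)
  stopifnot(inherits(noise, "noise_pack"))
  if (noise$length < n_frames) stop("noise pack too short", call. = FALSE)
  noise$increments[seq_len(n_frames)]
}

#' Published parameter presets for the OCT4 models
#'
#' Returns the per-fate \code{\link{model_spec}} set for each regime studied
#' with the models in this package, exactly as parameterised:
#' \describe{
#'   \item{fig3_additive}{additive-noise SLE, both fates together:
#'     r = 0.02, K = 1290, sigma_A = 90, H = 0.38.}
#'   \item{fig3_multiplicative}{multiplicative-noise SLE, both fates:
#'     r = 0.005, K = 1290, sigma_M = 0.0045.}
#'   \item{fig4_noise_switch}{combined noise; pluripotent cells switch from
#'     purely additive (sigma_A = 90) to purely multiplicative
#'     (sigma_M = 0.05) at 20 h, r = 0.01, K = 1290; differentiated cells
#'     keep K = 1000, sigma_A = 90 throughout.}
#'   \item{fig5_time_K}{time-dependent carrying capacity: pluripotent
#'     K 1500 -> 1000 at 25 h (sigma_A = 30, sigma_M = 0.035),
#'     differentiated K 1100 -> 1000 (sigma_A = 20, sigma_M = 0.03),
#'     r = 0.015 for both.}
#'   \item{fig6_time_K_differentiation}{as fig5 plus the differentiation
#'     step: differentiated K drops to 300 at 43 h with r = 0.008 from
#'     43 h on.}
#'   \item{fig6_allee}{single population, Allee differentiation:
#'     r = 0.025, K = 1290, sigma_A = 35, sigma_M = 0.035, A = 1000,
#'     Allee term armed at 43 h (when the differentiation agent is added).}
#' }
#' All presets use H = 0.38, the anti-persistence measured in the
#' experimental colony.
#'
#' @param name Preset name.
#' @return Named list of \code{model_spec} objects, one per fate group the
#'   preset distinguishes (a single \code{"all"} entry when it does not).
#' @export
preset <- function(name = c("fig3_additive", "fig3_multiplicative",
                            "fig4_noise_switch", "fig5_time_K",
                            "fig6_time_K_differentiation", "fig6_allee")) {
  name <- match.arg(name)
  H <- 0.38
  switch(name,
    fig3_additive = list(
      all = model_spec("SLE_ADDITIVE", r = 0.02, K = 1290, sigma_A = 90,
                       hurst = H)
    ),
    fig3_multiplicative = list(
      all = model_spec("SLE_MULTIPLICATIVE", r = 0.005, K = 1290,
                       sigma_M = 0.0045, hurst = H)
    ),
    fig4_noise_switch = list(
      pluripotent = model_spec("SLE_COMBINED", r = 0.01, K = 1290,
                               sigma_A = rbind(c(0, 90), c(20, 0)),
                               sigma_M = rbind(c(0, 0), c(20, 0.05)),
                               hurst = H),
      differentiated = model_spec("SLE_COMBINED", r = 0.01, K = 1000,
                                  sigma_A = 90, sigma_M = 0, hurst = H)
    ),
    fig5_time_K = list(
      pluripotent = model_spec("SLE_TIME_K", r = 0.015,
                               K = rbind(c(0, 1500), c(25, 1000)),
                               sigma_A = 30, sigma_M = 0.035, hurst = H),
      differentiated = model_spec("SLE_TIME_K", r = 0.015,
                                  K = rbind(c(0, 1100), c(25, 1000)),
                                  sigma_A = 20, sigma_M = 0.03, hurst = H)
    ),
    fig6_time_K_differentiation = list(
      pluripotent = model_spec("SLE_TIME_K", r = 0.015,
                               K = rbind(c(0, 1500), c(25, 1000)),
                               sigma_A = 30, sigma_M = 0.035, hurst = H),
      differentiated = model_spec("SLE_TIME_K",
                                  r = rbind(c(0, 0.015), c(43, 0.008)),
                                  K = rbind(c(0, 1100), c(25, 1000), c(43, 300)),
                                  sigma_A = 20, sigma_M = 0.03, hurst = H)
    ),
    fig6_allee = list(
      all = model_spec("SLE_ALLEE", r = 0.025, K = 1290, sigma_A = 35,
                       sigma_M = 0.035, hurst = H, allee_A = 1000,
                       allee_on_time = 43)
    )
  )
}

#' Classify terminal-cell fates after an Allee-effect simulation
#'
#' Under the Allee model the differentiated state is an outcome, not an
#' input: a terminal (leaf) cell whose final OCT4 lies below the threshold
#' (default: the Allee critical point A) is classed differentiated, the rest
#' pluripotent. Labels are propagated backwards through the lineage as
#' pro-fates: an ancestor whose terminal descendants all share one fate
#' inherits it; ancestors with mixed descendants are labelled
#' \code{"unknown"}.
#'
#' @param traj A \code{colony_trajectory} produced under an
#'   \code{SLE_ALLEE} model.
#' @param threshold Classification threshold in a.f.u.; defaults to the
#'   Allee critical point recorded in the trajectory's model.
#' @return The trajectory with updated per-cell \code{fate} labels.
#' @export
classify_fates_allee <- function(traj, threshold = NULL) {
  stopifnot(inherits(traj, "colony_trajectory"))
  models <- vapply(traj$model, function(m) m$model, character(1))
  if (!all(models == "SLE_ALLEE")) {
    stop("fate classification by final OCT4 is only meaningful for ",
         "trajectories simulated under the Allee model", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- traj$model[[1L]]$allee_A
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)

  cells <- traj$cells
  ids <- vapply(cells, `[[`, 0L, "cell_id")
  parents <- vapply(cells, function(c) {
    if (is.na(c$parent_id)) NA_integer_ else c$parent_id
  }, 0L)
  has_daughter <- ids %in% parents[!is.na(parents)]

  fate <- rep(NA_character_, length(cells))
  for (i in which(!has_daughter)) {
    final <- cells[[i]]$oct4[length(cells[[i]]$oct4)]
    fate[i] <- if (final < threshold) "differentiated" else "pluripotent"
  }
  # back-propagate: process cells in reverse id order (daughters have larger
  # ids than mothers by construction)
  ord <- order(ids, decreasing = TRUE)
  for (i in ord) {
    if (is.na(parents[i])) next
    p <- which(ids == parents[i])
    d_fates <- fate[which(parents == ids[p] & !is.na(parents))]
    fate[p] <- if (length(unique(d_fates)) == 1L && !anyNA(d_fates)) {
      d_fates[1L]
    } else "unknown"
  }
  for (i in seq_along(cells)) traj$cells[[i]]$fate <- fate[i]
  traj
}
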