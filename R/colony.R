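# The colony base model. Cells carry an OCT4 series on a common 5-minute
# frame grid; at the end of its cycle a cell divides into two daughters that
# both inherit its pre-division OCT4 value, and the simulation runs for a
# fixed budget of division events (not timesteps).

FRAME_HOURS <- 5 / 60
FRAMES_PER_HOUR <- 12L

# Deterministic seed splitting: every stochastic draw in a colony run is
# governed by the root seed through (cell_id, stream) offsets, so results do
# not depend on iteration order. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(root, id, stream) {
  as.integer((as.double(root %% 2147483647L) * 1103515 +
                as.double(id) * 7919 + as.double(stream) * 104729) %% 2147483629)
}

# Round a real-valued division delay up to the frame grid; every cell lives
# for at least one frame.
frames_ceiling <- function(hours) {
  max(1L, as.integer(ceiling(hours * FRAMES_PER_HOUR - 1e-9)))
}

#' Initialise a colony of cells at time zero
#'
#' Each founding cell receives an initial OCT4 value and a cell-cycle
#' duration drawn from the supplied samplers. In \code{"asynchronous"} mode
#' each cell's elapsed cycle fraction is drawn uniformly on (0, 1), so its
#' first division falls at \code{(1 - phase) * duration}; this spreads
#' divisions across frames the way a real unsynchronised colony divides.
#' \code{"synchronised"} mode starts every cell at the top of its cycle.
#'
#' @param n_pluripotent Number of founding cells labelled (pro-)pluripotent.
#' @param n_differentiated Number labelled (pro-)differentiated.
#' @param oct4_sampler Sampler for initial OCT4 (a.f.u.), e.g.
#'   \code{\link{make_initial_oct4_sampler}} or a \code{\link{kde_sampler}}.
#' @param cycle_sampler Sampler for cycle durations (hours); retained on the
#'   returned object and reused, unchanged, for every daughter generation.
#' @param phase_mode \code{"asynchronous"} (default) or
#'   \code{"synchronised"}.
#' @param seed Integer root seed.
#' @return A \code{colony_init} object holding the founding cells and the
#'   cycle sampler.
#' @export
init_colony <- function(n_pluripotent, n_differentiated,
                        oct4_sampler = make_initial_oct4_sampler(),
                        cycle_sampler = make_cycle_sampler(),
                        phase_mode = c("asynchronous", "synchronised"),
                        seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  n_p <- as.integer(n_pluripotent); n_d <- as.integer(n_differentiated)
  if (n_p < 0 || n_d < 0 || n_p + n_d < 1L) {
    stop("need at least one founding cell", call. = FALSE)
  }
  stopifnot(inherits(oct4_sampler, "oct4_sampler"),
            inherits(cycle_sampler, "oct4_sampler"))
  if (oct4_sampler$support[2L] <= 0) {
    stop("the initial-OCT4 sampler support must include positive values",
         call. = FALSE)
  }
  if (cycle_sampler$support[1L] <= 0) {
    stop("the cycle-duration sampler must have positive support", call. = FALSE)
  }
  n <- n_p + n_d
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, 0L, 0L))
  oct4_0 <- sampler_draw(oct4_sampler, n)
  durations <- sampler_draw(cycle_sampler, n)
  phases <- if (phase_mode == "asynchronous") stats::runif(n) else rep(0, n)

  cells <- vector("list", n)
  fates <- c(rep("pluripotent", n_p), rep("differentiated", n_d))
  for (i in seq_len(n)) {
    remaining <- (1 - phases[i]) * durations[i]
    cells[[i]] <- list(
      cell_id = i,
      parent_id = NA_integer_,
      fate = fates[i],
      birth_time = 0,
      cycle_duration = durations[i],
      n_frames = frames_ceiling(remaining),
      start_oct4 = oct4_0[i]
    )
  }
  structure(list(cells = cells, cycle_sampler = cycle_sampler,
                 phase_mode = phase_mode, seed = as.integer(seed)),
            class = "colony_init")
}

spec_for_fate <- function(model, fate) {
  if (inherits(model, "model_spec")) return(model)
  if (!is.null(model$all)) return(model$all)
  sp <- model[[fate]]
  if (is.null(sp)) {
    stop("no model_spec provided for fate '", fate, "'", call. = FALSE)
  }
  sp
}

simulate_cell_series <- function(cell, spec, root_seed) {
  n_frames <- cell$n_frames
  needs1 <- spec$model == "FBM_WALK" || spec$model == "SLE_ADDITIVE" ||
    any(spec$sigma_A$values > 0)
  needs2 <- any(spec$sigma_M$values > 0)
  noise1 <- if (needs1) {
    generate_fgn(n_frames, spec$hurst, derive_seed(root_seed, cell$cell_id, 1L))
  } else NULL
  noise2 <- if (needs2) {
    generate_fgn(n_frames, spec$hurst, derive_seed(root_seed, cell$cell_id, 2L))
  } else NULL
  if (spec$model == "FBM_WALK") {
    if (is.null(noise1)) {
      noise1 <- structure(list(increments = numeric(n_frames), hurst = spec$hurst,
                               seed = NA_integer_, length = n_frames),
                          class = "noise_pack")
    }
    simulate_fbm_walk(cell$start_oct4, spec, n_frames, noise1,
                      t0_hours = cell$birth_time)
  } else {
    integrate_sle(cell$start_oct4, spec, n_frames, noise1, noise2,
                  t0_hours = cell$birth_time)
  }
}

#' Run the colony base model
#'
#' Processes cells in order of division time. Each cell's OCT4 series is
#' simulated over its (remaining) cycle with the dynamics model bound to its
#' fate; at its division frame, if the event budget allows, two daughters
#' are created whose first value equals the mother's last, with freshly
#' sampled cycle durations. The budget counts divisions, not frames: when it
#' is spent, cells already alive still complete their current series.
#' Absorbed cells (boundary hit, or the additive model's floor at zero) do
#' not divide.
#'
#' @param initial_cells A \code{colony_init} from \code{\link{init_colony}}.
#' @param model A single \code{\link{model_spec}}, or a named list of specs
#'   per fate group (a \code{"all"} entry applies to every fate), e.g. from
#'   \code{\link{preset}}.
#' @param n_division_events Number of division events to perform (>= 0).
#' @param seed Integer root seed for the noise streams and daughter cycle
#'   draws; defaults to the seed recorded at initialisation.
#' @return A \code{colony_trajectory}: list with \code{cells} (each carrying
#'   \code{t} in hours and \code{oct4} in a.f.u.), the frame interval,
#'   the number of completed division events, the seed and the model set.
#' @export
run_colony <- function(initial_cells, model, n_division_events,
                       seed = initial_cells$seed) {
  stopifnot(inherits(initial_cells, "colony_init"))
  budget <- as.integer(n_division_events)
  if (budget < 0) stop("`n_division_events` must be >= 0", call. = FALSE)
  if (inherits(model, "model_spec")) model <- list(all = model)
  seed <- as.integer(seed)
  cycle_sampler <- initial_cells$cycle_sampler

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)

  cells <- initial_cells$cells
  n0 <- length(cells)
  # pending queue: indices into `cells` not yet simulated
  div_time <- vapply(cells, function(c) c$birth_time + c$n_frames * FRAME_HOURS,
                     numeric(1))
  pending <- seq_len(n0)
  next_id <- n0 + 1L
  events_done <- 0L

  while (length(pending) > 0L) {
    j <- pending[order(div_time[pending],
                       vapply(cells[pending], `[[`, 0, "cell_id"))[1L]]
    pending <- setdiff(pending, j)
    cell <- cells[[j]]
    spec <- spec_for_fate(model, cell$fate)
    sim <- simulate_cell_series(cell, spec, seed)
    n_used <- length(sim$values) - 1L
    cell$t <- cell$birth_time + (0:n_used) * FRAME_HOURS
    cell$oct4 <- sim$values
    cell$status <- sim$status
    cells[[j]] <- cell

    if (sim$status == "completed" && events_done < budget) {
      events_done <- events_done + 1L
      set.seed(derive_seed(seed, cell$cell_id, 3L))
      daughter_durations <- sampler_draw(cycle_sampler, 2L)
      birth <- cell$t[length(cell$t)]
      last_oct4 <- cell$oct4[length(cell$oct4)]
      for (k in 1:2) {
        d <- list(
          cell_id = next_id,
          parent_id = cell$cell_id,
          fate = cell$fate,
          birth_time = birth,
          cycle_duration = daughter_durations[k],
          n_frames = frames_ceiling(daughter_durations[k]),
          start_oct4 = last_oct4
        )
        cells[[length(cells) + 1L]] <- d
        div_time[length(cells)] <- birth + d$n_frames * FRAME_HOURS
        pending <- c(pending, length(cells))
        next_id <- next_id + 1L
      }
    }
  }

  structure(list(cells = cells, frame_interval = 5,
                 n_initial = n0, n_division_events = events_done,
                 seed = seed, model = model),
            class = "colony_trajectory")
}

#' @export
print.colony_trajectory <- function(x, ...) {
  term <- terminal_ids(x)
  cat(sprintf(paste0("<colony_trajectory> %d cell records (%d founding, ",
                     "%d division events, %d terminal cells), seed %d\n"),
              length(x$cells), x$n_initial, x$n_division_events,
              length(term), x$seed))
  invisible(x)
}

terminal_ids <- function(traj) {
  ids <- vapply(traj$cells, `[[`, 0L, "cell_id")
  parents <- vapply(traj$cells, function(c) {
    if (is.na(c$parent_id)) NA_integer_ else as.integer(c$parent_id)
  }, 0L)
  ids[!ids %in% parents]
}

#' Wrap a single OCT4 series as a one-cell trajectory
#'
#' Convenience constructor for feeding a bare series (simulated directly
#' with \code{\link{simulate_fbm_walk}} / \code{\link{integrate_sle}}, or
#' measured) into the trajectory-based analysis functions.
#'
#' @param values Numeric OCT4 series, one value per 5-minute frame.
#' @param fate Fate label for the cell.
#' @param birth_time Time of the first frame in hours.
#' @return A \code{colony_trajectory} with one cell.
#' @export
series_trajectory <- function(values, fate = "pluripotent", birth_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must be non-empty", call. = FALSE)
  cell <- list(cell_id = 1L, parent_id = NA_integer_, fate = fate,
               birth_time = birth_time, cycle_duration = NA_real_,
               t = birth_time + (seq_along(values) - 1L) * FRAME_HOURS,
               oct4 = values, status = "completed")
  structure(list(cells = list(cell), frame_interval = 5, n_initial = 1L,
                 n_division_events = 0L, seed = NA_integer_, model = NULL),
            class = "colony_trajectory")
}

#' Clip a trajectory to a time window
#'
#' All series are clipped to \code{[0, t_max]}; cells born after
#' \code{t_max} are dropped. A 68-hour window at 5-minute frames spans
#' exactly 817 frame times.
#'
#' @param traj A \code{colony_trajectory}.
#' @param t_max Window end in hours (> 0, or 0 to keep only the founding
#'   cells' first frame).
#' @return The clipped \code{colony_trajectory}.
#' @export
truncate_to_window <- function(traj, t_max) {
  stopifnot(inherits(traj, "colony_trajectory"))
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  eps <- 1e-9
  kept <- list()
  for (cell in traj$cells) {
    if (cell$birth_time > t_max + eps) next
    keep <- cell$t <= t_max + eps
    cell$t <- cell$t[keep]
    cell$oct4 <- cell$oct4[keep]
    if (length(cell$t) == 0L) next
    kept[[length(kept) + 1L]] <- cell
  }
  traj$cells <- kept
  traj
}

#' Flatten a trajectory to a long data frame
#'
#' One row per cell per frame, with columns \code{cell_id},
#' \code{parent_id}, \code{fate}, \code{t_hours}, \code{oct4_afu} —
#' the same layout the trajectory CSV uses.
#'
#' @param x A \code{colony_trajectory}.
#' @param ... Unused.
#' @return A \code{data.frame}.
#' @export
as.data.frame.colony_trajectory <- function(x, ...) {
  dfs <- lapply(x$cells, function(cell) {
    data.frame(cell_id = cell$cell_id,
               parent_id = if (is.na(cell$parent_id)) NA_integer_ else cell$parent_id,
               fate = cell$fate,
               t_hours = cell$t,
               oct4_afu = cell$oct4)
  })
  do.call(rbind, dfs)
}

#' Write a trajectory to CSV
#'
#' Long format, header \code{cell_id,parent_id,fate,t_hours,oct4_afu}; OCT4
#' is written with 6 significant digits. Lineage is recoverable from
#' \code{parent_id}.
#'
#' @param traj A \code{colony_trajectory}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$oct4_afu <- signif(df$oct4_afu, 6)
  df$t_hours <- round(df$t_hours, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Inverse of \code{\link{write_trajectory}}, with validation: series must
#' sit on the 5-minute grid, every non-founding cell must have exactly one
#' parent present, every mother exactly two daughters, and each daughter's
#' first value must equal its mother's last.
#'
#' @param path CSV file path.
#' @return A \code{colony_trajectory} (with no model attached).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("cell_id", "parent_id", "fate", "t_hours", "oct4_afu")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trajectory CSV is empty", call. = FALSE)
  bad <- which(!is.finite(df$t_hours) | !is.finite(df$oct4_afu))
  if (length(bad) > 0L) {
    stop("malformed rows at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  }
  cells <- list()
  for (id in unique(df$cell_id)) {
    rows <- df[df$cell_id == id, , drop = FALSE]
    rows <- rows[order(rows$t_hours), , drop = FALSE]
    frames <- round(rows$t_hours * FRAMES_PER_HOUR)
    if (any(abs(rows$t_hours * FRAMES_PER_HOUR - frames) > 1e-3) ||
        (nrow(rows) > 1L && any(diff(frames) != 1L))) {
      stop("cell ", id, ": series is not on a uniform 5-minute grid",
           call. = FALSE)
    }
    cells[[length(cells) + 1L]] <- list(
      cell_id = as.integer(id),
      parent_id = if (is.na(rows$parent_id[1L])) NA_integer_ else as.integer(rows$parent_id[1L]),
      fate = as.character(rows$fate[1L]),
      birth_time = rows$t_hours[1L],
      cycle_duration = NA_real_,
      t = rows$t_hours,
      oct4 = rows$oct4_afu,
      status = "completed"
    )
  }
  traj <- structure(list(cells = cells, frame_interval = 5,
                         n_initial = sum(vapply(cells, function(c) is.na(c$parent_id), TRUE)),
                         n_division_events = NA_integer_,
                         seed = NA_integer_, model = NULL),
                    class = "colony_trajectory")
  validate_trajectory(traj)
  traj
}

validate_trajectory <- function(traj) {
  ids <- vapply(traj$cells, `[[`, 0L, "cell_id")
  if (anyDuplicated(ids)) stop("duplicate cell ids", call. = FALSE)
  by_id <- stats::setNames(seq_along(ids), ids)
  n_daughters <- integer(length(ids))
  for (cell in traj$cells) {
    if (is.na(cell$parent_id)) next
    p <- by_id[as.character(cell$parent_id)]
    if (is.na(p)) {
      stop("cell ", cell$cell_id, " references missing parent ",
           cell$parent_id, call. = FALSE)
    }
    n_daughters[p] <- n_daughters[p] + 1L
    mother <- traj$cells[[p]]
    if (abs(cell$oct4[1L] - mother$oct4[length(mother$oct4)]) >
        1e-9 * max(1, abs(cell$oct4[1L]))) {
      stop("cell ", cell$cell_id,
           ": first value does not equal its mother's last value",
           call. = FALSE)
    }
  }
  if (any(!n_daughters %in% c(0L, 2L))) {
    stop("lineage is not a binary forest: some mother has ",
         "a number of daughters other than two", call. = FALSE)
  }
  invisible(traj)
}
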