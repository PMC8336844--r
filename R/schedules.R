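#' Piecewise-constant parameter schedule
#'
#' Builds a right-continuous step function of time (hours) from breakpoints:
#' the value at time \code{t} is the value of the latest breakpoint at or
#' before \code{t}. Model parameters that change during the experiment (the
#' carrying capacity dropping at 25 h, the additive-to-multiplicative noise
#' switch at 20 h, the Allee term arming at 43 h) are all expressed this way.
#'
#' @param breakpoints Either a single number (a constant schedule) or a
#'   two-column matrix / data.frame / list of \code{c(time, value)} pairs
#'   with strictly increasing times starting at 0.
#' @return A \code{schedule} object.
#' @examples
#' K <- make_schedule(rbind(c(0, 1500), c(25, 1000)))
#' schedule_value(K, 24.99)  # 1500
#' schedule_value(K, 25)     # 1000
#' @export
make_schedule <- function(breakpoints) {
  if (inherits(breakpoints, "schedule")) return(breakpoints)
  if (is.numeric(breakpoints) && length(breakpoints) == 1L) {
    breakpoints <- cbind(0, breakpoints)
  }
  if (is.list(breakpoints) && !is.data.frame(breakpoints)) {
    breakpoints <- do.call(rbind, lapply(breakpoints, function(b) as.numeric(b)))
  }
  bp <- as.matrix(breakpoints)
  if (ncol(bp) != 2L || nrow(bp) < 1L) {
    stop("breakpoints must be (time, value) pairs", call. = FALSE)
  }
  times <- as.numeric(bp[, 1L])
  values <- as.numeric(bp[, 2L])
  if (times[1L] != 0) stop("the first breakpoint must be at time 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, values = values), class = "schedule")
}

#' Evaluate a schedule at given times
#'
#' @param sched A \code{schedule} from \code{\link{make_schedule}}.
#' @param t Numeric vector of times in hours (must be >= 0).
#' @return Numeric vector of schedule values, right-continuous in \code{t}.
#' @export
schedule_value <- function(sched, t) {
  stopifnot(inherits(sched, "schedule"))
  if (any(t < 0)) stop("schedule evaluated at negative time", call. = FALSE)
  sched$values[findInterval(t, sched$times)]
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule> ", paste(sprintf("%g h -> %g", x$times, x$values),
                           collapse = ", "), "\n")
  invisible(x)
}

is_constant_schedule <- function(sched, value = NULL) {
  ok <- length(unique(sched$values)) == 1L
  if (ok && !is.null(value)) ok <- sched$values[1L] == value
  ok
}
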