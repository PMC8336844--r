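# Parametric stand-ins for the experimental input distributions. The
# experiment supplies only summary anchors (cycle durations 10.3 +/- 4 h on
# 0.25-30 h; initial OCT4 median about 1290 a.f.u.), not closed forms, so
# positive-support right-skewed families are moment-matched to those
# anchors: a truncated Gamma for cycle times and a lognormal for initial
# OCT4. Users with empirical columns bypass these via load_empirical().

#' Configuration of the parametric fixture distributions
#'
#' @param cycle_mean Target mean cell-cycle duration in hours
#'   (default 10.3).
#' @param cycle_sd Target cell-cycle standard deviation in hours
#'   (default 4).
#' @param cycle_range Hard support of cycle durations in hours
#'   (default \code{c(0.25, 30)}, the observed range).
#' @param oct4_init_median Median initial OCT4 in a.f.u. (default 1290, the
#'   median of all experimental OCT4 values).
#' @param oct4_init_cv Coefficient of variation of initial OCT4
#'   (default 0.25; not anchored by any printed value — adjust to taste or
#'   replace with an empirical column).
#' @param seed Integer seed recorded on derived samplers.
#' @return A \code{fixture_config} object.
#' @export
fixture_config <- function(cycle_mean = 10.3, cycle_sd = 4,
                           cycle_range = c(0.25, 30),
                           oct4_init_median = 1290, oct4_init_cv = 0.25,
                           seed = 1L) {
  if (length(cycle_range) != 2L || cycle_range[1L] <= 0 ||
      cycle_range[1L] >= cycle_range[2L]) {
    stop("`cycle_range` must be an increasing positive pair", call. = FALSE)
  }
  if (cycle_mean < cycle_range[1L] || cycle_mean > cycle_range[2L]) {
    stop("`cycle_mean` must lie within `cycle_range`", call. = FALSE)
  }
  if (cycle_sd < 0) stop("`cycle_sd` must be >= 0", call. = FALSE)
  if (oct4_init_median <= 0) stop("`oct4_init_median` must be positive", call. = FALSE)
  if (oct4_init_cv < 0) stop("`oct4_init_cv` must be >= 0", call. = FALSE)
  structure(list(cycle_mean = cycle_mean, cycle_sd = cycle_sd,
                 cycle_range = as.numeric(cycle_range),
                 oct4_init_median = oct4_init_median,
                 oct4_init_cv = oct4_init_cv, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Cell-cycle duration sampler (truncated Gamma)
#'
#' A Gamma distribution truncated to \code{cycle_range} whose
#' post-truncation mean and standard deviation are moment-matched
#' numerically (at construction) to \code{cycle_mean} and \code{cycle_sd}.
#' Draws use inverse-CDF sampling restricted to the support, so no mass
#' ever falls outside the range. A zero \code{cycle_sd} degenerates to a
#' constant sampler at \code{cycle_mean}.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @return An \code{oct4_sampler} over hours.
#' @export
make_cycle_sampler <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  lo <- cfg$cycle_range[1L]; hi <- cfg$cycle_range[2L]
  if (cfg$cycle_sd == 0) {
    return(new_sampler("constant", cfg$cycle_range,
                       function(n) rep(cfg$cycle_mean, n),
                       parameters = list(value = cfg$cycle_mean),
                       seed = cfg$seed))
  }
  par <- match_truncated_gamma(cfg$cycle_mean, cfg$cycle_sd, lo, hi)
  shape <- par[["shape"]]; rate <- par[["rate"]]
  p_lo <- stats::pgamma(lo, shape, rate)
  p_hi <- stats::pgamma(hi, shape, rate)
  draw_fun <- function(n) {
    u <- stats::runif(n, p_lo, p_hi)
    stats::qgamma(u, shape, rate)
  }
  new_sampler("gamma_trunc", cfg$cycle_range, draw_fun,
              parameters = list(shape = shape, rate = rate), seed = cfg$seed)
}

# Moments of a Gamma(shape, rate) truncated to (lo, hi), in closed form.
truncated_gamma_moments <- function(shape, rate, lo, hi) {
  z <- stats::pgamma(hi, shape, rate) - stats::pgamma(lo, shape, rate)
  if (z <= 0) return(c(mean = NaN, sd = NaN))
  mk <- function(k) {
    exp(lgamma(shape + k) - lgamma(shape) - k * log(rate)) *
      (stats::pgamma(hi, shape + k, rate) - stats::pgamma(lo, shape + k, rate)) / z
  }
  m1 <- mk(1); m2 <- mk(2)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

match_truncated_gamma <- function(target_mean, target_sd, lo, hi,
                                  tol = 1e-4) {
  # start from the untruncated moment-matched Gamma
  start <- c(log(target_mean^2 / target_sd^2), log(target_mean / target_sd^2))
  obj <- function(p) {
    m <- truncated_gamma_moments(exp(p[1L]), exp(p[2L]), lo, hi)
    if (any(!is.finite(m))) return(1e6)
    (m[["mean"]] - target_mean)^2 / target_mean^2 +
      (m[["sd"]] - target_sd)^2 / max(target_sd, 1e-8)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  shape <- exp(fit$par[1L]); rate <- exp(fit$par[2L])
  m <- truncated_gamma_moments(shape, rate, lo, hi)
  if (abs(m[["mean"]] - target_mean) > 0.02 * target_mean ||
      abs(m[["sd"]] - target_sd) > 0.02 * target_sd) {
    stop("could not match the requested cycle-time moments on the given ",
         "support (best mean ", format(m[["mean"]]), ", sd ",
         format(m[["sd"]]), ")", call. = FALSE)
  }
  c(shape = shape, rate = rate)
}

#' Initial OCT4 sampler (lognormal)
#'
#' Lognormal with median \code{oct4_init_median} and coefficient of
#' variation \code{oct4_init_cv}; support is the positive half-line, so all
#' draws are positive. A zero CV degenerates to a constant sampler at the
#' median.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @return An \code{oct4_sampler} over a.f.u.
#' @export
make_initial_oct4_sampler <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  meanlog <- log(cfg$oct4_init_median)
  if (cfg$oct4_init_cv == 0) {
    return(new_sampler("constant", c(0, Inf),
                       function(n) rep(cfg$oct4_init_median, n),
                       parameters = list(value = cfg$oct4_init_median),
                       seed = cfg$seed))
  }
  sdlog <- sqrt(log(1 + cfg$oct4_init_cv^2))
  new_sampler("lognormal", c(0, Inf),
              function(n) stats::rlnorm(n, meanlog, sdlog),
              parameters = list(meanlog = meanlog, sdlog = sdlog),
              seed = cfg$seed)
}

#' Build a kernel-density sampler from a plain-text column
#'
#' Reads a file of one number per line (blank lines ignored) and delegates
#' to \code{\link{kde_sampler}}. This is the bridge from users' own
#' empirical distributions (initial OCT4, cycle durations) into the colony
#' model.
#'
#' @param path Path to the text file.
#' @param support \code{c(low, high)} truncation interval; defaults to the
#'   data range.
#' @param seed Optional integer recorded on the sampler.
#' @return An \code{oct4_sampler}.
#' @export
load_empirical <- function(path, support = NULL, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no values found in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[is.na(vals)]
    stop("unparseable value(s) in ", path, " at line(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (is.null(support)) support <- range(vals)
  kde_sampler(vals, support = support, seed = seed)
}
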