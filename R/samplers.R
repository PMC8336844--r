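# Samplers supply the colony's probabilistic inputs: initial OCT4 values and
# cell-cycle durations. Two families exist: kernel-density samplers built
# from empirical columns, and parametric stand-ins (see fixtures.R). All
# draws respect a hard support interval and are deterministic given the
# caller's RNG state.

new_sampler <- function(kind, support, draw_fun, parameters = list(),
                        bandwidth = NULL, seed = NULL) {
  if (length(support) != 2L || support[1L] >= support[2L]) {
    stop("`support` must be an increasing (low, high) pair", call. = FALSE)
  }
  structure(list(kind = kind, support = as.numeric(support),
                 parameters = parameters, bandwidth = bandwidth,
                 seed = seed, draw_fun = draw_fun),
            class = "oct4_sampler")
}

#' Kernel-density sampler over an empirical column of values
#'
#' Draws by resampling a datum and adding Gaussian kernel noise with
#' Silverman's rule-of-thumb bandwidth, rejection-resampled into the support
#' interval, i.e. draws from the (truncated) kernel density estimate of the
#' input. This is the mechanism by which initial OCT4 values and cell-cycle
#' durations are drawn "probabilistically from the kernel density fit" to an
#' experimental distribution.
#'
#' @param values Numeric vector of at least 5 observations, all within
#'   \code{support}.
#' @param support \code{c(low, high)} truncation interval in natural units.
#' @param seed Optional integer recorded on the sampler; draws themselves
#'   use the caller's RNG state (seed it with \code{set.seed} for
#'   reproducibility).
#' @return An \code{oct4_sampler}.
#' @export
kde_sampler <- function(values, support = range(values), seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  if (length(support) != 2L || support[1L] >= support[2L]) {
    stop("`support` must be an increasing (low, high) pair", call. = FALSE)
  }
  if (any(values < support[1L] | values > support[2L])) {
    stop("all `values` must lie within `support`", call. = FALSE)
  }
  bw <- silverman_bw(values)
  draw_fun <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      m <- max(n - length(out), 16L)
      x <- sample(values, m, replace = TRUE) + stats::rnorm(m, 0, bw)
      out <- c(out, x[x >= support[1L] & x <= support[2L]])
    }
    out[seq_len(n)]
  }
  new_sampler("kde", support, draw_fun,
              parameters = list(values = values), bandwidth = bw, seed = seed)
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (s > 0 && iqr > 0) min(s, iqr) else max(s, iqr)
  if (spread == 0) return(.Machine$double.eps)  # degenerate column
  0.9 * spread * n^(-1 / 5)
}

#' Draw from a sampler
#'
#' @param sampler An \code{oct4_sampler}.
#' @param n Number of draws.
#' @return Numeric vector of \code{n} values, all within the sampler's
#'   support.
#' @export
sampler_draw <- function(sampler, n) {
  stopifnot(inherits(sampler, "oct4_sampler"))
  sampler$draw_fun(n)
}

#' @export
print.oct4_sampler <- function(x, ...) {
  cat(sprintf("<oct4_sampler> kind = %s, support = [%g, %g]\n",
              x$kind, x$support[1L], x$support[2L]))
  invisible(x)
}
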