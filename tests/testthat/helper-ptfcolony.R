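# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# A small colony with narrow, fast distributions so tests stay quick.
quick_fixtures <- function(seed = 1L, cycle_mean = 10.3, cycle_sd = 4) {
  fixture_config(cycle_mean = cycle_mean, cycle_sd = cycle_sd, seed = seed)
}

quick_init <- function(n_p = 14L, n_d = 2L, seed = 1L,
                       phase_mode = "asynchronous",
                       cfg = quick_fixtures(seed)) {
  init_colony(n_p, n_d,
              oct4_sampler = make_initial_oct4_sampler(cfg),
              cycle_sampler = make_cycle_sampler(cfg),
              phase_mode = phase_mode, seed = seed)
}

# Constant-duration cycle sampler (degenerate fixture) for grid arithmetic.
constant_cycle_init <- function(n_cells = 1L, duration_h = 23,
                                phase_mode = "synchronised", seed = 1L,
                                oct4_value = 1290) {
  cfg <- fixture_config(cycle_mean = duration_h, cycle_sd = 0,
                        cycle_range = c(0.25, 30),
                        oct4_init_median = oct4_value, oct4_init_cv = 0,
                        seed = seed)
  init_colony(n_cells, 0L,
              oct4_sampler = make_initial_oct4_sampler(cfg),
              cycle_sampler = make_cycle_sampler(cfg),
              phase_mode = phase_mode, seed = seed)
}

# Bartlett standard error of the lag-k sample autocovariance of a Gaussian
# stationary series with theoretical autocovariance gamma(). Independent of
# the generator under test.
acov_se <- function(n, hurst, k, L = 200L) {
  j <- (-L):L
  g <- function(l) fgn_autocovariance(abs(l), hurst)
  sqrt(sum(g(j)^2 + g(j + k) * g(j - k)) / n)
}

sample_acov <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
}
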