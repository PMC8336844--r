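# Summary statistics and feature diagnostics for simulated (or empirical)
# colony trajectories: increment noise scale, carrying-capacity estimate,
# time-binned expression distributions with skewness, two-sample KS
# comparisons, central tracks (mean/median/KDE-mode) and per-cell Hurst
# ensembles.

#' Standard deviation of one-frame OCT4 increments
#'
#' Pools within-cell differences \code{OCT4(t) - OCT4(t-1)} over all cells
#' with at least two frames before \code{t_max} and returns their standard
#' deviation — the statistic used to set the noise scale (about 90 a.f.u.
#' in the experimental colony). Mother-to-daughter joins are excluded: they
#' are continuity points with zero difference by construction and would
#' bias the estimate downward.
#'
#' @param traj A \code{colony_trajectory}.
#' @param t_max Only increments ending at or before this time (hours) are
#'   pooled (default: all).
#' @return The pooled increment SD in a.f.u.
#' @export
increment_sd <- function(traj, t_max = Inf) {
  stopifnot(inherits(traj, "colony_trajectory"))
  incs <- unlist(lapply(traj$cells, function(cell) {
    keep <- cell$t <= t_max + 1e-9
    v <- cell$oct4[keep]
    if (length(v) < 2L) return(numeric(0))
    diff(v)
  }))
  if (length(incs) < 2L) stop("no within-cell increments before t_max", call. = FALSE)
  stats::sd(incs)
}

#' Estimate the carrying capacity from a trajectory
#'
#' The median of all OCT4 values inside a time window — the estimator that
#' anchors K (1290 a.f.u. over the whole pre-differentiation record; 1500 /
#' 1100 per fate over 0-25 h for the time-dependent variant).
#'
#' @param traj A \code{colony_trajectory}.
#' @param window \code{c(t0, t1)} in hours.
#' @param by_fate If \code{TRUE}, return a named vector of per-fate medians.
#' @return Median OCT4 in a.f.u. (scalar, or named vector with
#'   \code{by_fate}).
#' @export
estimate_K <- function(traj, window = c(0, Inf), by_fate = FALSE) {
  stopifnot(inherits(traj, "colony_trajectory"))
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("`window` must be an increasing (t0, t1) pair", call. = FALSE)
  }
  df <- as.data.frame(traj)
  df <- df[df$t_hours >= window[1L] - 1e-9 & df$t_hours <= window[2L] + 1e-9, ]
  if (nrow(df) == 0L) stop("no values in the window", call. = FALSE)
  if (by_fate) {
    vapply(split(df$oct4_afu, df$fate), stats::median, numeric(1))
  } else {
    stats::median(df$oct4_afu)
  }
}

sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

#' Time-binned OCT4 distributions
#'
#' For each fate and time bin: the normalised histogram of all OCT4 values
#' observed in the bin, the number N of distinct cells contributing, and the
#' sample skewness. Histogram bin edges are shared across all time bins of a
#' fate so distributions are directly comparable.
#'
#' @param traj A \code{colony_trajectory}.
#' @param bin_edges Increasing time-bin edges in hours (default: the 0-43 h
#'   pre-differentiation window in four bins).
#' @param n_histogram_bins Number of OCT4 histogram bins (default 30).
#' @return A list with \code{histograms} (tidy data frame: \code{fate},
#'   \code{bin_start_h}, \code{bin_end_h}, \code{oct4_bin_mid},
#'   \code{density}, \code{N}) and \code{skewness} (data frame per fate and
#'   bin).
#' @export
binned_distributions <- function(traj, bin_edges = seq(0, 43, length.out = 5),
                                 n_histogram_bins = 30L) {
  stopifnot(inherits(traj, "colony_trajectory"))
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  df <- as.data.frame(traj)
  df <- df[df$t_hours >= bin_edges[1L] - 1e-9 &
             df$t_hours <= bin_edges[length(bin_edges)] + 1e-9, ]
  hist_rows <- list(); skew_rows <- list()
  for (fate in sort(unique(df$fate))) {
    dff <- df[df$fate == fate, ]
    if (nrow(dff) == 0L) next
    brk <- seq(min(dff$oct4_afu), max(dff$oct4_afu),
               length.out = n_histogram_bins + 1L)
    if (brk[1L] == brk[length(brk)]) brk <- brk[1L] + c(-0.5, 0.5)
    mids <- (utils::head(brk, -1L) + utils::tail(brk, -1L)) / 2
    for (b in seq_len(length(bin_edges) - 1L)) {
      lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
      sel <- dff$t_hours >= lo - 1e-9 &
        (if (b == length(bin_edges) - 1L) dff$t_hours <= hi + 1e-9
         else dff$t_hours < hi - 1e-9)
      vals <- dff$oct4_afu[sel]
      if (length(vals) == 0L) next
      h <- graphics::hist(vals, breaks = brk, plot = FALSE)
      n_cells <- length(unique(dff$cell_id[sel]))
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        fate = fate, bin_start_h = lo, bin_end_h = hi,
        oct4_bin_mid = mids, density = h$density, N = n_cells)
      skew_rows[[length(skew_rows) + 1L]] <- data.frame(
        fate = fate, bin_start_h = lo, bin_end_h = hi,
        skewness = sample_skewness(vals), N = n_cells)
    }
  }
  list(histograms = do.call(rbind, hist_rows),
       skewness = do.call(rbind, skew_rows))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The standard two-sample KS statistic \eqn{\sup_x |F_a(x) - F_b(x)|} with
#' the asymptotic p-value, rejecting equality of distributions at the 95\%
#' level — the test used to confirm that time-binned OCT4 distributions
#' shift over the experiment.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with \code{statistic}, \code{p_value} and \code{reject}
#'   (logical, \code{p < 0.05}).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       reject = unname(kt$p.value) < 0.05)
}

#' KDE mode of a sample
#'
#' Location of the maximum of a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth. Used for mode tracks: a KDE argmax
#' is deterministic given the bandwidth rule, whereas a histogram argmax is
#' a bin-width artefact.
#'
#' @param x Numeric sample.
#' @return The mode location.
#' @export
kde_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L || stats::sd(x) == 0) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Per-fate central tracks of OCT4 over time
#'
#' For each fate and frame, the chosen statistic over all cells of that fate
#' alive at that frame. Frames with no live cells of a fate are omitted (not
#' reported as zero).
#'
#' @param traj A \code{colony_trajectory}.
#' @param statistic \code{"mean"}, \code{"median"} or \code{"mode"} (KDE
#'   argmax, see \code{\link{kde_mode}}).
#' @return Data frame with columns \code{fate}, \code{t_hours},
#'   \code{value}, \code{n_cells}.
#' @export
central_tracks <- function(traj, statistic = c("mean", "median", "mode")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(traj, "colony_trajectory"))
  fun <- switch(statistic, mean = mean, median = stats::median, mode = kde_mode)
  df <- as.data.frame(traj)
  frame <- round(df$t_hours * FRAMES_PER_HOUR)
  out <- list()
  for (fate in sort(unique(df$fate))) {
    sel <- df$fate == fate
    sp <- split(df$oct4_afu[sel], frame[sel])
    out[[length(out) + 1L]] <- data.frame(
      fate = fate,
      t_hours = as.numeric(names(sp)) / FRAMES_PER_HOUR,
      value = vapply(sp, fun, numeric(1)),
      n_cells = vapply(sp, length, integer(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$fate, res$t_hours), ]
}

#' Ensemble Hurst statistics over a colony
#'
#' Applies \code{\link{estimate_hurst}} to every cell whose series exceeds
#' 50 frames and reports the ensemble mean and SD; shorter cells are counted
#' and skipped.
#'
#' @param traj A \code{colony_trajectory}.
#' @param method Estimator passed to \code{\link{estimate_hurst}}.
#' @return List with \code{mean}, \code{sd}, \code{n_cells} (eligible) and
#'   \code{n_skipped}.
#' @export
hurst_ensemble <- function(traj, method = c("DFA", "RS")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "colony_trajectory"))
  lens <- vapply(traj$cells, function(c) length(c$oct4), integer(1))
  eligible <- which(lens > 51L)  # > 50 increments
  if (length(eligible) == 0L) {
    stop("no cell has more than 50 time frames; the Hurst ensemble is empty",
         call. = FALSE)
  }
  ests <- vapply(traj$cells[eligible], function(cell) {
    estimate_hurst(diff(cell$oct4), method = method)$value
  }, numeric(1))
  list(mean = mean(ests), sd = stats::sd(ests),
       n_cells = length(eligible), n_skipped = length(lens) - length(eligible))
}

#' Fractions of terminal cells per fate
#'
#' @param traj A \code{colony_trajectory} (after fate classification for
#'   Allee runs).
#' @return Named numeric vector of proportions over terminal cells, summing
#'   to 1.
#' @export
fate_fractions <- function(traj) {
  stopifnot(inherits(traj, "colony_trajectory"))
  term <- terminal_ids(traj)
  ids <- vapply(traj$cells, `[[`, 0L, "cell_id")
  fates <- vapply(traj$cells, `[[`, "", "fate")[match(term, ids)]
  tab <- table(fates)
  as.numeric(tab) / sum(tab) -> p
  stats::setNames(p, names(tab))
}

#' Full summary bundle for a trajectory
#'
#' Computes in one pass the statistics used to characterise the colony:
#' ensemble Hurst mean and SD, the pooled increment SD (noise scale), the
#' in-window median (carrying-capacity estimate), time-binned histograms
#' with skewness, KS tests between consecutive time bins per fate, central
#' tracks (mean, median, mode) and terminal fate fractions.
#'
#' @param traj A \code{colony_trajectory}.
#' @param bin_edges Time-bin edges in hours for the binned distributions.
#' @param n_histogram_bins Number of OCT4 histogram bins.
#' @param k_window Window (hours) for the carrying-capacity estimate.
#' @param hurst_method Estimator for the Hurst ensemble.
#' @return A \code{summary_bundle} list.
#' @export
summarise_colony <- function(traj, bin_edges = seq(0, 43, length.out = 5),
                             n_histogram_bins = 30L, k_window = c(0, 43),
                             hurst_method = "DFA") {
  stopifnot(inherits(traj, "colony_trajectory"))
  binned <- binned_distributions(traj, bin_edges, n_histogram_bins)
  hur <- tryCatch(hurst_ensemble(traj, hurst_method),
                  error = function(e) list(mean = NA_real_, sd = NA_real_,
                                           n_cells = 0L, n_skipped = NA_integer_))
  df <- as.data.frame(traj)
  k_window[2L] <- min(k_window[2L], max(df$t_hours))

  ks_rows <- list()
  for (fate in sort(unique(df$fate))) {
    dff <- df[df$fate == fate, ]
    for (b in seq_len(length(bin_edges) - 2L)) {
      a_sel <- dff$t_hours >= bin_edges[b] & dff$t_hours < bin_edges[b + 1L]
      b_sel <- dff$t_hours >= bin_edges[b + 1L] & dff$t_hours < bin_edges[b + 2L]
      if (!any(a_sel) || !any(b_sel)) next
      ks <- ks_two_sample(dff$oct4_afu[a_sel], dff$oct4_afu[b_sel])
      ks_rows[[length(ks_rows) + 1L]] <- data.frame(
        fate = fate, bin_a_start_h = bin_edges[b],
        bin_b_start_h = bin_edges[b + 1L],
        statistic = ks$statistic, p_value = ks$p_value, reject = ks$reject)
    }
  }

  structure(list(
    hurst_mean_sd = c(mean = hur$mean, sd = hur$sd),
    hurst_n_cells = hur$n_cells,
    hurst_n_skipped = hur$n_skipped,
    sigma_hat = increment_sd(traj),
    K_hat = estimate_K(traj, k_window),
    binned_histograms = binned$histograms,
    skewness_by_bin = binned$skewness,
    ks_results = if (length(ks_rows) > 0L) do.call(rbind, ks_rows) else NULL,
    central_tracks = do.call(rbind, lapply(c("mean", "median", "mode"),
      function(s) cbind(statistic = s, central_tracks(traj, s)))),
    fate_fractions = fate_fractions(traj)
  ), class = "summary_bundle")
}

#' @export
print.summary_bundle <- function(x, ...) {
  cat("<summary_bundle>\n")
  cat(sprintf("  Hurst ensemble: %.3f +/- %.3f over %d cells\n",
              x$hurst_mean_sd[["mean"]], x$hurst_mean_sd[["sd"]], x$hurst_n_cells))
  cat(sprintf("  increment SD (sigma_hat): %.2f a.f.u.\n", x$sigma_hat))
  cat(sprintf("  median OCT4 (K_hat): %.1f a.f.u.\n", x$K_hat))
  cat("  fate fractions:",
      paste(sprintf("%s %.3f", names(x$fate_fractions), x$fate_fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a summary bundle to disk
#'
#' The scalar summaries go to \code{summary.json}; histograms and central
#' tracks additionally to tidy CSVs (\code{histograms.csv},
#' \code{central_tracks.csv}, \code{skewness.csv}, \code{ks_results.csv}).
#'
#' @param bundle A \code{summary_bundle}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_summary_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "summary_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(
    hurst_mean = bundle$hurst_mean_sd[["mean"]],
    hurst_sd = bundle$hurst_mean_sd[["sd"]],
    hurst_n_cells = bundle$hurst_n_cells,
    sigma_hat = bundle$sigma_hat,
    K_hat = bundle$K_hat,
    fate_fractions = as.list(bundle$fate_fractions)
  )
  jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$binned_histograms, file.path(dir, "histograms.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$skewness_by_bin, file.path(dir, "skewness.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$ks_results)) {
    utils::write.csv(bundle$ks_results, file.path(dir, "ks_results.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$central_tracks, file.path(dir, "central_tracks.csv"),
                   row.names = FALSE)
  invisible(dir)
}
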