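#' Box-plot statistics of a loss sample
#'
#' Median and quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7); whiskers extend to the most extreme data
#' points within 1.5 IQR of the quartiles.
#'
#' @param values Numeric vector, length >= 1.
#' @return List `(median, q1, q3, whisker_lo, whisker_hi, mean, n)`.
#' @export
boxplot_stats <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[values >= lo_lim]),
       whisker_hi = max(values[values <= hi_lim]),
       mean = mean(values), n = length(values))
}

#' Density histogram of losses with Gaussian overlay parameters
#'
#' @param values Numeric vector, length >= 2 with non-degenerate range.
#' @param n_bins Number of equal-width bins.
#' @return List `(breaks, counts, density, mids, gaussian = (mean, sd))`;
#'   the density integrates to 1 over the binned range.
#' @export
loss_histogram <- function(values, n_bins = 20L) {
  if (length(values) < 2) stop("need at least two values")
  rng <- range(values)
  if (rng[1] == rng[2]) stop("degenerate range")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, density = h$density,
       mids = h$mids,
       gaussian = list(mean = mean(values), sd = stats::sd(values)))
}

#' Default respiration-rate bins (peaks per 30 s)
#' @return List of `c(lo, hi)` inclusive ranges.
#' @export
default_rr_bins <- function() {
  list(c(1, 4), c(5, 6), c(7, 9), c(10, 11), c(12, 14))
}

#' Loss statistics binned by respiration rate
#'
#' Assigns each session to a peak-count bin (an extra overflow bin collects
#' counts outside all ranges) and summarizes the losses per bin with
#' [boxplot_stats()].
#'
#' @param peak_counts Integer vector: detected breathing peaks per session.
#' @param losses Numeric vector of the same length.
#' @param edges List of `c(lo, hi)` inclusive ranges (default
#'   [default_rr_bins()]).
#' @return A `rr_bin_report`: list with `bins` (labels), `n` (per-bin
#'   counts), `stats` (per-bin [boxplot_stats()] or `NULL` when empty).
#' @export
rr_binned_losses <- function(peak_counts, losses, edges = default_rr_bins()) {
  if (!length(peak_counts)) stop("empty input")
  if (length(peak_counts) != length(losses)) stop("length mismatch")
  labels <- c(vapply(edges, function(e) paste0(e[1], "-", e[2]),
                     character(1)), "other")
  assign_bin <- function(pc) {
    for (i in seq_along(edges)) {
      if (pc >= edges[[i]][1] && pc <= edges[[i]][2]) return(i)
    }
    length(edges) + 1L
  }
  bin_idx <- vapply(peak_counts, assign_bin, integer(1))
  n <- tabulate(bin_idx, nbins = length(labels))
  stats_list <- lapply(seq_along(labels), function(i) {
    if (n[i] == 0) NULL else boxplot_stats(losses[bin_idx == i])
  })
  names(stats_list) <- labels
  names(n) <- labels
  structure(list(bins = labels, n = n, stats = stats_list),
            class = "rr_bin_report")
}

#' Read a YAML run configuration
#'
#' Supported sections: `radar` (keys named after the waveform symbols:
#' `ntx`, `nrx`, `nc`, `ns`, `f0`, `fs`, `fps`, `tc`, `bw`, optional `c`),
#' and free-form `scene`, `preprocess`, `filter`, `metrics`, `model`,
#' `meta` sections returned as lists.
#'
#' @param path Path to the YAML file.
#' @return List with `radar` (a [radar_config()]) and the remaining sections.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$radar)) {
    r <- raw$radar
    pick <- function(key, default) {
      if (is.null(r[[key]])) default else as.numeric(r[[key]])
    }
    out$radar <- radar_config(
      n_tx = pick("ntx", 1L), n_rx = pick("nrx", 3L),
      n_chirps = pick("nc", 2L), n_samples = pick("ns", 200L),
      f0 = pick("f0", 60e9), fs_adc = pick("fs", 2e6),
      frame_rate = pick("fps", 20), t_chirp = pick("tc", 150e-6),
      bandwidth = pick("bw", 4e9), c_light = pick("c", 3e8))
  }
  out
}
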