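#' Detect breathing peaks
#'
#' Local maxima with a minimum mutual separation of one second (half the
#' period of the fastest in-band breath, 0.5 Hz) and a prominence of at least
#' 10% of the signal range. When two admissible peaks conflict, the higher one
#' wins; equal-height plateaus keep the lowest index.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param min_separation_s Minimum peak separation in seconds.
#' @param min_prominence_frac Prominence threshold as a fraction of
#'   `diff(range(signal))`.
#' @return Integer vector of peak indices (possibly empty).
#' @export
detect_peaks <- function(signal, fs, min_separation_s = 1,
                         min_prominence_frac = 0.1) {
  if (any(!is.finite(signal))) stop("non-finite signal")
  n <- length(signal)
  if (n < 3) return(integer(0))
  rng <- diff(range(signal))
  if (rng == 0) return(integer(0))

  left <- signal[2:(n - 1)] > signal[1:(n - 2)]
  right <- signal[2:(n - 1)] >= signal[3:n]
  cand <- which(left & right) + 1L
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, function(i) {
    h <- signal[i]
    lo_l <- h
    for (j in seq(i - 1L, 1L)) {
      if (signal[j] > h) break
      if (signal[j] < lo_l) lo_l <- signal[j]
    }
    lo_r <- h
    if (i < n) {
      for (j in seq(i + 1L, n)) {
        if (signal[j] > h) break
        if (signal[j] < lo_r) lo_r <- signal[j]
      }
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(integer(0))

  min_sep <- min_separation_s * fs
  ord <- cand[order(-signal[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Sliding-window length from detected peaks
#'
#' Twice the average distance between consecutive peaks - about two whole
#' breathing cycles. With fewer than two peaks the window falls back to two
#' cycles at the band-center frequency (0.3 Hz), with a warning.
#'
#' @param peaks Peak indices.
#' @param fs Sampling rate, Hz (needed only for the fallback).
#' @return Window length in samples.
#' @export
sliding_window <- function(peaks, fs = 20) {
  if (length(peaks) >= 2) {
    as.integer(floor(2 * mean(diff(peaks)) + 0.5))
  } else {
    warning("fewer than two peaks detected; falling back to a two-cycle ",
            "window at the 0.3 Hz band center")
    as.integer(floor(2 * fs / 0.3 + 0.5))
  }
}

#' Instantaneous breaths-per-minute series
#'
#' For each window start `t`, the number of peaks inside `[t, t + W)` rescaled
#' to breaths per minute: `bpm[t] = count * 60 * fs / W`.
#'
#' @param signal Numeric vector (used only for its length).
#' @param peaks Peak indices.
#' @param W Window length in samples.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of length `length(signal) - W + 1`.
#' @export
instantaneous_bpm <- function(signal, peaks, W, fs) {
  n <- length(signal)
  if (W > n) stop("window too long: W = ", W, " exceeds signal length ", n)
  ind <- integer(n)
  ind[peaks] <- 1L
  cs <- c(0L, cumsum(ind))
  starts <- seq_len(n - W + 1L)
  counts <- cs[starts + W] - cs[starts]
  counts * 60 * fs / W
}

#' Motion-corruption flags from windowed autocorrelation
#'
#' The signal is scanned with a window of `round(0.75 * W)` samples (about one
#' and a half breathing cycles). In each window the mean is removed and the
#' raw (unnormalized) autocorrelation is computed over lags
#' `1 ... W_ac - 1`; the window is flagged corrupted (1) when the maximum
#' autocorrelation falls below `threshold_coef * W`. The absolute threshold
#' presumes the session was normalized to [0, 1] upstream. Flags are assigned
#' to window starts.
#'
#' @param signal Band-passed signal derived from a unit-range session.
#' @param W The bpm sliding-window length in samples (see [sliding_window()]).
#' @param threshold_coef Threshold multiplier (default 0.001).
#' @return Integer 0/1 vector of length `length(signal) - W_ac + 1`.
#' @export
corruption_flags <- function(signal, W, threshold_coef = 0.001) {
  w_ac <- as.integer(floor(0.75 * W + 0.5))
  if (w_ac < 4) stop("degenerate window: round(0.75 * W) = ", w_ac, " < 4")
  n <- length(signal)
  if (w_ac > n) stop("window too long for signal")
  nwin <- n - w_ac + 1L
  idx <- outer(seq_len(w_ac), 0:(nwin - 1L), "+")
  wm <- matrix(signal[idx], nrow = w_ac)
  wm <- sweep(wm, 2, colMeans(wm))
  acmax <- rep(-Inf, nwin)
  for (lag in seq_len(w_ac - 1L)) {
    ac <- colSums(wm[seq_len(w_ac - lag), , drop = FALSE] *
                    wm[(1L + lag):w_ac, , drop = FALSE])
    acmax <- pmax(acmax, ac)
  }
  as.integer(acmax < threshold_coef * W)
}

#' Corruption fraction and its complement
#'
#' `gamma` is the mean corruption flag over the session; `tau = 1 - gamma`
#' weights the reconstruction term of the training loss, so heavily corrupted
#' sessions shift weight from signal reconstruction to central-frequency
#' regression.
#'
#' @param flags Binary flag vector.
#' @return Named list `list(tau = , gamma = )`.
#' @export
corruption_summary <- function(flags) {
  if (length(flags) && !all(flags %in% c(0, 1))) stop("flags must be binary")
  gamma <- if (length(flags)) mean(flags) else 0
  list(tau = 1 - gamma, gamma = gamma)
}

#' All breath metrics of one signal
#'
#' Convenience wrapper: band-pass filter at `fc` (if given), detect peaks,
#' derive the sliding window, the instantaneous bpm series, and the
#' corruption flags, and summarize the corruption fraction.
#'
#' @param signal Respiration signal (e.g. the normalized radar phase `x` or
#'   the belt trace).
#' @param fs Sampling rate, Hz.
#' @param fc Center frequency for the band-pass; `NULL` skips filtering.
#' @param filter_fs Sampling frequency assumed by the biquad design.
#' @param threshold_coef Passed to [corruption_flags()].
#' @param transient_pad If `TRUE` (default), the signal is extended at the
#'   front with its time-reversed mirror before filtering and the pad is
#'   dropped afterwards, so the zero-state filter transient does not leak
#'   into the session start (which would otherwise be mistaken for
#'   corruption).
#' @return An object of class `breath_metrics`: `filtered`, `peaks`,
#'   `window_bpm` (W), `window_ac`, `bpm`, `flags`, `corruption_fraction`
#'   (gamma), `tau`.
#' @export
breath_metrics <- function(signal, fs, fc = NULL, filter_fs = 20,
                           threshold_coef = 0.001, transient_pad = TRUE) {
  if (inherits(signal, "phase_trace")) signal <- signal$x
  filtered <- if (!is.null(fc)) {
    if (transient_pad) {
      n <- length(signal)
      padded <- c(rev(signal), signal)
      apply_cascade(padded, fc, q = 2, fs = filter_fs, stages = 2L)[n + seq_len(n)]
    } else {
      apply_cascade(signal, fc, q = 2, fs = filter_fs, stages = 2L)
    }
  } else signal
  peaks <- detect_peaks(filtered, fs)
  W <- sliding_window(peaks, fs)
  W <- min(W, length(filtered))
  bpm <- instantaneous_bpm(filtered, peaks, W, fs)
  flags <- corruption_flags(filtered, W, threshold_coef)
  cs <- corruption_summary(flags)
  structure(list(filtered = filtered, peaks = peaks, window_bpm = W,
                 window_ac = as.integer(floor(0.75 * W + 0.5)), bpm = bpm,
                 flags = flags, corruption_fraction = cs$gamma, tau = cs$tau),
            class = "breath_metrics")
}

#' @export
print.breath_metrics <- function(x, ...) {
  cat(sprintf(
    "<breath_metrics> %d peaks, W = %d, mean bpm = %.2f, corruption = %.3f\n",
    length(x$peaks), x$window_bpm, mean(x$bpm), x$corruption_fraction))
  invisible(x)
}
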