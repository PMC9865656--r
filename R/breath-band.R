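#' Design a peak-normalized band-pass biquad
#'
#' Second-order recursive (IIR) band-pass with two poles and two zeros,
#' constant 0 dB peak gain at the center frequency. With
#' `w0 = 2 * pi * fc / fs` and `aq = sin(w0) / (2 * q)` the feed-forward
#' weights are `(aq, 0, -aq) / (1 + aq)` and the feedback weights
#' `(-2 * cos(w0), 1 - aq) / (1 + aq)`, giving `|H| = 1` at `fc` and zeros at
#' DC and Nyquist. The respiration filter uses `q = 2` at `fs = 20` Hz.
#'
#' @param fc Center frequency, Hz.
#' @param q Quality factor (bandwidth = `fc / q`).
#' @param fs Sampling frequency, Hz.
#' @return An object of class `biquad_coeffs` with fields `a0`, `a1`, `a2`
#'   (feed-forward), `b1`, `b2` (feedback), `fc`, `q`, `fs`.
#' @examples
#' bq <- design_biquad(0.33, q = 2, fs = 20)
#' Mod(biquad_response(bq, 0.33))   # 1
#' @export
design_biquad <- function(fc, q = 2, fs = 20) {
  if (fc <= 0 || fc >= fs / 2) {
    stop("Nyquist violation: fc must satisfy 0 < fc < fs/2 (fc = ", fc,
         ", fs = ", fs, ")")
  }
  if (q <= 0) stop("q must be > 0")
  w0 <- 2 * pi * fc / fs
  aq <- sin(w0) / (2 * q)
  norm <- 1 + aq
  structure(list(a0 = aq / norm, a1 = 0, a2 = -aq / norm,
                 b1 = -2 * cos(w0) / norm, b2 = (1 - aq) / norm,
                 fc = fc, q = q, fs = fs),
            class = "biquad_coeffs")
}

#' Frequency response of a biquad
#'
#' @param coef A [design_biquad()] result.
#' @param f Frequencies in Hz.
#' @return Complex response `H(e^{i 2 pi f / fs})`.
#' @export
biquad_response <- function(coef, f) {
  stopifnot(inherits(coef, "biquad_coeffs"))
  z1 <- exp(-1i * 2 * pi * f / coef$fs)
  (coef$a0 + coef$a1 * z1 + coef$a2 * z1^2) /
    (1 + coef$b1 * z1 + coef$b2 * z1^2)
}

#' Poles of a biquad
#'
#' @inheritParams biquad_response
#' @return Complex roots of `z^2 + b1 z + b2`; stable iff both moduli < 1.
#' @export
biquad_poles <- function(coef) {
  stopifnot(inherits(coef, "biquad_coeffs"))
  polyroot(c(coef$b2, coef$b1, 1))
}

#' Apply one biquad stage
#'
#' Direct recurrence
#' `O[n] = a0 I[n] + a1 I[n-1] + a2 I[n-2] - b1 O[n-1] - b2 O[n-2]`
#' with zero initial state; output length equals input length.
#'
#' @param x Input vector.
#' @inheritParams biquad_response
#' @return Filtered vector.
#' @export
apply_biquad <- function(x, coef) {
  stopifnot(inherits(coef, "biquad_coeffs"))
  if (any(!is.finite(x))) stop("non-finite input values")
  as.numeric(signal::filter(c(coef$a0, coef$a1, coef$a2),
                            c(1, coef$b1, coef$b2), x))
}

#' Cascaded biquad respiration band-pass
#'
#' Runs `stages` identical band-pass biquads in series (default two), zero
#' initial state. Two cascaded unity-peak stages keep unity gain at `fc` and
#' double the out-of-band attenuation.
#'
#' @param x Input vector.
#' @param fc Center frequency, Hz.
#' @param q Quality factor.
#' @param fs Sampling frequency, Hz.
#' @param stages Number of cascaded stages.
#' @return Filtered vector, same length as `x`.
#' @export
apply_cascade <- function(x, fc, q = 2, fs = 20, stages = 2L) {
  coef <- design_biquad(fc, q, fs)
  out <- x
  for (s in seq_len(stages)) out <- apply_biquad(out, coef)
  out
}

new_fc_label <- function(fc, method) {
  band <- respiration_band()
  structure(list(fc = fc, method = method,
                 in_band = fc >= band["lo"] && fc <= band["hi"]),
            class = "fc_label")
}

#' @export
print.fc_label <- function(x, ...) {
  cat(sprintf("<fc_label> %.4g Hz (%.3g bpm) via %s\n", x$fc,
              fc_to_bpm(x$fc), x$method))
  invisible(x)
}

#' Reference central frequency from the belt spectrum
#'
#' Power spectrum of the linearly detrended trace (zero-padded by
#' `zero_pad` for grid refinement, no taper); the label is the frequency of
#' the maximum in-band peak, searched in [0.1, 0.5] Hz (6-30 bpm). Linear
#' detrending (rather than plain mean removal) stops slow drift from leaking
#' into the lower band edge, which matters when the same estimator is applied
#' to an extracted radar phase trace. This is the training label for the
#' central respiration frequency.
#'
#' @param belt Force trace (or any respiration signal, e.g. a phase trace).
#' @param fs Sampling rate of the trace, Hz.
#' @param band Search band in Hz.
#' @param zero_pad Zero-padding factor for the FFT grid.
#' @param detrend If `TRUE` (default), remove a least-squares linear trend
#'   before the FFT; `FALSE` removes only the mean.
#' @return An `fc_label` with `method = "belt_spectrum"`.
#' @export
belt_fc_reference <- function(belt, fs, band = respiration_band(),
                              zero_pad = 4L, detrend = TRUE) {
  n <- length(belt)
  if (n < 2 / band[[1]] * fs) {
    stop("belt trace too short: need at least two cycles of the slowest ",
         "in-band frequency (", ceiling(2 / band[[1]] * fs), " samples)")
  }
  v <- belt - mean(belt)
  if (detrend) {
    tt <- seq_len(n) - (n + 1) / 2
    v <- v - sum(v * tt) / sum(tt^2) * tt
  }
  npad <- n * zero_pad
  spec <- Mod(stats::fft(c(v, rep(0, npad - n))))^2
  freqs <- (seq_len(npad) - 1) * fs / npad
  sel <- which(freqs >= band[[1]] & freqs <= band[[2]])
  new_fc_label(freqs[sel[which.max(spec[sel])]], "belt_spectrum")
}

#' Central frequency by maximum radar-belt correlation
#'
#' For each candidate frequency on a grid over the search band, the radar
#' phase trace is band-pass filtered by the double biquad at that frequency
#' and the Pearson correlation with the mean-removed belt trace is computed;
#' the label is the argmax (ties and degenerate all-non-finite cases resolve
#' to the lowest candidate).
#'
#' @param x A `phase_trace` or numeric vector (the unwrapped radar phase).
#' @param belt Belt trace of the same length.
#' @param grid_step Candidate spacing in Hz.
#' @param q,fs,stages Filter parameters passed to [apply_cascade()].
#' @param band Search band in Hz.
#' @return An `fc_label` with `method = "max_correlation"`.
#' @export
correlation_fc_label <- function(x, belt, grid_step = 0.01, q = 2, fs = 20,
                                 stages = 2L, band = respiration_band()) {
  xv <- if (inherits(x, "phase_trace")) x$x else x
  if (length(xv) != length(belt)) stop("x and belt must have equal length")
  if (stats::sd(xv) == 0 || stats::sd(belt) == 0) {
    stop("undefined correlation: zero-variance input")
  }
  grid <- seq(band[[1]], band[[2]], by = grid_step)
  belt0 <- belt - mean(belt)
  cors <- vapply(grid, function(fc) {
    xf <- apply_cascade(xv, fc, q = q, fs = fs, stages = stages)
    if (stats::sd(xf) == 0) return(-Inf)
    stats::cor(xf, belt0)
  }, numeric(1))
  cors[!is.finite(cors)] <- -Inf
  new_fc_label(grid[which.max(cors)], "max_correlation")
}
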