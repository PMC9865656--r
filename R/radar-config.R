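#' FMCW radar configuration
#'
#' Bundles the waveform and acquisition parameters of an FMCW radar front end.
#' The default values reproduce the 60 GHz breath-sensing profile used
#' throughout the package: 1 Tx / 3 Rx, 2 chirps per frame, 200 fast-time
#' samples per chirp, 4 GHz swept bandwidth, 150 us chirps sampled at 2 MHz,
#' and a nominal 20 Hz frame rate.
#'
#' @param n_tx Number of transmit channels.
#' @param n_rx Number of receive channels.
#' @param n_chirps Chirps per frame.
#' @param n_samples Fast-time ADC samples per chirp.
#' @param f0 Center frequency in Hz.
#' @param fs_adc ADC sampling rate in Hz.
#' @param frame_rate Nominal frame rate in Hz.
#' @param t_chirp Chirp duration in seconds.
#' @param bandwidth Swept bandwidth in Hz.
#' @param c_light Propagation speed in m/s; defaults to 3e8.
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' range_resolution(cfg)  # 0.0375 m
#' max_range(cfg)         # 3.75 m
#' @export
radar_config <- function(n_tx = 1L, n_rx = 3L, n_chirps = 2L,
                         n_samples = 200L, f0 = 60e9, fs_adc = 2e6,
                         frame_rate = 20, t_chirp = 150e-6,
                         bandwidth = 4e9, c_light = 3e8) {
  counts <- c(n_tx = n_tx, n_rx = n_rx, n_chirps = n_chirps,
              n_samples = n_samples)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("invalid radar config: all channel/chirp/sample counts must be integers >= 1")
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("invalid radar config: bandwidth must be > 0")
  }
  if (f0 <= 0) stop("invalid radar config: f0 must be > 0")
  if (fs_adc <= 0 || frame_rate <= 0 || t_chirp <= 0 || c_light <= 0) {
    stop("invalid radar config: rates and durations must be > 0")
  }
  if (t_chirp < n_samples / fs_adc) {
    stop("invalid radar config: t_chirp must cover n_samples / fs_adc ",
         "(fast-time sampling must fit within the chirp)")
  }
  structure(
    list(n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
         n_chirps = as.integer(n_chirps), n_samples = as.integer(n_samples),
         f0 = f0, fs_adc = fs_adc, frame_rate = frame_rate,
         t_chirp = t_chirp, bandwidth = bandwidth, c_light = c_light),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  f0: %.3g GHz, Bw: %.3g GHz, tc: %.3g us, Fs: %.3g MHz\n",
              x$f0 / 1e9, x$bandwidth / 1e9, x$t_chirp * 1e6, x$fs_adc / 1e6))
  cat(sprintf("  Tx/Rx: %d/%d, chirps/frame: %d, samples/chirp: %d, frame rate: %g Hz\n",
              x$n_tx, x$n_rx, x$n_chirps, x$n_samples, x$frame_rate))
  cat(sprintf("  range resolution: %.4g m, max range: %.4g m\n",
              range_resolution(x), max_range(x)))
  invisible(x)
}

#' Theoretical range resolution
#'
#' The width of one range cell for a linear FMCW sweep, `c / (2 * Bw)`.
#'
#' @param cfg A [radar_config()].
#' @return Range resolution in metres.
#' @export
range_resolution <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  if (cfg$bandwidth <= 0) stop("invalid radar config: bandwidth must be > 0")
  cfg$c_light / (2 * cfg$bandwidth)
}

#' Theoretical maximum detection range
#'
#' Half the fast-time sample count times the range resolution,
#' `(delta_r / 2) * ns`: the one-sided fast-time FFT spans `ns / 2` cells.
#'
#' @inheritParams range_resolution
#' @return Maximum unambiguous range in metres.
#' @export
max_range <- function(cfg) {
  (range_resolution(cfg) / 2) * cfg$n_samples
}

#' Carrier wavelength
#'
#' `c / f0`; the phase of a range cell advances by `4 * pi / lambda` per metre
#' of round-trip target displacement, which is what makes millimetre chest
#' motion observable far below the range resolution.
#'
#' @inheritParams range_resolution
#' @return Wavelength in metres.
#' @export
wavelength <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  if (cfg$f0 <= 0) stop("invalid radar config: f0 must be > 0")
  cfg$c_light / cfg$f0
}

#' Spacing of the sampled fast-time FFT range grid
#'
#' The ADC samples only `n_samples / fs_adc` seconds of each `t_chirp`-long
#' sweep, so the bandwidth actually covered by the sampled window is
#' `Bw * (ns / Fs) / tc` and one FFT bin spans
#' `c * tc * Fs / (2 * Bw * ns)` metres. With a fully sampled chirp this
#' reduces to [range_resolution()].
#'
#' @inheritParams range_resolution
#' @return Grid spacing in metres of the one-sided fast-time FFT.
#' @export
range_bin_spacing <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  (cfg$c_light * cfg$t_chirp * cfg$fs_adc) / (2 * cfg$bandwidth * cfg$n_samples)
}

#' Beat frequency of a target at a given range
#'
#' `f_b = 2 * Bw * R / (c * tc)` for a linear sweep.
#'
#' @inheritParams range_resolution
#' @param range_m Target range in metres.
#' @return Beat (intermediate) frequency in Hz.
#' @export
beat_frequency <- function(cfg, range_m) {
  stopifnot(inherits(cfg, "radar_config"))
  2 * cfg$bandwidth * range_m / (cfg$c_light * cfg$t_chirp)
}

#' Convert a respiration frequency to breaths per minute
#'
#' @param fc_hz Frequency in Hz.
#' @return Breaths per minute (`fc_hz * 60`).
#' @export
fc_to_bpm <- function(fc_hz) fc_hz * 60

#' Respiration search band
#'
#' The band in which the central respiration frequency is searched:
#' 0.1 to 0.5 Hz, i.e. 6 to 30 breaths per minute.
#'
#' @return Named numeric vector `c(lo = 0.1, hi = 0.5)` in Hz.
#' @export
respiration_band <- function() c(lo = 0.1, hi = 0.5)
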