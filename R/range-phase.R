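#' Resample a session to a fixed frame count
#'
#' Every session is brought to exactly `target_frames` time points (default
#' 660, 10% above the nominal 600 frames of a 30 s recording at 20 Hz).
#' Longer recordings are linearly interpolated onto the grid
#' `1 + (0:(target-1)) * Nm / target`, so when the input length is an integer
#' multiple of the target the original samples are reproduced exactly; shorter
#' recordings are zero-padded at the tail. Radar frames, belt trace, and truth
#' arrays are resampled together.
#'
#' @param record A `session_record`.
#' @param target_frames Output frame count.
#' @return The resampled `session_record`.
#' @export
resample_session <- function(record, target_frames = 660L) {
  stopifnot(inherits(record, "session_record"))
  nm <- length(record$belt)
  if (nm == 0) stop("empty session")
  if (nm == target_frames) return(record)

  resample_vec <- function(v) {
    if (nm > target_frames) {
      xout <- 1 + (seq_len(target_frames) - 1) * nm / target_frames
      stats::approx(seq_len(nm), v, xout = xout)$y
    } else {
      c(v, rep(0, target_frames - nm))
    }
  }
  record$belt <- resample_vec(record$belt)
  if (!is.null(record$frames)) {
    d <- dim(record$frames)
    flat <- matrix(record$frames, nrow = d[1])
    out <- apply(flat, 2, resample_vec)
    record$frames <- array(out, dim = c(target_frames, d[2], d[3], d[4]))
  }
  if (!is.null(record$truth)) {
    record$truth$displacement <- resample_vec(record$truth$displacement)
    mm <- resample_vec(as.numeric(record$truth$motion_mask))
    record$truth$motion_mask <- as.integer(mm > 0.5)
  }
  record$frame_rate <- target_frames / record$duration
  record
}

#' Range spectrum cube from raw frames
#'
#' Steps: (i) subtract the scalar mean of the whole cube, removing any
#' constant DC/ADC offset; (ii) average over chirps and receive channels,
#' which observe the same event and whose average is more noise-robust than
#' any single channel; (iii) complex FFT along fast time, keeping the
#' one-sided spectrum of `ns / 2` range bins.
#'
#' @param record A `session_record` with frames.
#' @param cfg A [radar_config()]; defaults to the one stored in the record.
#' @return An object of class `range_cube`: list with `sr` (complex
#'   `Nm x ns/2` matrix, column `s` = range bin `s - 1` of the FFT grid),
#'   `bin_spacing` (m), and `frame_rate` (Hz).
#' @export
to_range_cube <- function(record, cfg = record$cfg) {
  stopifnot(inherits(record, "session_record"))
  if (is.null(record$frames)) stop("session has no radar frames")
  d <- dim(record$frames)
  if (length(d) != 4 || d[2] != cfg$n_chirps || d[3] != cfg$n_rx ||
      d[4] != cfg$n_samples) {
    stop("frame cube shape ", paste(d, collapse = "x"),
         " does not match the radar config")
  }
  x <- record$frames - mean(record$frames)
  avg <- matrix(0, d[1], d[4])
  for (ci in seq_len(d[2])) {
    for (ri in seq_len(d[3])) avg <- avg + x[, ci, ri, ]
  }
  avg <- avg / (d[2] * d[3])
  spec <- stats::mvfft(t(avg))          # ns x Nm, FFT along fast time
  sr <- t(spec[seq_len(d[4] %/% 2), , drop = FALSE])
  structure(list(sr = sr, bin_spacing = range_bin_spacing(cfg),
                 frame_rate = record$frame_rate),
            class = "range_cube")
}

#' Strongest range bin of one frame
#'
#' Argmax of the range spectrum magnitude, restricted to bins at or above
#' `min_bin` to skip the zero-frequency region. Ties return the lowest index.
#'
#' @param cube A [to_range_cube()] result.
#' @param frame Frame index (1-based).
#' @param min_bin Lowest admissible bin column (1-based; default 2 skips DC).
#' @return Bin column index (1-based).
#' @export
detect_max_bin <- function(cube, frame, min_bin = 2L) {
  stopifnot(inherits(cube, "range_cube"))
  nbin <- ncol(cube$sr)
  if (frame < 1 || frame > nrow(cube$sr)) stop("frame out of range")
  mag <- Mod(cube$sr[frame, ])
  mag[seq_len(min(min_bin - 1L, nbin))] <- -Inf
  which.max(mag)
}

#' Track the processed range-bin window over a session
#'
#' Per frame, the window center is the trailing moving average (8 frames,
#' shorter during warm-up) of the per-frame strongest bin, rounded; the
#' processed window spans 12 bins, `center - 6 ... center + 5`, clipped at the
#' grid edges. Smoothing the center avoids abrupt window jumps caused by
#' instantaneous noise.
#'
#' @inheritParams detect_max_bin
#' @param smoother_len Moving-average length in frames.
#' @param width Window width in bins.
#' @return A `bin_track` list: `max_bin`, `center`, `lo`, `hi` (per-frame
#'   integer vectors), `smoother_len`, `width`.
#' @export
track_bin_window <- function(cube, smoother_len = 8L, width = 12L,
                             min_bin = 2L) {
  stopifnot(inherits(cube, "range_cube"))
  nm <- nrow(cube$sr)
  nbin <- ncol(cube$sr)
  max_bin <- vapply(seq_len(nm), function(m) detect_max_bin(cube, m, min_bin),
                    integer(1))
  center <- integer(nm)
  for (m in seq_len(nm)) {
    lo_m <- max(1L, m - smoother_len + 1L)
    center[m] <- as.integer(floor(mean(max_bin[lo_m:m]) + 0.5))
  }
  half_lo <- width %/% 2          # asymmetric split for even width: -6 ... +5
  lo <- center - half_lo
  hi <- lo + width - 1L
  shift_up <- pmax(0L, 1L - lo)
  lo <- lo + shift_up; hi <- hi + shift_up
  shift_dn <- pmax(0L, hi - nbin)
  hi <- hi - shift_dn; lo <- pmax(1L, lo - shift_dn)
  structure(list(max_bin = max_bin, center = center, lo = lo, hi = hi,
                 smoother_len = smoother_len, width = width),
            class = "bin_track")
}

#' Moving-target-indication clutter update
#'
#' Recursive exponential estimate of the static scene,
#' `S_new = alpha * S(m, s) + (1 - alpha) * S_old`, element-wise over the
#' currently selected bins. `alpha = 0.4` balances memory of previous clutter
#' against the current return.
#'
#' @param state A `clutter_state` from [clutter_state()], or `NULL` to start
#'   from zero.
#' @param sr_frame Complex values of the selected bins for the current frame.
#' @return The updated `clutter_state`.
#' @export
update_clutter <- function(state, sr_frame) {
  stopifnot(inherits(state, "clutter_state"))
  if (length(state$s_bar) != length(sr_frame)) {
    stop("clutter state covers ", length(state$s_bar),
         " bins but frame has ", length(sr_frame))
  }
  state$s_bar <- state$alpha * sr_frame + (1 - state$alpha) * state$s_bar
  state
}

#' @rdname update_clutter
#' @param n_bins Number of tracked bins.
#' @param alpha Smoothing weight in [0, 1].
#' @export
clutter_state <- function(n_bins, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(s_bar = complex(real = rep(0, n_bins)), alpha = alpha),
            class = "clutter_state")
}

#' Select the breathing bin within the tracked window
#'
#' Returns the bin maximizing the squared deviation from the updated clutter,
#' `|S(m, s) - S_new(s)|^2` - the per-frame "MSE to the clutter", i.e. the
#' highest peak-to-clutter bin, theoretically the subject position. Ties
#' return the lowest index.
#'
#' @param cube_frame Complex values of the windowed bins for the current frame.
#' @param clutter The updated `clutter_state` covering the same bins.
#' @return Index within the window (1-based).
#' @export
select_phase_bin <- function(cube_frame, clutter) {
  stopifnot(inherits(clutter, "clutter_state"))
  dev <- Mod(cube_frame - clutter$s_bar)^2
  which.max(dev)
}

#' Unwrap a wrapped phase sequence
#'
#' Threshold approach: wherever a consecutive difference exceeds pi in
#' magnitude, an integer multiple of 2 pi is added to the suffix so that all
#' consecutive differences of the output lie in (-pi, pi].
#'
#' @param raw Phase values in radians.
#' @return Unwrapped phase, same length; first element unchanged.
#' @export
unwrap_phase <- function(raw) {
  if (length(raw) < 2) return(raw)
  d <- diff(raw)
  k <- floor(d / (2 * pi) + 0.5)
  d_adj <- d - 2 * pi * k
  d_adj[d_adj <= -pi] <- d_adj[d_adj <= -pi] + 2 * pi
  raw[1] + cumsum(c(0, d_adj))
}

#' Extract the normalized unwrapped phase trace of a session
#'
#' Full preprocessing chain: resample to 660 frames, range FFT with DC removal
#' and chirp/channel averaging, dynamic 12-bin window tracking, per-frame MTI
#' clutter update, peak-to-clutter bin selection, phase of the (by default
#' clutter-subtracted) complex value at the selected bin, unwrapping, and
#' min-max normalization to [0, 1].
#'
#' @param record A `session_record` with frames.
#' @param cfg A [radar_config()].
#' @param target_frames Session length after resampling.
#' @param alpha MTI smoothing weight.
#' @param phase_source `"clutter_subtracted"` (default; rejects static
#'   reflections) or `"raw"` (phase of the unmodified bin value, which tracks
#'   absolute displacement more faithfully).
#' @param normalize `"minmax"` maps the unwrapped phase onto [0, 1];
#'   `"none"` skips normalization (`x` equals the unwrapped phase).
#' @param min_bin Lowest admissible bin for the max-bin search.
#' @param hysteresis Bin-selection hysteresis: the currently tracked bin is
#'   kept unless a challenger's peak-to-clutter deviation exceeds it by this
#'   factor (default 1.3). A target sitting on a range-cell boundary would otherwise
#'   alternate bins every few frames, and each switch costs one noisy offset
#'   estimate. 1 disables.
#' @return An object of class `phase_trace`: `x` (normalized, length
#'   `target_frames`), `raw_phase` (radians, unwrapped), `selected_bin`
#'   (per-frame absolute bin), `frame_rate`, `track` (the `bin_track`).
#' @export
extract_phase_trace <- function(record, cfg = record$cfg,
                                target_frames = 660L, alpha = 0.4,
                                phase_source = c("clutter_subtracted", "raw"),
                                normalize = c("minmax", "none"),
                                min_bin = 2L, hysteresis = 1.3) {
  phase_source <- match.arg(phase_source)
  normalize <- match.arg(normalize)
  record <- resample_session(record, target_frames)
  cube <- to_range_cube(record, cfg)
  track <- track_bin_window(cube, min_bin = min_bin)
  nm <- nrow(cube$sr)
  nbin <- ncol(cube$sr)

  s_bar <- complex(real = rep(0, nbin))   # clutter per absolute bin
  raw <- numeric(nm)
  selected <- integer(nm)
  offset <- 0
  prev_bin <- NA_integer_
  bin_phase <- function(m, b) {
    v <- cube$sr[m, b]
    if (phase_source == "clutter_subtracted") Arg(v - s_bar[b]) else Arg(v)
  }
  for (m in seq_len(nm)) {
    w <- track$lo[m]:track$hi[m]
    vals <- cube$sr[m, w]
    s_bar[w] <- alpha * vals + (1 - alpha) * s_bar[w]
    dev <- Mod(vals - s_bar[w])^2
    b <- w[which.max(dev)]
    if (!is.na(prev_bin) && b != prev_bin && prev_bin %in% w &&
        dev[match(prev_bin, w)] * hysteresis >= dev[match(b, w)]) {
      b <- prev_bin
    }
    selected[m] <- b
    # a bin switch changes the static phase offset of the echo; estimate the
    # offset jump as the circular mean phase difference over the trailing
    # frames and remove it so the trace stays continuous across switches
    if (!is.na(prev_bin) && b != prev_bin) {
      mm <- max(1L, m - 7L):m
      delta <- Arg(sum(exp(1i * (vapply(mm, bin_phase, numeric(1), b = b) -
                                   vapply(mm, bin_phase, numeric(1),
                                          b = prev_bin)))))
      offset <- offset + delta
    }
    prev_bin <- b
    raw[m] <- bin_phase(m, b) - offset
  }
  raw <- unwrap_phase(raw)
  x <- if (normalize == "minmax") {
    rng <- range(raw)
    if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else
      rep(0.5, length(raw))
  } else raw
  structure(list(x = x, raw_phase = raw, selected_bin = selected,
                 frame_rate = record$frame_rate, track = track),
            class = "phase_trace")
}
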