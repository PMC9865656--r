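#' Draw a synthetic user profile
#'
#' A user is characterised by a true central respiration frequency, a chest
#' displacement amplitude, an inhale/exhale asymmetry, a typical chest-to-board
#' distance, a motion-burst rate, and the gain of the reference belt. The
#' defaults emulate a healthy adult behaving normally at a desk 20-40 cm from
#' the radar: `fc_true` uniform on [0.12, 0.48] Hz, peak-to-peak chest
#' displacement log-uniform on 2-10 mm (typical tidal chest-wall motion at the diaphragm), and on average four motion bursts
#' (typing, laughing, reaching) per 30 s session.
#'
#' @param seed Integer seed; the profile is deterministic given the seed.
#' @param overrides Named list overriding any drawn field.
#' @return An object of class `user_profile` with fields `user_id`, `fc_true`
#'   (Hz), `breath_amp` (m, peak-to-peak), `duty_asymmetry` (inhale fraction of
#'   the cycle, in (0,1)), `base_range` (m), `motion_rate` (expected bursts per
#'   session), `motion_amp` (m, typical burst excursion), `belt_gain` (N/m).
#' @examples
#' u <- make_user(1)
#' u$fc_true
#' @export
make_user <- function(seed, overrides = list()) {
  rng <- local({ set.seed(seed); list(
    fc_true = stats::runif(1, 0.12, 0.48),
    breath_amp = exp(stats::runif(1, log(2e-3), log(10e-3))),
    duty_asymmetry = stats::runif(1, 0.35, 0.6),
    base_range = stats::runif(1, 0.2, 0.4),
    motion_rate = 4,
    motion_amp = stats::runif(1, 0.02, 0.05),
    belt_gain = stats::runif(1, 300, 700)
  )})
  prof <- utils::modifyList(rng, overrides)
  prof$user_id <- if (!is.null(overrides$user_id)) overrides$user_id else
    sprintf("user%06d", seed %% 1000000L)
  band <- respiration_band()
  if (prof$fc_true < band["lo"] || prof$fc_true > band["hi"]) {
    stop("invalid user profile: fc_true must lie in [",
         band["lo"], ", ", band["hi"], "] Hz")
  }
  if (prof$breath_amp <= 0) stop("invalid user profile: breath_amp must be > 0")
  if (prof$duty_asymmetry <= 0 || prof$duty_asymmetry >= 1) {
    stop("invalid user profile: duty_asymmetry must be in (0,1)")
  }
  if (prof$base_range <= 0) stop("invalid user profile: base_range must be > 0")
  if (prof$motion_rate < 0) stop("invalid user profile: motion_rate must be >= 0")
  structure(prof, class = "user_profile")
}

# Periodic asymmetric breath waveform on [0,1): raised-cosine inhale over the
# first `duty` fraction of the cycle, raised-cosine exhale over the rest.
# Returns values in [0,1]; duty = 0.5 is a pure sinusoid (phase-shifted).
breath_waveform <- function(u, duty = 0.5) {
  u <- u %% 1
  out <- numeric(length(u))
  inh <- u < duty
  out[inh] <- 0.5 - 0.5 * cos(pi * u[inh] / duty)
  out[!inh] <- 0.5 + 0.5 * cos(pi * (u[!inh] - duty) / (1 - duty))
  out
}

# Sparse motion bursts of 1.5-6 s (typing, laughing, reaching episodes; the
# upper end matters for slow breathers, whose 10-12 s autocorrelation windows
# dilute shorter bursts below detectability). Each burst carries a sine
# envelope (the
# hands swing in and out of the field of view) and an integrated
# Gaussian-increment range trajectory (random walk) tapered by that envelope,
# scaled to a peak excursion ~ motion_amp. `m` drives the interfering
# scatterer's range, `env` its strength and the occlusion of the chest echo.
motion_trace <- function(n, fs, n_bursts, motion_amp) {
  m <- numeric(n)
  env <- numeric(n)
  mask <- integer(n)
  if (n_bursts <= 0) return(list(m = m, env = env, mask = mask))
  for (b in seq_len(n_bursts)) {
    len <- round(stats::runif(1, 1.5, 6) * fs)
    len <- min(len, n)
    start <- sample.int(max(1L, n - len + 1L), 1L)
    idx <- start:(start + len - 1L)
    walk <- cumsum(stats::rnorm(len))
    walk <- walk - walk[1]
    peak <- max(abs(walk))
    if (peak > 0) walk <- walk / peak * motion_amp
    e <- sin(pi * seq(0, 1, length.out = len))
    m[idx] <- m[idx] + walk * e
    env[idx] <- pmax(env[idx], e)
    mask[idx] <- 1L
  }
  list(m = m, env = env, mask = mask)
}

#' Default noise / scene specification for the simulator
#'
#' Amplitudes are in ADC counts on a 12-bit scale. The static clutter is a set
#' of reflectors at fixed ranges (desk edge, monitor, wall) plus one weaker
#' reflector near the user; the user echo is the strongest return, as expected
#' for the closest target.
#'
#' @param adc_sd White-noise standard deviation per sample (counts).
#' @param dc_offset Constant ADC offset (counts).
#' @param target_amp User echo amplitude (counts).
#' @param clutter_ranges Ranges (m) of static reflectors; `NA` entries are
#'   placed relative to the user at +0.15 m.
#' @param clutter_amps Amplitudes (counts) of the static reflectors.
#' @param belt_sd Belt sensor noise standard deviation (N), added before
#'   0.1 N quantization.
#' @param interferer_amp Echo amplitude (counts) of the moving scatterer
#'   active during motion bursts.
#' @return A named list.
#' @export
noise_spec <- function(adc_sd = 5, dc_offset = 100, target_amp = 300,
                       clutter_ranges = c(NA, 0.9, 1.6, 2.4),
                       clutter_amps = c(120, 150, 100, 80),
                       belt_sd = 0.02, interferer_amp = 300) {
  list(adc_sd = adc_sd, dc_offset = dc_offset, target_amp = target_amp,
       clutter_ranges = clutter_ranges, clutter_amps = clutter_amps,
       belt_sd = belt_sd, interferer_amp = interferer_amp)
}

#' Simulate one synchronized radar + belt recording session
#'
#' Generates a raw radar frame cube and a quantized reference belt trace for a
#' breathing user in front of a cluttered static scene. The chest range is
#' `R(t) = base_range + d(t)`, with `d(t)` a periodic asymmetric breath
#' displacement. Each chirp's intermediate-frequency samples contain a tone at
#' the beat frequency `2 * Bw * R / (c * tc)` with carrier phase
#' `4 * pi * R / lambda`, static clutter tones at other ranges, white noise,
#' and a constant DC offset. Motion bursts model hands moving toward the desk
#' through the radar line of sight for 1.5-6 s: the chest echo is partially
#' occluded (60 GHz does not penetrate the arms) in proportion to the burst
#' envelope and `motion_amp`, while a speckle-like interfering echo appears
#' near the chest range, its position following a tapered random walk plus
#' frame-to-frame sub-millimetre jitter. The selected range bin's phase
#' therefore turns into bounded, rapidly decorrelating jitter during the
#' burst - the corruption signature seen in real recordings. The belt sees
#' the breathing displacement (arm motion is invisible to the chest-worn
#' sensor), scaled by `belt_gain` and quantized to 0.1 N.
#'
#' @param profile A [make_user()] profile.
#' @param cfg A [radar_config()].
#' @param duration Session length in seconds (default 30).
#' @param seed Integer seed.
#' @param noise A [noise_spec()] list.
#' @param frames_hz Slow-time simulation rate (frames per second). The default
#'   22 Hz yields 660 frames per 30 s session, matching the fixed session
#'   length used downstream.
#' @param distance_class Label `"30cm"` or `"40cm"` recorded in the session.
#' @param belt_sees_motion If `TRUE`, motion bursts also enter the belt trace.
#' @param quantize_adc If `TRUE`, round radar samples to integer counts and
#'   clip to the signed 12-bit range.
#' @return An object of class `session_record`: list with `frames`
#'   (`Nm x Nc x NRx x ns` array of ADC counts), `belt` (N), `user_id`,
#'   `distance_class`, `frame_rate`, `duration`, `cfg`, and `truth`
#'   (`displacement` (m), `motion_mask`, `fc_true`).
#' @export
simulate_session <- function(profile, cfg = radar_config(), duration = 30,
                             seed = 1, noise = noise_spec(), frames_hz = 22,
                             distance_class = NULL, belt_sees_motion = FALSE,
                             quantize_adc = FALSE) {
  stopifnot(inherits(profile, "user_profile"), inherits(cfg, "radar_config"))
  if (duration <= 0) stop("duration must be > 0")
  set.seed(seed)

  nm <- round(duration * frames_hz)
  tt <- (seq_len(nm) - 1) / frames_hz
  phase0 <- stats::runif(1)

  d_breath <- profile$breath_amp *
    (breath_waveform(profile$fc_true * tt + phase0, profile$duty_asymmetry) - 0.5)
  n_bursts <- stats::rpois(1, profile$motion_rate)
  mot <- motion_trace(nm, frames_hz, n_bursts, profile$motion_amp)
  d <- d_breath
  r_chest <- profile$base_range + d
  if (max(r_chest) >= max_range(cfg)) {
    stop("out of range: chest range (", signif(max(r_chest), 3),
         " m) reaches the maximum detection range (", max_range(cfg), " m)")
  }

  lambda <- wavelength(cfg)
  t_fast <- (seq_len(cfg$n_samples) - 1) / cfg$fs_adc

  # user echo: ns x Nm matrix of IF samples, one column per frame; the chest
  # is occluded by the moving hands in proportion to the burst envelope
  occ_depth <- min(0.95, 35 * profile$motion_amp)
  amp_chest <- noise$target_amp * (1 - occ_depth * mot$env)
  fb <- beat_frequency(cfg, r_chest)
  phi <- 4 * pi * r_chest / lambda
  sig <- cos(outer(t_fast, 2 * pi * fb) +
               matrix(phi, cfg$n_samples, nm, byrow = TRUE)) *
    matrix(amp_chest, cfg$n_samples, nm, byrow = TRUE)

  # static clutter: fixed tones shared by every frame
  cl_ranges <- noise$clutter_ranges
  cl_ranges[is.na(cl_ranges)] <- profile$base_range + 0.15
  keep <- cl_ranges < max_range(cfg) & noise$clutter_amps > 0
  clutter <- numeric(cfg$n_samples)
  for (j in which(keep)) {
    clutter <- clutter + noise$clutter_amps[j] *
      cos(2 * pi * beat_frequency(cfg, cl_ranges[j]) * t_fast +
            stats::runif(1, 0, 2 * pi))
  }
  # interfering speckle echo (hands) during motion bursts: i.i.d. sub-mm
  # range jitter around a fixed offset, so its phase decorrelates frame to
  # frame without accumulating drift or leaking into the respiration band
  burst <- which(mot$mask == 1L)
  if (length(burst) && noise$interferer_amp > 0) {
    r_int <- profile$base_range + 0.02 +
      stats::rnorm(length(burst), sd = 3e-4)
    fb_i <- beat_frequency(cfg, r_int)
    phi_i <- 4 * pi * r_int / lambda
    amp_i <- noise$interferer_amp * mot$env[burst] *
      min(1, 25 * profile$motion_amp)
    sig[, burst] <- sig[, burst] +
      cos(outer(t_fast, 2 * pi * fb_i) +
            matrix(phi_i, cfg$n_samples, length(burst), byrow = TRUE)) *
      matrix(amp_i, cfg$n_samples, length(burst), byrow = TRUE)
  }

  base <- t(sig + clutter + noise$dc_offset)   # Nm x ns

  frames <- array(0, dim = c(nm, cfg$n_chirps, cfg$n_rx, cfg$n_samples))
  for (ci in seq_len(cfg$n_chirps)) {
    for (ri in seq_len(cfg$n_rx)) {
      slice <- base
      if (noise$adc_sd > 0) {
        slice <- slice + matrix(stats::rnorm(nm * cfg$n_samples, sd = noise$adc_sd),
                                nm, cfg$n_samples)
      }
      frames[, ci, ri, ] <- slice
    }
  }
  if (quantize_adc) {
    frames <- pmax(pmin(round(frames), 2047), -2048)
  }

  belt_disp <- if (belt_sees_motion) d else d_breath
  belt <- profile$belt_gain * belt_disp
  if (noise$belt_sd > 0) belt <- belt + stats::rnorm(nm, sd = noise$belt_sd)
  belt <- round(belt / 0.1) * 0.1

  if (is.null(distance_class)) {
    distance_class <- if (profile$base_range <= 0.3) "30cm" else "40cm"
  }
  structure(
    list(frames = frames, belt = belt, user_id = profile$user_id,
         distance_class = distance_class, frame_rate = frames_hz,
         duration = duration, cfg = cfg,
         truth = list(displacement = d, motion_mask = mot$mask,
                      fc_true = profile$fc_true)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s [%s] %d frames @ %g Hz, %g s\n",
              x$user_id, x$distance_class, dim(x$frames)[1], x$frame_rate,
              x$duration))
  invisible(x)
}

#' Generate a full synthetic meta-dataset
#'
#' Simulates a cohort of users and writes one session container per recording
#' plus a manifest. Defaults reproduce the study protocol: 14 training users
#' and 10 test users, 20 sessions of 30 s each per user, half of each user's
#' sessions at chest-to-board distances up to 30 cm and half up to 40 cm -
#' 480 sessions and 4 h of signal in total.
#'
#' @param dir Output directory (created if missing).
#' @param n_train_users,n_test_users Cohort split sizes.
#' @param sessions_per_user Sessions per user.
#' @param cfg A [radar_config()].
#' @param seed Integer master seed; all per-user and per-session seeds derive
#'   from it.
#' @param duration Session length in seconds.
#' @param store_frames If `FALSE`, the raw frame cube is simulated but not
#'   written; the container keeps belt, truth and metadata. Use for protocol
#'   audits where the ~6 MB/session cubes are not needed on disk.
#' @param user_overrides Named list applied to every drawn user profile.
#' @return Invisibly, the manifest `data.frame` with columns `session_path`,
#'   `user_id`, `split`, `distance_class`, `fc_true`, `duration`. Also written
#'   to `file.path(dir, "manifest.csv")`.
#' @export
build_meta_dataset <- function(dir, n_train_users = 14, n_test_users = 10,
                               sessions_per_user = 20, cfg = radar_config(),
                               seed = 1, duration = 30, store_frames = TRUE,
                               user_overrides = list()) {
  if (n_train_users < 1 || sessions_per_user < 1 || n_test_users < 0) {
    stop("counts must be >= 1 (n_test_users may be 0)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_users <- n_train_users + n_test_users
  set.seed(seed)
  user_seeds <- sample.int(2^31 - 1, n_users)
  sess_seeds <- matrix(sample.int(2^31 - 1, n_users * sessions_per_user),
                       nrow = n_users)
  base_ranges <- matrix(stats::runif(n_users * sessions_per_user, 0, 1),
                        nrow = n_users)

  rows <- vector("list", n_users * sessions_per_user)
  k <- 0L
  for (ui in seq_len(n_users)) {
    ov <- user_overrides
    ov$user_id <- sprintf("user%03d", ui)
    prof <- make_user(user_seeds[ui], overrides = ov)
    split <- if (ui <= n_train_users) "train" else "test"
    n30 <- ceiling(sessions_per_user / 2)
    for (si in seq_len(sessions_per_user)) {
      near <- si <= n30
      cls <- if (near) "30cm" else "40cm"
      prof_s <- prof
      prof_s$base_range <- if (near) 0.20 + 0.10 * base_ranges[ui, si] else
        0.30 + 0.10 * base_ranges[ui, si]
      rec <- simulate_session(prof_s, cfg, duration = duration,
                              seed = sess_seeds[ui, si],
                              distance_class = cls)
      path <- file.path(dir, sprintf("user%03d_s%02d.rds", ui, si))
      if (!store_frames) rec$frames <- NULL
      write_session(rec, path)
      k <- k + 1L
      rows[[k]] <- data.frame(session_path = path, user_id = prof$user_id,
                              split = split, distance_class = cls,
                              fc_true = prof$fc_true, duration = duration,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
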