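# Shared, lazily-built fixtures. Everything is generated in code from fixed
# seeds; expensive objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# idle user sitting mid-bin (no boundary ambiguity), no motion
idle_session <- function() fixture("idle", function() {
  cfg <- radar_config()
  u <- make_user(42, overrides = list(motion_rate = 0,
                                      base_range = 5 * range_bin_spacing(cfg)))
  rec <- simulate_session(u, cfg, seed = 7)
  list(user = u, rec = rec, cfg = cfg)
})

# idle user without noise, for exact-physics checks
idle_noiseless <- function() fixture("idle0", function() {
  cfg <- radar_config()
  u <- make_user(42, overrides = list(motion_rate = 0,
                                      base_range = 5 * range_bin_spacing(cfg)))
  rec <- simulate_session(u, cfg, seed = 7,
                          noise = noise_spec(adc_sd = 0, belt_sd = 0))
  list(user = u, rec = rec, cfg = cfg)
})

tiny_arch <- function() cvae_architecture(input_len = 20L, latent_dim = 3L,
                                          enc_filters = c(4L, 6L))

small_arch <- function() cvae_architecture(latent_dim = 8L,
                                           enc_filters = c(8L, 16L))

# one scaled meta-training study, reused by episodic properties and the
# acceptance suite
scaled_fit <- function() fixture("scaled_fit", function() {
  scaled_meta_experiment(seed = 1)
})
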