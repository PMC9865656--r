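#' Scaled-down episodic training study
#'
#' A self-contained, seeded reduction of the full episodic protocol, sized so
#' the whole study runs in minutes on one CPU: 6 synthetic users (4 training,
#' 2 test) with 6 sessions of 30 s each, second-order MAML for 60 episodes
#' with 1-shot support and a query batch of 3, a latent dimension of 8 with a
#' reduced convolutional backbone (8/16 filters), the deterministic latent
#' code during training, and fixed evaluation tasks so the learning curve is
#' a paired comparison. Evaluation adapts on the least-corrupted session of
#' the evaluated user, per the recommendation that heavily corrupted sessions
#' should not be used for adaptation.
#'
#' Two summary quantities are produced. The learning trend compares the mean
#' evaluated test-task loss over the first half of the evaluation points with
#' the second half. The adaptation experiment draws fresh synthetic test
#' users and measures, over `n_adapt_trials` trials, how often one-shot
#' adaptation moves the predicted central frequency closer to the user's true
#' frequency; support sessions are required to be motion-corrupted, since the
#' corruption-weighted loss routes frequency supervision through the
#' corrupted regime by design.
#'
#' @param seed Master seed for the whole study.
#' @param cfg A [radar_config()].
#' @param n_train_users,n_test_users,sessions_per_user Cohort shape.
#' @param episodes,eval_every,eval_examples Training schedule.
#' @param latent_dim,enc_filters Model size.
#' @param n_adapt_trials Adaptation-improvement trials.
#' @return List with `fit` (the [train_meta()] result), `model`, `arch`,
#'   `tasks`, `trend` (`first_block`, `last_block` mean test-task losses),
#'   and `adapt` (`wins`, `trials`, `pre_err`, `post_err`).
#' @export
scaled_meta_experiment <- function(seed = 1, cfg = radar_config(),
                                   n_train_users = 4L, n_test_users = 2L,
                                   sessions_per_user = 6L,
                                   episodes = 60L, eval_every = 10L,
                                   eval_examples = 5L,
                                   latent_dim = 8L,
                                   enc_filters = c(8L, 16L),
                                   n_adapt_trials = 20L) {
  n_users <- n_train_users + n_test_users
  set.seed(seed)
  user_seeds <- sample.int(2^31 - 1, n_users)
  sess_seeds <- matrix(sample.int(2^31 - 1, n_users * sessions_per_user),
                       n_users)
  sessions <- list()
  splits <- character()
  for (u in seq_len(n_users)) {
    prof <- make_user(user_seeds[u],
                      overrides = list(user_id = sprintf("u%02d", u)))
    for (k in seq_len(sessions_per_user)) {
      sessions <- c(sessions,
                    list(simulate_session(prof, cfg, seed = sess_seeds[u, k])))
    }
    splits[sprintf("u%02d", u)] <- if (u <= n_train_users) "train" else "test"
  }
  tasks <- prepare_meta_tasks(sessions, splits, cfg, latent_dim = 0L)

  arch <- cvae_architecture(latent_dim = latent_dim,
                            enc_filters = enc_filters)
  model <- cvae_meta_model(cvae_init(arch, seed = seed))
  mc <- meta_config("maml2", episodes = episodes, eval_every = eval_every,
                    eval_examples = eval_examples, shots = 1L,
                    query_size = 3L)
  fit <- train_meta(tasks, model, mc, seed = seed + 1L,
                    eval_fixed_tasks = TRUE)

  tv <- fit$eval_log[fit$eval_log$split == "test_task", ]
  k <- nrow(tv)
  half <- k %/% 2
  trend <- list(first_block = mean(tv$mean[seq_len(half)]),
                last_block = mean(tv$mean[(k - half + 1L):k]))

  pre_err <- post_err <- numeric(0)
  tr <- 0L
  while (length(pre_err) < n_adapt_trials && tr < 50L * n_adapt_trials) {
    tr <- tr + 1L
    prof <- make_user(seed * 100L + tr, overrides = list(user_id = "new"))
    s_sup <- simulate_session(prof, cfg, seed = seed * 211L + tr)
    s_qry <- simulate_session(prof, cfg, seed = seed * 307L + tr)
    tk <- prepare_meta_tasks(list(s_sup, s_qry), c(new = "test"), cfg)
    sup <- tk$users$new[[1]]
    if (sup$gamma == 0) next      # frequency pathway inactive on clean supports
    qry <- tk$users$new[[2]]
    m0 <- structure(list(arch = arch,
                         params = par_unflatten(fit$par, model$skeleton)),
                    class = "cvae")
    pre <- abs(cvae_predict(m0, qry$x)$y_hat - prof$fc_true)
    par_ad <- adapt_to_user(fit$par, model, list(sup),
                            inner_lr = mc$inner_lr, epochs = 4L)
    m1 <- structure(list(arch = arch,
                         params = par_unflatten(par_ad, model$skeleton)),
                    class = "cvae")
    post <- abs(cvae_predict(m1, qry$x)$y_hat - prof$fc_true)
    pre_err <- c(pre_err, pre)
    post_err <- c(post_err, post)
  }
  list(fit = fit, model = model, arch = arch, tasks = tasks, trend = trend,
       adapt = list(wins = sum(post_err < pre_err),
                    trials = length(pre_err),
                    pre_err = pre_err, post_err = post_err))
}

#' Central-frequency recovery study on idle users
#'
#' Simulates `n_users` idle (motion-free) users, runs the full preprocessing
#' chain on each session, estimates the central respiration frequency from
#' the spectral peak of the extracted phase trace, and compares with the
#' simulated truth.
#'
#' @param seed Master seed.
#' @param n_users Number of users (one session each).
#' @param cfg A [radar_config()].
#' @return List with `fc_true`, `fc_est`, `max_abs_err` (Hz), and
#'   `rank_correlation` (Spearman).
#' @export
fc_recovery_experiment <- function(seed = 1, n_users = 20L,
                                   cfg = radar_config()) {
  set.seed(seed)
  useeds <- sample.int(2^31 - 1, n_users)
  sseeds <- sample.int(2^31 - 1, n_users)
  fc_true <- fc_est <- numeric(n_users)
  for (i in seq_len(n_users)) {
    u <- make_user(useeds[i], overrides = list(motion_rate = 0))
    rec <- simulate_session(u, cfg, seed = sseeds[i])
    trace <- extract_phase_trace(rec, cfg)
    fc_true[i] <- u$fc_true
    fc_est[i] <- belt_fc_reference(trace$x, rec$frame_rate)$fc
  }
  list(fc_true = fc_true, fc_est = fc_est,
       max_abs_err = max(abs(fc_true - fc_est)),
       rank_correlation = stats::cor(fc_true, fc_est, method = "spearman"))
}

#' Motion-corruption response study
#'
#' Measures the mean corruption fraction of full pipeline runs as a function
#' of motion-burst amplitude (at a fixed burst rate) averaged over seeded
#' users, plus the idle baseline.
#'
#' @param seed Master seed.
#' @param amplitudes Burst peak amplitudes (m); 0 entries are simulated idle.
#' @param n_seeds Users per amplitude level.
#' @param motion_rate Expected bursts per session for non-idle levels.
#' @param cfg A [radar_config()].
#' @return List with `amplitudes` and `mean_gamma` (same length).
#' @export
corruption_response_experiment <- function(seed = 1,
                                           amplitudes = c(0, 0.005, 0.02, 0.04),
                                           n_seeds = 20L, motion_rate = 2,
                                           cfg = radar_config()) {
  mean_gamma <- vapply(amplitudes, function(a) {
    mean(vapply(seq_len(n_seeds), function(s) {
      ov <- if (a == 0) list(motion_rate = 0) else
        list(motion_rate = motion_rate, motion_amp = a)
      u <- make_user(seed * 500L + s, overrides = ov)
      rec <- simulate_session(u, cfg, seed = seed * 900L + s)
      trace <- extract_phase_trace(rec, cfg)
      y <- belt_fc_reference(rec$belt, rec$frame_rate)$fc
      breath_metrics(trace$x, rec$frame_rate, fc = y)$corruption_fraction
    }, numeric(1)))
  }, numeric(1))
  list(amplitudes = amplitudes, mean_gamma = mean_gamma)
}
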