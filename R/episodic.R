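#' Episodic training configuration
#'
#' Defaults follow the study protocol: 3000 episodes of 4 inner epochs,
#' Adam(beta1 = 0, beta2 = 0.5) on the outer step, inner learning rate
#' 1.8e-3 for 1-shot (8e-4 for 5/10-shot), outer rate 1.7e-3, evaluation
#' every 300 episodes on 10 query examples; Reptile uses inner rate 3e-5 and
#' meta step 0.4; the stabilized variant starts its cosine-annealed outer
#' rate at 1.7e-5.
#'
#' @param algorithm One of `"maml2"`, `"maml1"`, `"reptile"`, `"mamlplus"`.
#' @param episodes Number of training episodes.
#' @param epochs_per_episode Inner gradient-descent epochs per episode.
#' @param shots Support examples per episode (1, 5 or 10).
#' @param query_size Query examples per episode (default = shots).
#' @param inner_lr Inner-loop learning rate; default depends on `shots`.
#' @param outer_lr Outer (meta) learning rate.
#' @param adam_beta1,adam_beta2 Adam moment coefficients for the outer step.
#' @param adam_eps Adam denominator offset. With the protocol's
#'   `beta1 = 0, beta2 = 0.5` the update degenerates to sign-steps for
#'   coordinates with tiny gradients, letting tens of thousands of
#'   weakly-constrained weights random-walk; an offset of 1e-3 damps those
#'   coordinates toward plain SGD behavior while leaving large-gradient
#'   coordinates fully Adam-normalized.
#' @param inner_clip Gradient-norm clip for the inner loop of the *training*
#'   episodes. The second-order meta-gradient differentiates through the
#'   inner trajectory, so large inner excursions feed curvature amplification
#'   back into the outer step; a conservative clip keeps the trajectory near
#'   the meta-parameters. User adaptation at deployment
#'   ([adapt_to_user()]) is first-order and uses its own, larger clip.
#' @param weight_decay L2 coefficient added to the outer meta-gradient
#'   (`g + weight_decay * theta`). Under the protocol's sign-step-like Adam
#'   there is otherwise no magnitude-proportional restoring force on weakly
#'   constrained weights, and the latent heads can grow without bound.
#' @param eval_every Evaluate every this many episodes.
#' @param eval_examples Query examples per evaluation task.
#' @param reptile_meta_step,reptile_inner_lr Reptile hyperparameters.
#' @param mamlplus_outer_lr0 Initial outer rate for cosine annealing.
#' @param mamlplus_da_fraction Fraction of episodes trained first-order
#'   before switching to second-order (derivative-order annealing).
#' @param mamlplus_lr_floor_frac Cosine-annealing floor as a fraction of
#'   `mamlplus_outer_lr0`.
#' @return A `meta_config` list.
#' @export
meta_config <- function(algorithm = c("maml2", "maml1", "reptile", "mamlplus"),
                        episodes = 3000L, epochs_per_episode = 4L,
                        shots = 1L, query_size = shots,
                        inner_lr = if (shots == 1) 1.8e-3 else 8e-4,
                        outer_lr = 1.7e-3,
                        adam_beta1 = 0, adam_beta2 = 0.5, adam_eps = 1e-3,
                        inner_clip = 10, weight_decay = 1e-2,
                        eval_every = 300L, eval_examples = 10L,
                        reptile_meta_step = 0.4, reptile_inner_lr = 3e-5,
                        mamlplus_outer_lr0 = 1.7e-5,
                        mamlplus_da_fraction = 0.3,
                        mamlplus_lr_floor_frac = 0.01) {
  algorithm <- match.arg(algorithm)
  if (!shots %in% c(1L, 5L, 10L)) stop("shots must be 1, 5 or 10")
  if (episodes > 0 && eval_every > 0 && episodes %% eval_every != 0) {
    stop("eval_every must divide episodes")
  }
  structure(list(algorithm = algorithm, episodes = as.integer(episodes),
                 epochs_per_episode = as.integer(epochs_per_episode),
                 shots = as.integer(shots), query_size = as.integer(query_size),
                 inner_lr = inner_lr, outer_lr = outer_lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, inner_clip = inner_clip,
                 weight_decay = weight_decay,
                 eval_every = as.integer(eval_every),
                 eval_examples = as.integer(eval_examples),
                 reptile_meta_step = reptile_meta_step,
                 reptile_inner_lr = reptile_inner_lr,
                 mamlplus_outer_lr0 = mamlplus_outer_lr0,
                 mamlplus_da_fraction = mamlplus_da_fraction,
                 mamlplus_lr_floor_frac = mamlplus_lr_floor_frac),
            class = "meta_config")
}

# ---- generic meta-model interface -----------------------------------------
# A meta-model is a list with:
#   par0    : initial flat parameter vector
#   fn_gr   : function(par, samples) -> list(loss =, grad =) (mean over samples)
#   hvp     : optional function(par, samples, v) -> Hessian-vector product;
#             when absent, a central finite difference of fn_gr's analytic
#             gradient is used.

model_hvp <- function(model, par, samples, v, rel_step = 1e-6) {
  if (!is.null(model$hvp)) return(model$hvp(par, samples, v))
  vmax <- max(abs(v))
  if (vmax == 0) return(v)
  h <- rel_step * (1 + max(abs(par))) / vmax
  gp <- model$fn_gr(par + h * v, samples)$grad
  gm <- model$fn_gr(par - h * v, samples)$grad
  (gp - gm) / (2 * h)
}

#' Wrap a C-VAE as a meta-model
#'
#' Produces the flat-parameter interface consumed by the episodic trainer.
#' A training sample is a list with fields `x`, `x_belt`, `y`, `tau`,
#' `gamma`, and optionally `eta` (latent noise; `NULL` gives the
#' deterministic code `z = mu`). The loss is the mean L* over the samples.
#'
#' @param model A [cvae_init()] model providing architecture and
#'   initialization.
#' @param K Frequency-term equalization coefficient.
#' @return A meta-model list (`par0`, `fn_gr`, `skeleton`, `arch`).
#' @export
cvae_meta_model <- function(model, K = 1000) {
  stopifnot(inherits(model, "cvae"))
  arch <- model$arch
  skeleton <- model$params
  fn_gr <- function(par, samples) {
    params <- par_unflatten(par, skeleton)
    total <- 0
    gsum <- NULL
    for (s in samples) {
      lg <- cvae_loss_grad(params, arch, s$x, s$x_belt, s$y, eta = s$eta,
                           tau = s$tau, gamma = s$gamma, K = K)
      if (!is.finite(lg$loss)) stop("non-finite loss in episode")
      total <- total + lg$loss
      gv <- par_flatten(lg$grad)
      gsum <- if (is.null(gsum)) gv else gsum + gv
    }
    n <- length(samples)
    list(loss = total / n, grad = gsum / n)
  }
  list(par0 = par_flatten(model$params), fn_gr = fn_gr,
       skeleton = skeleton, arch = arch)
}

#' Toy task family with analytic Hessian
#'
#' A non-quadratic 10-parameter regression surrogate used to validate the
#' meta-gradient machinery: per-task loss
#' `0.5 t(theta) A theta - t(b) theta + lambda / 4 * (t(theta) theta)^2`
#' with analytic gradient and Hessian-vector product. Tasks (samples) are
#' lists `(A, b, lambda)`.
#'
#' @param n_par Parameter dimension.
#' @return A meta-model list with `par0`, `fn_gr`, `hvp`, and
#'   `make_task(seed)` drawing a random task.
#' @export
quartic_meta_model <- function(n_par = 10L) {
  fn_gr <- function(par, samples) {
    loss <- 0
    grad <- numeric(length(par))
    for (s in samples) {
      loss <- loss + 0.5 * sum(par * (s$A %*% par)) - sum(s$b * par) +
        s$lambda / 4 * sum(par^2)^2
      grad <- grad + as.vector(s$A %*% par) - s$b +
        s$lambda * sum(par^2) * par
    }
    n <- length(samples)
    list(loss = loss / n, grad = grad / n)
  }
  hvp <- function(par, samples, v) {
    out <- numeric(length(par))
    for (s in samples) {
      out <- out + as.vector(s$A %*% v) +
        s$lambda * (sum(par^2) * v + 2 * par * sum(par * v))
    }
    out / length(samples)
  }
  make_task <- function(seed) {
    set.seed(seed)
    M <- matrix(stats::rnorm(n_par^2), n_par)
    list(A = crossprod(M) / n_par + diag(n_par), b = stats::rnorm(n_par),
         lambda = stats::runif(1, 0.1, 0.5))
  }
  list(par0 = numeric(n_par), fn_gr = fn_gr, hvp = hvp, make_task = make_task)
}

# ---- Adam outer optimizer --------------------------------------------------

adam_state <- function(n_par) list(m = numeric(n_par), v = numeric(n_par), t = 0L)

adam_update <- function(state, par, grad, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- episodic operations ---------------------------------------------------

#' Sample one training episode
#'
#' Draws a user uniformly from the training split and disjoint support and
#' query session sets from that user.
#'
#' @param tasks A task bank from [prepare_meta_tasks()].
#' @param shots Support set size.
#' @param seed Integer seed.
#' @param query_size Query set size (default = shots).
#' @param split Which split to sample the user from.
#' @param support_policy `"random"` draws the support uniformly;
#'   `"least_corrupted"` adapts on the user's cleanest sessions (lowest
#'   corruption fraction, ties by session order), following the
#'   recommendation that heavily motion-corrupted sessions should not be
#'   used for adaptation. Queries are drawn from the remaining sessions
#'   either way.
#' @return List `(task_user, support, query)`.
#' @export
sample_episode <- function(tasks, shots, seed, query_size = shots,
                           split = "train",
                           support_policy = c("random", "least_corrupted")) {
  support_policy <- match.arg(support_policy)
  users <- names(tasks$users)[tasks$splits == split]
  if (!length(users)) stop("no users in split '", split, "'")
  set.seed(seed)
  u <- users[sample.int(length(users), 1)]
  samples <- tasks$users[[u]]
  n <- length(samples)
  if (n <= shots) {
    stop("insufficient sessions: user ", u, " has ", n,
         " sessions, need > ", shots)
  }
  if (support_policy == "least_corrupted") {
    gammas <- vapply(samples, function(s) s$gamma, numeric(1))
    ord <- order(gammas, seq_len(n))
    support_idx <- ord[seq_len(shots)]
    rest <- setdiff(sample.int(n), support_idx)
    query_idx <- rest[seq_len(min(query_size, n - shots))]
  } else {
    idx <- sample.int(n)
    support_idx <- idx[seq_len(shots)]
    query_idx <- idx[shots + seq_len(min(query_size, n - shots))]
  }
  d <- if (!is.null(tasks$latent_dim)) tasks$latent_dim else 0L
  attach_eta <- function(s) {
    if (d > 0) s$eta <- stats::rnorm(d)
    s
  }
  list(task_user = u,
       support = lapply(samples[support_idx], attach_eta),
       query = lapply(samples[query_idx], attach_eta))
}

#' Inner-loop adaptation
#'
#' `epochs` full passes of plain gradient descent on the mean loss over the
#' support set. With `track_higher_order = TRUE` the parameter trajectory is
#' retained so the outer step can differentiate through the inner updates.
#'
#' @param par Flat parameter vector.
#' @param model A meta-model (see [cvae_meta_model()]).
#' @param support Support samples.
#' @param inner_lr Learning rate.
#' @param epochs Number of gradient steps.
#' @param track_higher_order Keep the pre-step parameter trajectory.
#' @param clip_norm Global gradient-norm clip for each inner step. The
#'   frequency-regression term's `K = 1000` equalizer gives the loss a very
#'   stiff direction through the latent path; clipping keeps plain gradient
#'   descent stable at the protocol's learning rates. Inactive whenever the
#'   gradient norm is below the threshold. `Inf` disables.
#' @return List `(par, trajectory, losses)`; `trajectory[[k]]` is the
#'   parameter vector *before* inner step `k`.
#' @export
inner_adapt <- function(par, model, support, inner_lr, epochs,
                        track_higher_order = FALSE, clip_norm = 100) {
  if (epochs < 1) stop("epochs must be >= 1")
  trajectory <- if (track_higher_order) vector("list", epochs) else NULL
  losses <- numeric(epochs)
  clip_factors <- rep(1, epochs)
  for (k in seq_len(epochs)) {
    if (track_higher_order) trajectory[[k]] <- par
    fg <- model$fn_gr(par, support)
    losses[k] <- fg$loss
    g <- fg$grad
    gn <- sqrt(sum(g^2))
    if (is.finite(clip_norm) && gn > clip_norm) {
      clip_factors[k] <- clip_norm / gn
      g <- g * clip_factors[k]
    }
    par <- par - inner_lr * g
  }
  list(par = par, trajectory = trajectory, losses = losses,
       clip_factors = clip_factors)
}

# Reverse accumulation of the MAML meta-gradient: propagate the query
# gradient back through the inner gradient-descent trajectory,
# v <- (I - lr * c_k * H(theta_k)) v for k = K ... 1, where c_k is the
# gradient-clip factor of step k (treated as a constant of the step).
maml_meta_gradient <- function(model, trajectory, support, inner_lr, qgrad,
                               clip_factors = rep(1, length(trajectory))) {
  v <- qgrad
  for (k in rev(seq_along(trajectory))) {
    v <- v - inner_lr * clip_factors[k] *
      model_hvp(model, trajectory[[k]], support, v)
  }
  v
}

#' One MAML outer step
#'
#' Adapts on the support set, evaluates the query gradient at the adapted
#' parameters, and applies Adam to the initial parameters. `order = 2`
#' differentiates through the inner trajectory (Hessian-vector products);
#' `order = 1` stops gradients at the adapted parameters.
#'
#' @param trainer A trainer state from [meta_trainer()].
#' @param episode An episode from [sample_episode()].
#' @param order 1 or 2.
#' @return The updated trainer.
#' @export
meta_step_maml <- function(trainer, episode, order = 2L) {
  cfg <- trainer$cfg
  ad <- inner_adapt(trainer$par, trainer$model, episode$support,
                    cfg$inner_lr, cfg$epochs_per_episode,
                    track_higher_order = order == 2L,
                    clip_norm = cfg$inner_clip)
  qg <- trainer$model$fn_gr(ad$par, episode$query)$grad
  meta_grad <- if (order == 2L) {
    maml_meta_gradient(trainer$model, ad$trajectory, episode$support,
                       cfg$inner_lr, qg, ad$clip_factors)
  } else qg
  meta_grad <- meta_grad + cfg$weight_decay * trainer$par
  up <- adam_update(trainer$adam, trainer$par, meta_grad, cfg$outer_lr,
                    cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
  trainer$par <- up$par
  trainer$adam <- up$state
  trainer
}

#' One Reptile outer step
#'
#' Moves the initialization toward the inner-adapted parameters:
#' `theta <- theta + meta_step * (theta_adapted - theta)`.
#'
#' @inheritParams meta_step_maml
#' @return The updated trainer.
#' @export
meta_step_reptile <- function(trainer, episode) {
  cfg <- trainer$cfg
  ad <- inner_adapt(trainer$par, trainer$model, episode$support,
                    cfg$reptile_inner_lr, cfg$epochs_per_episode,
                    clip_norm = cfg$inner_clip)
  trainer$par <- trainer$par + cfg$reptile_meta_step * (ad$par - trainer$par)
  trainer
}

#' Cosine-annealed outer learning rate
#'
#' @param episode_index 0-based episode index.
#' @param episodes Total episodes.
#' @param lr0 Initial rate.
#' @param floor_frac Floor as a fraction of `lr0`.
#' @return Learning rate for this episode.
#' @export
cosine_annealed_lr <- function(episode_index, episodes, lr0,
                               floor_frac = 0.01) {
  floor_lr <- lr0 * floor_frac
  frac <- if (episodes <= 1) episode_index else
    episode_index / (episodes - 1)
  floor_lr + 0.5 * (lr0 - floor_lr) * (1 + cos(pi * min(max(frac, 0), 1)))
}

#' Multi-step loss weights
#'
#' Annealed from uniform over the inner steps toward final-step-only as
#' training progresses.
#'
#' @param epochs Inner steps per episode.
#' @param progress Training progress in [0, 1].
#' @return Weight vector of length `epochs`, summing to 1.
#' @export
msl_weights <- function(epochs, progress) {
  progress <- min(max(progress, 0), 1)
  w <- (1 - progress) * rep(1 / epochs, epochs)
  w[epochs] <- w[epochs] + progress
  w
}

#' One stabilized-MAML outer step
#'
#' Combines multi-step loss (the outer objective is a weighted sum of query
#' losses after each inner epoch, weights annealed from uniform toward
#' final-step-only), derivative-order annealing (first-order until a fraction
#' of the episodes, second-order after), and cosine annealing of the outer
#' learning rate.
#'
#' @inheritParams meta_step_maml
#' @param episode_index 0-based episode index (drives the annealing
#'   schedules).
#' @return The updated trainer.
#' @export
meta_step_mamlplus <- function(trainer, episode, episode_index) {
  cfg <- trainer$cfg
  progress <- if (cfg$episodes <= 1) 1 else episode_index / (cfg$episodes - 1)
  second_order <- progress >= cfg$mamlplus_da_fraction
  K <- cfg$epochs_per_episode
  w <- msl_weights(K, progress)

  ad <- inner_adapt(trainer$par, trainer$model, episode$support,
                    cfg$inner_lr, K, track_higher_order = TRUE,
                    clip_norm = cfg$inner_clip)
  thetas <- c(ad$trajectory[-1], list(ad$par))  # theta after step k

  if (second_order) {
    carry <- numeric(length(trainer$par))
    for (k in rev(seq_len(K))) {
      carry <- carry + w[k] * trainer$model$fn_gr(thetas[[k]], episode$query)$grad
      carry <- carry - cfg$inner_lr * ad$clip_factors[k] *
        model_hvp(trainer$model, ad$trajectory[[k]], episode$support, carry)
    }
    meta_grad <- carry
  } else {
    meta_grad <- numeric(length(trainer$par))
    for (k in seq_len(K)) {
      meta_grad <- meta_grad +
        w[k] * trainer$model$fn_gr(thetas[[k]], episode$query)$grad
    }
  }
  meta_grad <- meta_grad + cfg$weight_decay * trainer$par
  lr <- cosine_annealed_lr(episode_index, cfg$episodes,
                           cfg$mamlplus_outer_lr0, cfg$mamlplus_lr_floor_frac)
  up <- adam_update(trainer$adam, trainer$par, meta_grad, lr,
                    cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
  trainer$par <- up$par
  trainer$adam <- up$state
  trainer
}

#' Construct a trainer state
#'
#' @param model A meta-model.
#' @param cfg A [meta_config()].
#' @return A trainer list (`par`, `adam`, `model`, `cfg`).
#' @export
meta_trainer <- function(model, cfg = meta_config()) {
  list(par = model$par0, adam = adam_state(length(model$par0)),
       model = model, cfg = cfg)
}

#' Adapt a trained model to a new user
#'
#' First-order gradient descent (4 epochs by default, per the training
#' protocol) on the mean L* over the `k` support sessions, starting from the
#' meta-learned parameters. The input checkpoint is left untouched; with an
#' empty support set it is returned unchanged.
#'
#' @param par Flat meta-learned parameter vector (the checkpoint).
#' @param model A meta-model.
#' @param support Support samples for the new user.
#' @param inner_lr Learning rate.
#' @param epochs Adaptation epochs.
#' @param clip_norm Gradient-norm clip per adaptation step. Large enough to
#'   let the stiff frequency term move the prediction within four epochs,
#'   small enough that the reconstruction pathway does not overfit a single
#'   support session.
#' @return The adapted flat parameter vector.
#' @export
adapt_to_user <- function(par, model, support, inner_lr = 1.8e-3,
                          epochs = 4L, clip_norm = 20) {
  if (!length(support)) return(par)
  inner_adapt(par, model, support, inner_lr, epochs,
              clip_norm = clip_norm)$par
}

#' Episodic meta-training loop
#'
#' Runs `cfg$episodes` episodes of the configured algorithm. Every
#' `cfg$eval_every` episodes the current initialization is evaluated on two
#' training tasks and one test task: for each, a fresh support set is drawn,
#' the model is adapted first-order (the meta-parameters themselves are never
#' mutated by evaluation), and the per-example query losses are summarized as
#' box-plot statistics.
#'
#' @param tasks A task bank from [prepare_meta_tasks()].
#' @param model A meta-model.
#' @param cfg A [meta_config()].
#' @param seed Master seed; every episode and evaluation derives its own
#'   stream from it.
#' @param eval_fixed_tasks If `TRUE`, every evaluation point re-uses the same
#'   evaluation tasks (same users, support and query sessions), turning the
#'   learning curve into a paired comparison. Recommended for short scaled
#'   runs, where freshly sampled evaluation tasks would swamp the trend with
#'   between-task variance; the full protocol samples fresh tasks.
#' @return List `(par, eval_log, cfg)`; `eval_log` is a data frame with one
#'   row per evaluated task per evaluation point (episode, split, median,
#'   q1, q3, whisker_lo, whisker_hi, mean).
#' @export
train_meta <- function(tasks, model, cfg = meta_config(), seed = 1,
                       eval_fixed_tasks = FALSE) {
  set.seed(seed)
  ep_seeds <- sample.int(2^31 - 1, max(cfg$episodes, 1))
  ev_seeds <- sample.int(2^31 - 1, max(cfg$episodes, 1) + 1)
  if (eval_fixed_tasks) ev_seeds[] <- ev_seeds[1]
  trainer <- meta_trainer(model, cfg)
  log_rows <- list()

  for (ep in seq_len(cfg$episodes)) {
    episode <- sample_episode(tasks, cfg$shots, ep_seeds[ep],
                              query_size = cfg$query_size)
    trainer <- switch(cfg$algorithm,
      maml2 = meta_step_maml(trainer, episode, order = 2L),
      maml1 = meta_step_maml(trainer, episode, order = 1L),
      reptile = meta_step_reptile(trainer, episode),
      mamlplus = meta_step_mamlplus(trainer, episode, ep - 1L))

    if (cfg$eval_every > 0 && ep %% cfg$eval_every == 0) {
      log_rows[[length(log_rows) + 1L]] <-
        evaluate_tasks(trainer, tasks, ep, ev_seeds[ep])
    }
  }
  eval_log <- if (length(log_rows)) do.call(rbind, log_rows) else NULL
  list(par = trainer$par, eval_log = eval_log, cfg = cfg)
}

# Evaluation loop: two training tasks and one test task; adaptation happens
# on a copy of the parameters, never the meta-parameters themselves.
evaluate_tasks <- function(trainer, tasks, episode_num, seed) {
  cfg <- trainer$cfg
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, 3)
  specs <- list(c("train", "train_task"), c("train", "train_task"),
                c("test", "test_task"))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    split <- specs[[i]][1]
    if (!any(tasks$splits == split)) next
    ev <- sample_episode(tasks, cfg$shots, sub_seeds[i],
                         query_size = cfg$eval_examples, split = split,
                         support_policy = "least_corrupted")
    par_ad <- adapt_to_user(trainer$par, trainer$model, ev$support,
                            inner_lr = cfg$inner_lr,
                            epochs = cfg$epochs_per_episode)
    losses <- vapply(ev$query, function(s) {
      trainer$model$fn_gr(par_ad, list(s))$loss
    }, numeric(1))
    st <- boxplot_stats(losses)
    rows[[i]] <- data.frame(episode = episode_num, split = specs[[i]][2],
                            median = st$median, q1 = st$q1, q3 = st$q3,
                            whisker_lo = st$whisker_lo,
                            whisker_hi = st$whisker_hi, mean = st$mean,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Build a task bank from simulated sessions
#'
#' Runs the full preprocessing chain on each session: phase extraction,
#' belt resampling and [0, 1] normalization, belt-spectrum frequency
#' labeling, and corruption weighting of the band-passed radar phase. The
#' result groups per-session training triples by user.
#'
#' @param sessions List of `session_record`s (or file paths).
#' @param splits Character vector (`"train"`/`"test"`) per *user*, named by
#'   user id; alternatively a manifest data frame with `user_id` and `split`.
#' @param cfg A [radar_config()].
#' @param latent_dim Latent dimension used to draw per-episode latent noise;
#'   0 disables noise (deterministic code).
#' @param target_frames Session length after resampling.
#' @return A task bank: list with `users` (named list of sample lists),
#'   `splits` (named character vector), `latent_dim`.
#' @export
prepare_meta_tasks <- function(sessions, splits, cfg = radar_config(),
                               latent_dim = 0L, target_frames = 660L) {
  if (is.data.frame(splits)) {
    sp <- splits$split[!duplicated(splits$user_id)]
    names(sp) <- splits$user_id[!duplicated(splits$user_id)]
    splits <- sp
  }
  users <- list()
  for (s in sessions) {
    rec <- if (is.character(s)) read_session(s) else s
    rec <- resample_session(rec, target_frames)
    fs <- rec$frame_rate
    trace <- extract_phase_trace(rec, cfg, target_frames = target_frames)
    rng <- range(rec$belt)
    x_belt <- if (rng[2] > rng[1]) (rec$belt - rng[1]) / (rng[2] - rng[1]) else
      rep(0.5, length(rec$belt))
    y <- belt_fc_reference(rec$belt, fs)$fc
    bm <- breath_metrics(trace$x, fs, fc = y)
    sample <- list(x = trace$x, x_belt = x_belt, y = y,
                   tau = bm$tau, gamma = bm$corruption_fraction, eta = NULL)
    users[[rec$user_id]] <- c(users[[rec$user_id]], list(sample))
  }
  user_ids <- names(users)
  sp <- splits[user_ids]
  sp[is.na(sp)] <- "train"
  names(sp) <- user_ids
  list(users = users, splits = sp, latent_dim = as.integer(latent_dim))
}
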