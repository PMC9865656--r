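test_that("inner adaptation performs plain gradient descent", {
  mm <- quartic_meta_model(4L)
  task <- mm$make_task(1)
  task$lambda <- 0                       # pure quadratic
  par0 <- c(1, -1, 0.5, 2)

  ad <- inner_adapt(par0, mm, list(task), inner_lr = 0, epochs = 3)
  expect_identical(ad$par, par0)

  # one step moves theta by lr * (A theta - b), the closed form
  lr <- 0.05
  ad1 <- inner_adapt(par0, mm, list(task), lr, epochs = 1)
  expect_equal(ad1$par, par0 - lr * (as.vector(task$A %*% par0) - task$b))

  # at the optimum the gradient vanishes and nothing moves
  opt <- solve(task$A, task$b)
  ad2 <- inner_adapt(opt, mm, list(task), lr, epochs = 5)
  expect_equal(ad2$par, opt, tolerance = 1e-10)

  expect_error(inner_adapt(par0, mm, list(task), lr, epochs = 0), "epochs")
})

test_that("the second-order meta-gradient matches a finite-difference
           oracle on the toy family", {
  mm <- quartic_meta_model(10L)
  support <- list(mm$make_task(1), mm$make_task(2))
  query <- list(mm$make_task(3))
  set.seed(5)
  par0 <- rnorm(10) * 0.5
  lr <- 0.05
  epochs <- 4L

  ad <- inner_adapt(par0, mm, support, lr, epochs, track_higher_order = TRUE)
  qg <- mm$fn_gr(ad$par, query)$grad
  mg <- breathradar:::maml_meta_gradient(mm, ad$trajectory, support, lr, qg,
                                         ad$clip_factors)
  post_loss <- function(p0) {
    mm$fn_gr(inner_adapt(p0, mm, support, lr, epochs)$par, query)$loss
  }
  h <- 1e-6
  fd <- vapply(1:10, function(i) {
    vp <- par0; vp[i] <- vp[i] + h
    vm <- par0; vm[i] <- vm[i] - h
    (post_loss(vp) - post_loss(vm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(mg - fd)) / max(abs(fd)), 1e-3)

  # the finite-difference Hessian-vector fallback agrees with the analytic one
  mm_fd <- mm
  mm_fd$hvp <- NULL
  mg2 <- breathradar:::maml_meta_gradient(mm_fd, ad$trajectory, support, lr,
                                          qg, ad$clip_factors)
  expect_lt(max(abs(mg2 - mg)) / max(abs(mg)), 1e-4)
})

test_that("with a zero inner rate both MAML orders reduce to the plain
           query gradient step", {
  mm <- quartic_meta_model(6L)
  tasks <- list(users = list(a = list(mm$make_task(1), mm$make_task(2),
                                      mm$make_task(3))),
                splits = c(a = "train"), latent_dim = 0L)
  cfg <- meta_config("maml2", episodes = 1L, eval_every = 0L, shots = 1L,
                     inner_lr = 0, weight_decay = 0)
  set.seed(2)
  mm$par0 <- rnorm(6)
  ep <- sample_episode(tasks, 1L, seed = 3)
  t2 <- meta_step_maml(meta_trainer(mm, cfg), ep, order = 2L)
  t1 <- meta_step_maml(meta_trainer(mm, cfg), ep, order = 1L)
  expect_equal(t1$par, t2$par)
  # determinism
  t2b <- meta_step_maml(meta_trainer(mm, cfg), ep, order = 2L)
  expect_identical(t2$par, t2b$par)
})

test_that("Reptile interpolates toward the adapted parameters", {
  mm <- quartic_meta_model(4L)
  tasks <- list(users = list(a = list(mm$make_task(1), mm$make_task(2))),
                splits = c(a = "train"), latent_dim = 0L)
  ep <- sample_episode(tasks, 1L, seed = 1)
  cfg <- meta_config("reptile", episodes = 1L, eval_every = 0L, shots = 1L,
                     reptile_inner_lr = 0)
  tr <- meta_step_reptile(meta_trainer(mm, cfg), ep)
  expect_equal(tr$par, mm$par0)           # adapted == initial -> no movement

  cfg2 <- meta_config("reptile", episodes = 1L, eval_every = 0L, shots = 1L,
                      reptile_inner_lr = 0.05, reptile_meta_step = 1)
  tr2 <- meta_step_reptile(meta_trainer(mm, cfg2), ep)
  ad <- inner_adapt(mm$par0, mm, ep$support, 0.05, cfg2$epochs_per_episode,
                    clip_norm = cfg2$inner_clip)
  expect_equal(tr2$par, ad$par)           # meta step 1 jumps to theta-tilde

  cfg3 <- meta_config("reptile", episodes = 1L, eval_every = 0L, shots = 1L,
                      reptile_inner_lr = 0.05, reptile_meta_step = 0.4)
  tr3 <- meta_step_reptile(meta_trainer(mm, cfg3), ep)
  expect_equal(tr3$par, mm$par0 + 0.4 * (ad$par - mm$par0))
})

test_that("the stabilized-MAML schedules behave at their endpoints", {
  expect_equal(cosine_annealed_lr(0, 100, 1.7e-5, 0.01), 1.7e-5)
  expect_equal(cosine_annealed_lr(99, 100, 1.7e-5, 0.01), 1.7e-7)
  expect_equal(msl_weights(4, 0), rep(0.25, 4))
  expect_equal(msl_weights(4, 1), c(0, 0, 0, 1))
  expect_equal(sum(msl_weights(4, 0.37)), 1)
})

test_that("episode sampling is seeded, disjoint, and uniform over users", {
  mm <- quartic_meta_model(3L)
  mk <- function(n) lapply(seq_len(n), mm$make_task)
  tasks <- list(users = list(a = mk(4), b = mk(4), c = mk(4)),
                splits = c(a = "train", b = "train", c = "train"),
                latent_dim = 0L)
  e1 <- sample_episode(tasks, 2L, seed = 9)
  e2 <- sample_episode(tasks, 2L, seed = 9)
  expect_identical(e1, e2)
  expect_equal(length(e1$support), 2)

  small <- list(users = list(a = mk(2)), splits = c(a = "train"),
                latent_dim = 0L)
  expect_error(sample_episode(small, 2L, seed = 1), "insufficient")

  picks <- vapply(1:2000, function(s) sample_episode(tasks, 1L, s)$task_user,
                  character(1))
  freq <- table(picks) / 2000
  se <- sqrt((1 / 3) * (2 / 3) / 2000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se + 0.01))
})

test_that("a zero-episode run returns the initialization and adaptation
           never mutates its checkpoint", {
  mm <- quartic_meta_model(5L)
  mk <- function(n) lapply(seq_len(n), mm$make_task)
  tasks <- list(users = list(a = mk(3), b = mk(3)),
                splits = c(a = "train", b = "test"), latent_dim = 0L)
  cfg <- meta_config("maml1", episodes = 0L, eval_every = 0L, shots = 1L)
  fit <- train_meta(tasks, mm, cfg, seed = 1)
  expect_identical(fit$par, mm$par0)

  par0 <- mm$par0 + 1
  expect_identical(adapt_to_user(par0, mm, list(), 0.01, 4L), par0)
  adapted <- adapt_to_user(par0, mm, tasks$users$a[1:2], 0.01, 4L)
  expect_identical(par0, mm$par0 + 1)     # input untouched
  adapted2 <- adapt_to_user(par0, mm, tasks$users$a[1:2], 0.01, 4L)
  expect_identical(adapted, adapted2)     # deterministic
})

test_that("meta-training transfers: adaptation from the meta-trained
           checkpoint beats no adaptation and a random initialization", {
  ex <- scaled_fit()
  model <- ex$model
  tasks <- ex$tasks
  rnd <- cvae_meta_model(cvae_init(ex$arch, seed = 991))
  wins_noadapt <- 0L
  wins_random <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    ev <- sample_episode(tasks, 1L, seed = 600 + r, query_size = 5L,
                         split = "test", support_policy = "random")
    la <- mean(vapply(ev$query, function(s) {
      model$fn_gr(adapt_to_user(ex$fit$par, model, ev$support), list(s))$loss
    }, numeric(1)))
    l0 <- mean(vapply(ev$query, function(s) {
      model$fn_gr(ex$fit$par, list(s))$loss
    }, numeric(1)))
    lr <- mean(vapply(ev$query, function(s) {
      model$fn_gr(adapt_to_user(rnd$par0, model, ev$support), list(s))$loss
    }, numeric(1)))
    wins_random <- wins_random + (la < lr)
    wins_noadapt <- wins_noadapt + (la <= l0)
  }
  expect_gt(wins_random, reps / 2)
  expect_gt(wins_noadapt, reps / 2)
})
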