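test_that("parameter counts follow the closed-form audit and are affine in
           the latent dimension", {
  arch <- tiny_arch()
  m <- cvae_init(arch, seed = 1)
  expect_equal(count_parameters(arch),
               length(breathradar:::par_flatten(m$params)))

  counts <- vapply(c(16L, 32L, 64L, 128L), function(d) {
    count_parameters(cvae_architecture(latent_dim = d))
  }, numeric(1))
  # affinity: equal second differences
  expect_equal(counts[3] - counts[2], 2 * (counts[2] - counts[1]))
  expect_equal(counts[4] - counts[3], 2 * (counts[3] - counts[2]))

  # frequency head contributes latent_dim + 1 parameters
  expect_equal(length(m$params$fc_W) + length(m$params$fc_b),
               arch$latent_dim + 1)

  # doubling encoder filters strictly increases the count
  expect_gt(count_parameters(cvae_architecture(enc_filters = c(64L, 128L))),
            count_parameters(cvae_architecture()))

  expect_error(cvae_architecture(input_len = 10L), "divisible")
})

test_that("the analytic backprop matches central finite differences", {
  arch <- tiny_arch()
  m <- cvae_init(arch, seed = 3)
  set.seed(9)
  x <- runif(20); xb <- runif(20); y <- 0.3; eta <- rnorm(3)
  v0 <- breathradar:::par_flatten(m$params)

  for (case in list(list(eta = eta, tau = 0.7, gamma = 0.3),
                    list(eta = NULL, tau = 1, gamma = 1))) {
    lg <- breathradar:::cvae_loss_grad(m$params, arch, x, xb, y,
                                       eta = case$eta, tau = case$tau,
                                       gamma = case$gamma)
    g <- breathradar:::par_flatten(lg$grad)
    fn <- function(v) {
      p <- breathradar:::par_unflatten(v, m$params)
      breathradar:::cvae_loss_grad(p, arch, x, xb, y, eta = case$eta,
                                   tau = case$tau, gamma = case$gamma)$loss
    }
    idx <- sort(sample(length(v0), 50))
    h <- 1e-5
    gfd <- vapply(idx, function(i) {
      vp <- v0; vp[i] <- vp[i] + h
      vm <- v0; vm[i] <- vm[i] - h
      (fn(vp) - fn(vm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g[idx] - gfd) / pmax(abs(gfd), 1e-6)), 1e-4)
  }
})

test_that("encoding is deterministic with correctly shaped output", {
  arch <- tiny_arch()
  m <- cvae_init(arch, seed = 2)
  x <- runif(20)
  e1 <- encode(m, x)
  e2 <- encode(m, x)
  expect_identical(e1, e2)
  expect_length(e1$mu, 3)
  expect_length(e1$sigma, 3)
  expect_true(all(e1$sigma > 0))
  expect_error(encode(m, runif(10)), "length")
})

test_that("the reparameterized draw has the right moments", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), seed = 1), c(1, 2))
  expect_identical(reparameterize(0, 1, seed = 5), reparameterize(0, 1, seed = 5))
  n <- 2e4
  draws <- reparameterize(rep(1.5, n), rep(0.5, n), seed = 7)
  expect_lt(abs(mean(draws) - 1.5), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(draws) - 0.5), 3 * 0.5 / sqrt(2 * n))
  expect_error(reparameterize(0, -1), "non-negative")
})

test_that("decoding and frequency regression have the declared structure", {
  arch <- tiny_arch()
  m <- cvae_init(arch, seed = 4)
  z <- rnorm(3)
  out <- decode(m, z)
  expect_length(out, 20)
  expect_true(all(out > 0 & out < 1))
  # affinity of the frequency head
  expect_equal(regress_fc(m, 2 * z) - regress_fc(m, z),
               regress_fc(m, 3 * z) - regress_fc(m, 2 * z))
  # zero-weight head returns the bias for any z
  m0 <- m
  m0$params$fc_W[] <- 0
  expect_equal(regress_fc(m0, z), m0$params$fc_b)
  expect_equal(regress_fc(m0, 10 * z), m0$params$fc_b)
})

test_that("the loss terms match their closed forms", {
  expect_equal(bce_term(rep(0.5, 660), rep(0.5, 660)), 660 * log(2))
  expect_lt(bce_term(c(0, 1), c(0, 1)), 1e-5)
  set.seed(12)
  a <- runif(100); b <- runif(100)
  manual <- sum(vapply(seq_along(a), function(i) {
    h <- min(max(a[i], 1e-7), 1 - 1e-7)
    -b[i] * log(h) - (1 - b[i]) * log(1 - h)
  }, numeric(1)))
  expect_equal(bce_term(a, b), manual, tolerance = 1e-9)
  expect_error(bce_term(a, b[1:10]), "mismatch")

  expect_equal(kl_term(rep(0, 32), rep(1, 32)), 0)
  expect_equal(kl_term(rep(1, 32), rep(1, 32)), 16)
  set.seed(13)
  for (r in 1:200) {
    mu <- rnorm(8); sg <- exp(rnorm(8))
    expect_gte(kl_term(mu, sg), 0)
  }
  expect_error(kl_term(0, 0), "sigma")
})

test_that("L and L* reduce to their stated forms", {
  out <- structure(list(x_hat_belt = rep(0.4, 660), mu = rep(0.5, 4),
                        sigma = rep(1.2, 4), z = rep(0.5, 4), y_hat = 0.25),
                   class = "cvae_output")
  xb <- rep(0.6, 660)
  l <- loss_L(out, xb, 0.35)
  expect_equal(l$total, l$bce + l$kl + 1000 * (0.35 - 0.25)^2)
  expect_equal(1000 * l$mse_fc, 10)

  l_match <- loss_L(out, xb, 0.25)
  expect_equal(l_match$total, l_match$bce + l_match$kl)

  ls <- loss_Lstar(out, xb, 0.35, tau = 1, gamma = 0)
  expect_equal(ls$total, ls$bce + ls$kl)
  ls2 <- loss_Lstar(out, xb, 0.35, tau = 0, gamma = 1)
  expect_equal(ls2$total, ls2$kl + 1000 * ls2$mse_fc)
  ls3 <- loss_Lstar(out, xb, 0.35, tau = 0.5, gamma = 0.5)
  expect_equal(ls3$total, 0.5 * ls3$bce + ls3$kl + 0.5 * 1000 * ls3$mse_fc)

  expect_error(loss_Lstar(out, xb, 0.35, tau = 0.7, gamma = 0.7), "equal 1")
})

test_that("the fusion estimator is the stated convex-like combination", {
  set.seed(14)
  xhat <- runif(660)
  x <- runif(660)
  expect_identical(fuse_prediction(xhat, x, 0.3, tau = 1, gamma = 0), xhat)
  filt <- apply_cascade(x, 0.3, q = 2, fs = 20)
  expect_equal(fuse_prediction(xhat, x, 0.3, tau = 0, gamma = 1), filt)
  expect_equal(fuse_prediction(xhat, x, 0.3, tau = 0.5, gamma = 0.5, eps = 2),
               (0.5 * xhat + 1.0 * filt) / 1.5)
  # bounded by the envelope of its two inputs
  fused <- fuse_prediction(xhat, x, 0.3, tau = 0.6, gamma = 0.4)
  expect_true(all(fused <= pmax(xhat, filt) + 1e-12))
  expect_true(all(fused >= pmin(xhat, filt) - 1e-12))
  expect_error(fuse_prediction(xhat, x, 15, tau = 0.5, gamma = 0.5),
               "filter-design")
})

test_that("200 optimizer steps on one triple cut the loss by half", {
  arch <- small_arch()
  meta <- cvae_meta_model(cvae_init(arch, seed = 1))
  t <- (0:659) / 22
  x <- (sin(2 * pi * 0.3 * t) + 1) / 2
  xb <- (sin(2 * pi * 0.3 * t + 0.5) + 1) / 2
  s <- list(x = x, x_belt = xb, y = 0.3, tau = 1, gamma = 1, eta = NULL)
  par <- meta$par0
  st <- breathradar:::adam_state(length(par))
  l0 <- meta$fn_gr(par, list(s))$loss
  for (i in 1:200) {
    fg <- meta$fn_gr(par, list(s))
    up <- breathradar:::adam_update(st, par, fg$grad, 1.7e-3, 0, 0.5)
    par <- up$par; st <- up$state
  }
  l1 <- meta$fn_gr(par, list(s))$loss
  expect_lt(l1, 0.5 * l0)
})
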