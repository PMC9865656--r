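#' C-VAE architecture description
#'
#' Convolutional variational autoencoder mapping a normalized radar phase
#' trace to the reference belt signal, with a central-frequency regression
#' head on the latent code. Encoder: two strided convolutional blocks (ReLU);
#' flatten; dense heads for the latent mean and log-variance. Decoder: dense
#' projection of `z`, reshape, and two deconvolution blocks (nearest-neighbor
#' up-sampling followed by convolution, mirroring the encoder), ending in a
#' sigmoid so the reconstruction lies in (0, 1). The frequency head is a
#' single linear unit on `z`.
#'
#' @param input_len Input length (default 660 samples, one session).
#' @param latent_dim Latent dimensionality (default 32).
#' @param enc_filters Channel counts of the two encoder blocks.
#' @param kernel Convolution kernel length.
#' @param stride Encoder stride per block (the decoder up-samples by the same
#'   factor).
#' @return An object of class `cvae_architecture`.
#' @export
cvae_architecture <- function(input_len = 660L, latent_dim = 32L,
                              enc_filters = c(32L, 64L), kernel = 5L,
                              stride = 2L) {
  if (length(enc_filters) != 2) stop("exactly two encoder blocks are supported")
  if (input_len %% stride^2 != 0) {
    stop("input_len must be divisible by stride^2 so the decoder mirrors ",
         "the encoder exactly")
  }
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  mid_len <- input_len %/% stride^2
  structure(list(input_len = as.integer(input_len),
                 latent_dim = as.integer(latent_dim),
                 enc_filters = as.integer(enc_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 mid_len = as.integer(mid_len),
                 flat = as.integer(mid_len * enc_filters[2])),
            class = "cvae_architecture")
}

#' Trainable parameter count of an architecture
#'
#' Closed-form audit of all layer sizes. The count is affine in the latent
#' dimension for a fixed convolutional backbone: each additional latent unit
#' adds two dense-head rows, one decoder-projection column, and one frequency
#' head weight.
#'
#' @param arch A [cvae_architecture()].
#' @return Total number of trainable parameters.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "cvae_architecture"))
  k <- arch$kernel; f1 <- arch$enc_filters[1]; f2 <- arch$enc_filters[2]
  d <- arch$latent_dim; flat <- arch$flat
  f1 * (k * 1 + 1) +          # encoder conv 1
    f2 * (k * f1 + 1) +       # encoder conv 2
    2 * d * (flat + 1) +      # mu and log-variance heads
    flat * (d + 1) +          # decoder dense projection
    f1 * (k * f2 + 1) +       # decoder conv 1
    1 * (k * f1 + 1) +        # decoder conv 2
    (d + 1)                   # frequency head
}

#' Initialize a C-VAE model
#'
#' Glorot-uniform weights, zero biases; deterministic given `seed`.
#'
#' @param arch A [cvae_architecture()].
#' @param seed Integer seed.
#' @return An object of class `cvae`: list with `arch` and `params` (named
#'   list of weight arrays).
#' @export
cvae_init <- function(arch = cvae_architecture(), seed = 1) {
  stopifnot(inherits(arch, "cvae_architecture"))
  set.seed(seed)
  k <- arch$kernel; f1 <- arch$enc_filters[1]; f2 <- arch$enc_filters[2]
  d <- arch$latent_dim; flat <- arch$flat
  params <- list(
    enc1_W = matrix(glorot(k, f1, k * f1), k, f1),
    enc1_b = numeric(f1),
    enc2_W = matrix(glorot(k * f1, f2, k * f1 * f2), k * f1, f2),
    enc2_b = numeric(f2),
    mu_W = matrix(glorot(flat, d, flat * d), d, flat),
    mu_b = numeric(d),
    lv_W = matrix(glorot(flat, d, flat * d), d, flat),
    lv_b = numeric(d),
    dec_W = matrix(glorot(d, flat, flat * d), flat, d),
    dec_b = numeric(flat),
    dec1_W = matrix(glorot(k * f2, f1, k * f2 * f1), k * f2, f1),
    dec1_b = numeric(f1),
    dec2_W = matrix(glorot(k * f1, 1, k * f1), k * f1, 1),
    dec2_b = numeric(1),
    fc_W = numeric(d),
    fc_b = numeric(1)
  )
  structure(list(arch = arch, params = params), class = "cvae")
}

#' @export
print.cvae <- function(x, ...) {
  cat(sprintf("<cvae> input %d, latent %d, filters %s, %d parameters\n",
              x$arch$input_len, x$arch$latent_dim,
              paste(x$arch$enc_filters, collapse = "/"),
              count_parameters(x$arch)))
  invisible(x)
}

LOGVAR_CLAMP <- 10

cvae_forward_full <- function(params, arch, x, eta = NULL) {
  if (length(x) != arch$input_len) {
    stop("input length ", length(x), " != ", arch$input_len)
  }
  k <- arch$kernel; s <- arch$stride
  X0 <- matrix(x, ncol = 1)
  c1 <- conv1d_forward(X0, params$enc1_W, params$enc1_b, k, s)
  A1 <- relu(c1$Y)
  c2 <- conv1d_forward(A1, params$enc2_W, params$enc2_b, k, s)
  A2 <- relu(c2$Y)
  h <- as.vector(A2)
  mu <- as.vector(params$mu_W %*% h) + params$mu_b
  lv_raw <- as.vector(params$lv_W %*% h) + params$lv_b
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  sigma <- exp(0.5 * lv)
  z <- if (is.null(eta)) mu else mu + sigma * eta
  hd_pre <- as.vector(params$dec_W %*% z) + params$dec_b
  hd <- relu(hd_pre)
  D0 <- matrix(hd, arch$mid_len, arch$enc_filters[2])
  U1 <- upsample2_forward(D0)
  c3 <- conv1d_forward(U1, params$dec1_W, params$dec1_b, k, 1L)
  A3 <- relu(c3$Y)
  U2 <- upsample2_forward(A3)
  c4 <- conv1d_forward(U2, params$dec2_W, params$dec2_b, k, 1L)
  logits <- as.vector(c4$Y)
  xhat <- sigmoid(logits)
  yhat <- sum(params$fc_W * z) + params$fc_b
  list(xhat = xhat, mu = mu, sigma = sigma, lv = lv, lv_raw = lv_raw, z = z,
       y_hat = yhat, logits = logits,
       cache = list(c1 = c1, A1 = A1, c2 = c2, A2 = A2, h = h,
                    hd_pre = hd_pre, hd = hd, c3 = c3, A3 = A3, c4 = c4,
                    eta = eta, X0 = X0))
}

#' Run the C-VAE on one phase trace
#'
#' @param model A [cvae_init()] model.
#' @param x Normalized phase trace of length `input_len`, values in [0, 1].
#' @param eta Optional standard-normal vector (length `latent_dim`) for the
#'   reparameterized latent draw; `NULL` uses the deterministic code `z = mu`.
#' @return An object of class `cvae_output`: `x_hat_belt`, `mu`, `sigma`,
#'   `z`, `y_hat`.
#' @export
cvae_predict <- function(model, x, eta = NULL) {
  stopifnot(inherits(model, "cvae"))
  fw <- cvae_forward_full(model$params, model$arch, x, eta)
  structure(list(x_hat_belt = fw$xhat, mu = fw$mu, sigma = fw$sigma,
                 z = fw$z, y_hat = fw$y_hat),
            class = "cvae_output")
}

#' Encode a phase trace to its latent Gaussian
#'
#' @inheritParams cvae_predict
#' @return List `(mu, sigma)`, each of length `latent_dim`; `sigma` is
#'   derived from a clamped log-variance head, hence strictly positive.
#' @export
encode <- function(model, x) {
  fw <- cvae_forward_full(model$params, model$arch, x)
  list(mu = fw$mu, sigma = fw$sigma)
}

#' Reparameterized latent draw
#'
#' `z = mu + sigma * eta` with `eta ~ N(0, I)`, seeded.
#'
#' @param mu,sigma Latent mean and standard deviation (`sigma > 0`).
#' @param seed Integer seed.
#' @return Latent sample `z`.
#' @export
reparameterize <- function(mu, sigma, seed = 1) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  set.seed(seed)
  mu + sigma * stats::rnorm(length(mu))
}

#' Decode a latent code to a belt-signal reconstruction
#'
#' @param model A `cvae` model.
#' @param z Latent vector of length `latent_dim`.
#' @return Reconstruction of length `input_len`, values in (0, 1).
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "cvae"))
  arch <- model$arch; params <- model$params
  if (length(z) != arch$latent_dim) stop("z has wrong length")
  hd <- relu(as.vector(params$dec_W %*% z) + params$dec_b)
  D0 <- matrix(hd, arch$mid_len, arch$enc_filters[2])
  c3 <- conv1d_forward(upsample2_forward(D0), params$dec1_W, params$dec1_b,
                       arch$kernel, 1L)
  c4 <- conv1d_forward(upsample2_forward(relu(c3$Y)), params$dec2_W,
                       params$dec2_b, arch$kernel, 1L)
  sigmoid(as.vector(c4$Y))
}

#' Regress the central frequency from a latent code
#'
#' Affine (single linear unit): `y_hat = fc_W . z + fc_b`.
#'
#' @inheritParams decode
#' @return Predicted central frequency in Hz.
#' @export
regress_fc <- function(model, z) {
  stopifnot(inherits(model, "cvae"))
  if (length(z) != model$arch$latent_dim) stop("z has wrong length")
  sum(model$params$fc_W * z) + model$params$fc_b
}

#' Binary cross-entropy reconstruction term
#'
#' Element-wise `-ref * log(hat) - (1 - ref) * log(1 - hat)`, summed over the
#' samples; `hat` is clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param x_hat Prediction in [0, 1].
#' @param x_ref Target in [0, 1].
#' @return Scalar BCE (summed, not averaged).
#' @export
bce_term <- function(x_hat, x_ref) {
  if (length(x_hat) != length(x_ref)) stop("length mismatch")
  h <- pmin(pmax(x_hat, 1e-7), 1 - 1e-7)
  sum(-x_ref * log(h) - (1 - x_ref) * log(1 - h))
}

#' Kullback-Leibler term toward N(0, 1)
#'
#' `sum_d 0.5 * (mu_d^2 + sigma_d^2 - 1 - 2 log sigma_d)`, the closed form of
#' `KL[N(mu, sigma) || N(0, 1)]` per latent dimension, summed.
#'
#' @param mu,sigma Latent mean and standard deviation (`sigma > 0`).
#' @return Scalar KL divergence (non-negative).
#' @export
kl_term <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sum(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma)))
}

new_loss_terms <- function(bce, kl, mse_fc, K, tau, gamma, eps_fusion = 2) {
  structure(list(bce = bce, kl = kl, mse_fc = mse_fc, k_coeff = K,
                 tau = tau, gamma = gamma,
                 total = tau * bce + kl + gamma * K * mse_fc,
                 eps_fusion = eps_fusion),
            class = "loss_terms")
}

#' Training loss L
#'
#' `L = BCE(x_hat_belt, x_belt) + KL + K * (y - y_hat)^2` with `K = 1000`
#' equalizing the magnitude of the frequency term.
#'
#' @param out A `cvae_output`.
#' @param x_belt Normalized belt target in [0, 1].
#' @param y Reference central frequency, Hz.
#' @param K Equalization coefficient.
#' @return A `loss_terms` object; `total` holds L.
#' @export
loss_L <- function(out, x_belt, y, K = 1000) {
  stopifnot(inherits(out, "cvae_output"))
  # unweighted form: both the reconstruction and the frequency term at
  # full weight
  new_loss_terms(bce_term(out$x_hat_belt, x_belt),
                 kl_term(out$mu, out$sigma),
                 (y - out$y_hat)^2, K, tau = 1, gamma = 1)
}

#' Corruption-weighted training loss L*
#'
#' `L* = tau * BCE + KL + gamma * K * (y - y_hat)^2`: the more corrupted the
#' session (larger `gamma`), the more weight shifts from reconstructing the
#' belt signal to regressing the central frequency.
#'
#' @inheritParams loss_L
#' @param tau,gamma Corruption weights with `tau + gamma = 1`, both in [0, 1].
#' @return A `loss_terms` object; `total` holds L*.
#' @export
loss_Lstar <- function(out, x_belt, y, tau, gamma, K = 1000) {
  stopifnot(inherits(out, "cvae_output"))
  if (tau < 0 || tau > 1 || gamma < 0 || gamma > 1) {
    stop("tau and gamma must lie in [0, 1]")
  }
  if (abs(tau + gamma - 1) > 1e-8) stop("tau + gamma must equal 1")
  new_loss_terms(bce_term(out$x_hat_belt, x_belt),
                 kl_term(out$mu, out$sigma),
                 (y - out$y_hat)^2, K, tau = tau, gamma = gamma)
}

#' Corruption-weighted fusion of the two breathing estimates
#'
#' Combines the C-VAE reconstruction with the phase trace band-pass filtered
#' at the predicted central frequency:
#' `x_star = (tau * x_hat_belt + gamma * eps * biquad(x, y_hat)) /
#' (tau + gamma * eps)`. With `eps = 2` the filtered-phase branch dominates
#' under motion corruption; at `gamma = 0` the reconstruction is returned
#' unchanged, at `tau = 0` the filtered phase.
#'
#' @param x_hat_belt C-VAE reconstruction (length 660).
#' @param x Phase trace (`phase_trace` or numeric vector).
#' @param y_hat Predicted central frequency, Hz.
#' @param tau,gamma Corruption weights, `tau + gamma = 1`.
#' @param eps Fusion emphasis for the filtered branch.
#' @param q,fs Filter parameters for the biquad cascade.
#' @return Fused breathing estimate, same length as `x_hat_belt`.
#' @export
fuse_prediction <- function(x_hat_belt, x, y_hat, tau, gamma, eps = 2,
                            q = 2, fs = 20) {
  if (abs(tau + gamma - 1) > 1e-8) stop("tau + gamma must equal 1")
  xv <- if (inherits(x, "phase_trace")) x$x else x
  if (gamma == 0) return(x_hat_belt)
  if (y_hat <= 0 || y_hat >= fs / 2) {
    stop("filter-design error: predicted fc ", signif(y_hat, 4),
         " Hz outside (0, ", fs / 2, ")")
  }
  filtered <- apply_cascade(xv, y_hat, q = q, fs = fs)
  (tau * x_hat_belt + gamma * eps * filtered) / (tau + gamma * eps)
}

# Loss + full analytic gradient of L* for one sample. `eta = NULL` uses the
# deterministic code z = mu. Returns list(loss, parts, grad) with grad a
# named list shaped like `params`.
cvae_loss_grad <- function(params, arch, x, x_belt, y, eta = NULL,
                           tau = 1, gamma = 0, K = 1000) {
  fw <- cvae_forward_full(params, arch, x, eta)
  ca <- fw$cache
  bce <- bce_term(fw$xhat, x_belt)
  kl <- kl_term(fw$mu, fw$sigma)
  mse <- (y - fw$y_hat)^2
  loss <- tau * bce + kl + gamma * K * mse

  g <- lapply(params, function(p) { p[] <- 0; p })

  # reconstruction head (BCE + sigmoid collapse on the logits)
  dlogits <- matrix(tau * (fw$xhat - x_belt), ncol = 1)
  b4 <- conv1d_backward(dlogits, ca$c4$cache)
  g$dec2_W <- b4$dW; g$dec2_b <- b4$db
  dA3 <- upsample2_backward(b4$dX)
  dA3 <- dA3 * (ca$c3$Y > 0)
  b3 <- conv1d_backward(dA3, ca$c3$cache)
  g$dec1_W <- b3$dW; g$dec1_b <- b3$db
  dD0 <- upsample2_backward(b3$dX)
  dhd <- as.vector(dD0) * (ca$hd_pre > 0)
  g$dec_W <- dhd %o% fw$z
  g$dec_b <- dhd
  dz <- as.vector(crossprod(params$dec_W, dhd))

  # frequency head
  dyhat <- gamma * K * 2 * (fw$y_hat - y)
  g$fc_W <- dyhat * fw$z
  g$fc_b <- dyhat
  dz <- dz + dyhat * params$fc_W

  # latent heads: KL plus the reparameterized path
  dmu <- fw$mu + dz
  dlv <- 0.5 * (fw$sigma^2 - 1)
  if (!is.null(eta)) dlv <- dlv + dz * eta * 0.5 * fw$sigma
  clamp_open <- fw$lv_raw > -LOGVAR_CLAMP & fw$lv_raw < LOGVAR_CLAMP
  dlv <- dlv * clamp_open

  g$mu_W <- dmu %o% ca$h
  g$mu_b <- dmu
  g$lv_W <- dlv %o% ca$h
  g$lv_b <- dlv
  dh <- as.vector(crossprod(params$mu_W, dmu)) +
    as.vector(crossprod(params$lv_W, dlv))

  dA2 <- matrix(dh, arch$mid_len, arch$enc_filters[2]) * (ca$c2$Y > 0)
  b2 <- conv1d_backward(dA2, ca$c2$cache)
  g$enc2_W <- b2$dW; g$enc2_b <- b2$db
  dA1 <- b2$dX * (ca$c1$Y > 0)
  b1 <- conv1d_backward(dA1, ca$c1$cache)
  g$enc1_W <- b1$dW; g$enc1_b <- b1$db

  list(loss = loss, parts = list(bce = bce, kl = kl, mse_fc = mse),
       grad = g, y_hat = fw$y_hat)
}
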