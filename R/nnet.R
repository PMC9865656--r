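# Minimal 1-D neural-network primitives with manual backpropagation.
# Everything operates on plain matrices: a feature map is L x C (time x
# channels), conv weights are (k * C_in) x C_out with rows ordered
# (channel-major, tap-minor): row index = (ch - 1) * k + tap.

conv1d_forward <- function(X, W, b, k, stride) {
  L <- nrow(X); cin <- ncol(X)
  out_len <- as.integer(ceiling(L / stride))
  pad_total <- max(0L, (out_len - 1L) * stride + k - L)
  pl <- pad_total %/% 2L
  pr <- pad_total - pl
  Xp <- rbind(matrix(0, pl, cin), X, matrix(0, pr, cin))
  starts <- (seq_len(out_len) - 1L) * stride + 1L
  Xcol <- matrix(0, out_len, k * cin)
  for (ch in seq_len(cin)) {
    for (tap in seq_len(k)) {
      Xcol[, (ch - 1L) * k + tap] <- Xp[starts + tap - 1L, ch]
    }
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = out_len)
  list(Y = Y, cache = list(Xcol = Xcol, W = W, k = k, stride = stride,
                           L = L, cin = cin, pl = pl, Lp = nrow(Xp),
                           starts = starts))
}

conv1d_backward <- function(dY, cache) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, cache$W)
  dXp <- matrix(0, cache$Lp, cache$cin)
  for (ch in seq_len(cache$cin)) {
    for (tap in seq_len(cache$k)) {
      rows <- cache$starts + tap - 1L
      dXp[rows, ch] <- dXp[rows, ch] + dXcol[, (ch - 1L) * cache$k + tap]
    }
  }
  dX <- dXp[(cache$pl + 1L):(cache$pl + cache$L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

upsample2_forward <- function(X) {
  X[rep(seq_len(nrow(X)), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(dY) {
  L <- nrow(dY) %/% 2L
  dY[2L * seq_len(L) - 1L, , drop = FALSE] + dY[2L * seq_len(L), , drop = FALSE]
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# Flatten a named list of numeric arrays to one vector and back.
par_flatten <- function(params) unlist(params, use.names = FALSE)

par_unflatten <- function(v, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    out[[nm]][] <- v[pos + seq_len(n)]
    pos <- pos + n
  }
  if (pos != length(v)) stop("parameter vector length mismatch")
  out
}
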