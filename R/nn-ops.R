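# Low-level differentiable operations for the classifier.
#
# Tensors are numeric arrays laid out (H, W, C, N) -- column-major friendly.
# Every op returns list(out, cache) from its forward and list(dx, d<param>...)
# from its backward; gradients are exact (verified against finite differences
# in the test suite). Stride is fixed at 1 with same-padding: the input
# matrices are small (15 x 30) and the network never downsamples.

nn_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  xp
}

# im2col: (Hp, Wp, C, N) -> matrix (k*k*C) x (H*W*N)
# The gather index depends only on the shape, so it is memoised: one
# vectorised subset replaces per-call aperm/reshape traffic.
.im2col_cache <- new.env(parent = emptyenv())

nn_im2col_index <- function(Hp, Wp, C, N, k, H, W) {
  key <- paste(Hp, Wp, C, N, k, H, W, sep = "_")
  idx <- .im2col_cache[[key]]
  if (is.null(idx)) {
    Hp <- as.integer(Hp); Wp <- as.integer(Wp); C <- as.integer(C)
    N <- as.integer(N); k <- as.integer(k); H <- as.integer(H)
    W <- as.integer(W)
    HpWp <- Hp * Wp
    off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
    rows <- as.vector(outer(off, (0:(C - 1L)) * HpWp, "+"))   # k2*C
    start <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
    cols <- as.vector(outer(start, (0:(N - 1L)) * (HpWp * C), "+"))
    idx <- outer(rows, cols, "+")                  # (k2*C) x (HW*N)
    storage.mode(idx) <- "integer"
    # keep a plain vector: a matrix subscript whose column count equals the
    # array's dimensionality would be read as per-row coordinates
    dm <- dim(idx)
    dim(idx) <- NULL
    attr(idx, "dims") <- dm
    .im2col_cache[[key]] <- idx
  }
  idx
}

nn_im2col <- function(xp, k, H, W) {
  d <- dim(xp)
  idx <- nn_im2col_index(d[1L], d[2L], d[3L], d[4L], k, H, W)
  col <- xp[idx]
  dim(col) <- attr(idx, "dims")
  col
}

# Same-padding stride-1 convolution. W: (k, k, Cin, Cout), b: length Cout.
conv2d_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; N <- d[4L]
  k <- dim(W)[1L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  stopifnot(dim(W)[2L] == k, d[3L] == Cin, k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  col <- nn_im2col(nn_pad(x, p), k, H, Wd)         # (k2*Cin) x (HW*N)
  Wm <- matrix(W, k * k * Cin, Cout)
  out <- crossprod(Wm, col) + b                    # Cout x (HW*N)
  out <- array(out, c(Cout, H * Wd, N))
  out <- aperm(out, c(2L, 1L, 3L))
  dim(out) <- c(H, Wd, Cout, N)
  list(out = out, cache = list(col = col, W = W, dims = d))
}

conv2d_backward <- function(dout, cache) {
  W <- cache$W; d <- cache$dims
  H <- d[1L]; Wd <- d[2L]; N <- d[4L]
  k <- dim(W)[1L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  dm <- aperm(array(dout, c(H * Wd, Cout, N)), c(2L, 1L, 3L))
  dim(dm) <- c(Cout, H * Wd * N)                   # Cout x (HW*N)
  dW <- cache$col %*% t(dm)                        # (k2*Cin) x Cout
  dim(dW) <- c(k, k, Cin, Cout)
  db <- rowSums(dm)
  # dx: convolve dout with the spatially flipped, channel-transposed kernel
  Wf <- W[k:1, k:1, , , drop = FALSE]
  Wt <- aperm(Wf, c(1L, 2L, 4L, 3L))               # (k, k, Cout, Cin)
  dx <- conv2d_forward(dout, Wt, rep(0, Cin))$out
  list(dx = dx, dW = dW, db = db)
}

# Instance normalisation: statistics per (channel, sample) over H x W, with
# per-channel affine parameters. Batch-independent, so tiny batches are fine.
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  xm <- matrix(x, HW, C * N)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = HW)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = HW)
  g <- rep(gamma, times = N)
  out <- xhat * rep(g, each = HW) + rep(rep(beta, times = N), each = HW)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, dims = d))
}

instnorm_backward <- function(dout, cache) {
  d <- cache$dims; HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  dm <- matrix(dout, HW, C * N)
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(colSums(dm * xhat), C, N))
  dbeta <- rowSums(matrix(colSums(dm), C, N))
  g <- rep(cache$gamma, times = N)
  dxhat <- dm * rep(g, each = HW)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = HW) - xhat * rep(m2, each = HW)) *
    rep(cache$istd, each = HW)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_backward <- function(dout, mask) dout * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Global average pool over H, W: (H, W, C, N) -> (C, N)
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])),
              d[3L], d[4L])
  list(out = m, cache = d)
}
gap_backward <- function(dout, d) {
  HW <- d[1L] * d[2L]
  dx <- array(rep(as.vector(dout) / HW, each = HW), d)
  dx
}

# Global max pool over H, W: (C, N) values + argmax locations
gmp_forward <- function(x) {
  d <- dim(x); HW <- d[1L] * d[2L]
  m <- matrix(x, HW, d[3L] * d[4L])
  am <- max.col(t(m), ties.method = "first")
  out <- matrix(m[cbind(am, seq_along(am))], d[3L], d[4L])
  list(out = out, cache = list(am = am, dims = d))
}
gmp_backward <- function(dout, cache) {
  d <- cache$dims; HW <- d[1L] * d[2L]
  dm <- matrix(0, HW, d[3L] * d[4L])
  dm[cbind(cache$am, seq_len(ncol(dm)))] <- as.vector(dout)
  array(dm, d)
}

# Fully connected: W (n_out x n_in), x (n_in x N)
linear_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}
linear_backward <- function(dout, cache) {
  list(dx = crossprod(cache$W, dout),
       dW = dout %*% t(cache$x),
       db = rowSums(dout))
}

# Softmax cross-entropy. logits: (K x N), y: integer class in 1..K.
# Returns mean loss, probabilities and dlogits.
softmax_ce <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), "/")
  loss <- -mean(log(pmax(p[cbind(y, seq_len(N))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = p, dlogits = dlogits)
}
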