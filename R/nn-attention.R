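# Channel and spatial attention (the convolutional-block-attention pattern):
# channel gating from pooled per-channel statistics through a shared
# bottleneck MLP, then spatial gating from channel-pooled maps through a
# wide convolution. Both end in a sigmoid, so each gate lies in (0, 1) and
# the module is a pure rescaling of its input.

#' Initialise channel-attention parameters
#'
#' Shared two-layer bottleneck MLP with hidden size
#' `channels / reduction_ratio`.
#'
#' @param channels Number of input channels.
#' @param reduction_ratio Bottleneck reduction (>= 1, must divide
#'   `channels`).
#' @return Parameter list (`W1`, `b1`, `W2`, `b2`).
#' @export
channel_attention_params <- function(channels, reduction_ratio = 4L) {
  if (reduction_ratio < 1L || channels %% reduction_ratio != 0L) {
    stop("reduction_ratio must be >= 1 and divide the channel count",
         call. = FALSE)
  }
  hidden <- channels %/% reduction_ratio
  list(W1 = matrix(stats::rnorm(hidden * channels, 0,
                                sqrt(2 / channels)), hidden, channels),
       b1 = rep(0, hidden),
       W2 = matrix(stats::rnorm(channels * hidden, 0,
                                sqrt(2 / hidden)), channels, hidden),
       b2 = rep(0, channels))
}

#' Channel attention forward pass
#'
#' Gates each channel by
#' `sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` with a shared bottleneck
#' MLP; the module output is `x` scaled channel-wise by the gate.
#'
#' @param x Activation array `(H, W, C, N)`.
#' @param params Parameters from [channel_attention_params()].
#' @return `list(out, weights, cache)`; `weights` is `C x N`, all in
#'   (0, 1).
#' @export
channel_attention_forward <- function(x, params) {
  C <- dim(x)[3L]
  if (nrow(params$W1) > C) {
    stop("reduction bottleneck larger than channel count", call. = FALSE)
  }
  avg <- gap_forward(x); mx <- gmp_forward(x)
  mlp <- function(s) {
    h_pre <- params$W1 %*% s + params$b1
    h <- pmax(h_pre, 0)
    list(out = params$W2 %*% h + params$b2, h_mask = h_pre > 0, h = h, s = s)
  }
  ma <- mlp(avg$out); mm <- mlp(mx$out)
  w <- sigmoid(ma$out + mm$out)                    # C x N
  d <- dim(x); HW <- d[1L] * d[2L]
  wfull <- rep(as.vector(w), each = HW)
  out <- array(as.vector(x) * wfull, d)
  list(out = out, weights = w,
       cache = list(x = x, w = w, ma = ma, mm = mm,
                    avg_cache = avg$cache, max_cache = mx$cache))
}

channel_attention_backward <- function(dout, cache, params) {
  x <- cache$x; w <- cache$w
  d <- dim(x); HW <- d[1L] * d[2L]
  wfull <- rep(as.vector(w), each = HW)
  dx <- array(as.vector(dout) * wfull, d)
  # dL/dw: sum over spatial of dout * x, per (c, n)
  dw <- matrix(colSums(matrix(as.vector(dout) * as.vector(x),
                              HW, d[3L] * d[4L])), d[3L], d[4L])
  dlogit <- dw * w * (1 - w)
  mlp_bwd <- function(m, dlogit) {
    dW2 <- dlogit %*% t(m$h)
    db2 <- rowSums(dlogit)
    dh <- crossprod(params$W2, dlogit) * m$h_mask
    dW1 <- dh %*% t(m$s)
    db1 <- rowSums(dh)
    list(ds = crossprod(params$W1, dh),
         dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
  }
  ba <- mlp_bwd(cache$ma, dlogit)
  bm <- mlp_bwd(cache$mm, dlogit)
  dx <- dx + gap_backward(ba$ds, cache$avg_cache) +
    gmp_backward(bm$ds, cache$max_cache)
  list(dx = dx,
       dW1 = ba$dW1 + bm$dW1, db1 = ba$db1 + bm$db1,
       dW2 = ba$dW2 + bm$dW2, db2 = ba$db2 + bm$db2)
}

#' Initialise spatial-attention parameters
#'
#' A single `kernel x kernel` convolution over the 2-channel map formed by
#' the channel-wise mean and maximum.
#'
#' @param kernel Odd kernel size (default 7).
#' @return Parameter list (`W` of shape `(k, k, 2, 1)`, `b`).
#' @export
spatial_attention_params <- function(kernel = 7L) {
  if (kernel %% 2L != 1L) stop("spatial kernel must be odd", call. = FALSE)
  list(W = array(stats::rnorm(kernel * kernel * 2L, 0,
                              sqrt(2 / (kernel * kernel * 2L))),
                 c(kernel, kernel, 2L, 1L)),
       b = 0)
}

#' Spatial attention forward pass
#'
#' Gates each spatial location by
#' `sigmoid(conv_k(concat(channel_mean(x), channel_max(x))))` with same
#' padding; the module output is `x` scaled location-wise.
#'
#' @param x Activation array `(H, W, C, N)`.
#' @param params Parameters from [spatial_attention_params()].
#' @return `list(out, map, cache)`; `map` is `(H, W, 1, N)`, values in
#'   (0, 1).
#' @export
spatial_attention_forward <- function(x, params) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; C <- d[3L]; N <- d[4L]
  xm <- aperm(x, c(3L, 1L, 2L, 4L))                # C, H, W, N
  dim(xm) <- c(C, H * Wd * N)
  mu <- colMeans(xm)
  am <- max.col(t(xm), ties.method = "first")
  mxv <- xm[cbind(am, seq_along(am))]
  cat2 <- array(0, c(H, Wd, 2L, N))
  cat2[, , 1L, ] <- array(mu, c(H, Wd, N))
  cat2[, , 2L, ] <- array(mxv, c(H, Wd, N))
  cv <- conv2d_forward(cat2, params$W, params$b)
  map <- sigmoid(cv$out)                           # H, W, 1, N
  mrep <- array(0, d)                              # map broadcast over C
  mv <- array(map, c(H, Wd, N))
  for (cc in seq_len(C)) mrep[, , cc, ] <- mv
  out <- x * mrep
  list(out = out, map = map,
       cache = list(x = x, map = map, mrep = mrep, conv_cache = cv$cache,
                    am = am, dims = d))
}

spatial_attention_backward <- function(dout, cache, params) {
  d <- cache$dims; H <- d[1L]; Wd <- d[2L]; C <- d[3L]; N <- d[4L]
  x <- cache$x; map <- cache$map
  dx <- dout * cache$mrep
  # dL/dmap: sum over channels of dout * x
  s <- matrix(aperm(dout * x, c(3L, 1L, 2L, 4L)), C, H * Wd * N)
  dmap <- array(colSums(s), c(H, Wd, 1L, N))
  dlogit <- dmap * map * (1 - map)
  cb <- conv2d_backward(dlogit, cache$conv_cache)
  dcat <- cb$dx                                    # H, W, 2, N
  # mean path: spread evenly over channels
  dmu <- array(dcat[, , 1L, ] / C, c(H, Wd, N))
  for (cc in seq_len(C)) dx[, , cc, ] <- dx[, , cc, ] + dmu
  # max path: route to the argmax channel
  dmx <- as.vector(dcat[, , 2L, ])                 # length H*W*N
  dxm <- matrix(0, C, H * Wd * N)
  dxm[cbind(cache$am, seq_along(cache$am))] <- dmx
  dx <- dx + aperm(array(dxm, c(C, H, Wd, N)), c(2L, 3L, 1L, 4L))
  list(dx = dx, dW = cb$dW, db = cb$db)
}
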