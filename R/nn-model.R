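#' Network configuration
#'
#' Architecture hyperparameters of the residual classifier. With
#' `use_attention = TRUE` every residual block is augmented by channel
#' attention followed by spatial attention (the convolutional-block
#' attention pattern); with `FALSE` the same trunk is the plain residual
#' baseline. Defaults are deliberately small — the study cohort has 40
#' subjects — and all widths are constant along the trunk.
#'
#' @param in_shape Input `(pairs, frequencies)`, default `c(15, 30)`.
#' @param stem_channels Trunk width, default 16.
#' @param n_blocks Number of residual blocks, default 3.
#' @param reduction_ratio Channel-attention bottleneck; must divide
#'   `stem_channels`. Default 4.
#' @param spatial_kernel Odd spatial-attention kernel size, default 7.
#' @param use_attention Attention-augmented (`TRUE`) or plain baseline.
#' @param n_classes Number of classes (2).
#' @param init_seed Seed for parameter initialisation.
#' @return Object of class `network_config`.
#' @export
network_config <- function(in_shape = c(15L, 30L), stem_channels = 16L,
                           n_blocks = 3L, reduction_ratio = 4L,
                           spatial_kernel = 7L, use_attention = TRUE,
                           n_classes = 2L, init_seed = 1L) {
  if (spatial_kernel %% 2L != 1L) {
    stop("spatial_kernel must be odd", call. = FALSE)
  }
  if (reduction_ratio < 1L || stem_channels %% reduction_ratio != 0L) {
    stop("reduction_ratio must be >= 1 and divide stem_channels",
         call. = FALSE)
  }
  if (n_classes != 2L) stop("binary classifier: n_classes must be 2",
                            call. = FALSE)
  structure(list(in_shape = as.integer(in_shape),
                 stem_channels = as.integer(stem_channels),
                 n_blocks = as.integer(n_blocks),
                 reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 use_attention = isTRUE(use_attention),
                 n_classes = 2L,
                 init_seed = as.integer(init_seed)),
            class = "network_config")
}

conv_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Residual block parameters
#'
#' The transform branch is a 1x1 convolution, instance norm, rectifier,
#' 3x3 convolution, instance norm. The shortcut is the identity when
#' input and output channel counts agree, otherwise a projecting 1x1
#' convolution with its own norm.
#'
#' @param cin,cout Input/output channel counts.
#' @param config A [network_config()] (attention settings are read from
#'   it).
#' @return Parameter list for [residual_block_forward()].
#' @export
residual_block_params <- function(cin, cout, config) {
  p <- list(
    conv1_W = conv_init(1L, cin, cout), conv1_b = rep(0, cout),
    in1_gamma = rep(1, cout), in1_beta = rep(0, cout),
    conv2_W = conv_init(3L, cout, cout), conv2_b = rep(0, cout),
    in2_gamma = rep(1, cout), in2_beta = rep(0, cout)
  )
  if (config$use_attention) {
    p$ca <- channel_attention_params(cout, config$reduction_ratio)
    p$sa <- spatial_attention_params(config$spatial_kernel)
  }
  if (cin != cout) {
    p$proj_W <- conv_init(1L, cin, cout)
    p$proj_b <- rep(0, cout)
    p$projn_gamma <- rep(1, cout)
    p$projn_beta <- rep(0, cout)
  }
  p
}

#' Residual block forward pass
#'
#' `out = relu(F(x) + shortcut(x))` where `F` is conv-norm-relu-conv-norm
#' and, when attention is enabled, `F`'s output passes through channel
#' then spatial attention before the addition.
#'
#' @param x Activation array `(H, W, C, N)`.
#' @param p Parameters from [residual_block_params()].
#' @param use_attention Apply the attention gates.
#' @return `list(out, cache)`.
#' @export
residual_block_forward <- function(x, p, use_attention = !is.null(p$ca)) {
  c1 <- conv2d_forward(x, p$conv1_W, p$conv1_b)
  n1 <- instnorm_forward(c1$out, p$in1_gamma, p$in1_beta)
  r1 <- relu_forward(n1$out)
  c2 <- conv2d_forward(r1$out, p$conv2_W, p$conv2_b)
  n2 <- instnorm_forward(c2$out, p$in2_gamma, p$in2_beta)
  h <- n2$out
  ca <- sa <- NULL
  if (use_attention) {
    ca <- channel_attention_forward(h, p$ca)
    sa <- spatial_attention_forward(ca$out, p$sa)
    h <- sa$out
  }
  if (!is.null(p$proj_W)) {
    pc <- conv2d_forward(x, p$proj_W, p$proj_b)
    pn <- instnorm_forward(pc$out, p$projn_gamma, p$projn_beta)
    sc <- pn$out
    proj <- list(pc = pc$cache, pn = pn$cache)
  } else {
    if (!identical(dim(h), dim(x))) {
      stop("shape mismatch between transform and shortcut", call. = FALSE)
    }
    sc <- x
    proj <- NULL
  }
  r2 <- relu_forward(h + sc)
  list(out = r2$out,
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    c2 = c2$cache, n2 = n2$cache, ca = ca, sa = sa,
                    proj = proj, r2 = r2$cache,
                    use_attention = use_attention))
}

residual_block_backward <- function(dout, cache, p) {
  g <- list()
  dsum <- relu_backward(dout, cache$r2)
  dh <- dsum
  if (cache$use_attention) {
    sb <- spatial_attention_backward(dh, cache$sa$cache, p$sa)
    g$sa <- list(W = sb$dW, b = sb$db)
    cb <- channel_attention_backward(sb$dx, cache$ca$cache, p$ca)
    g$ca <- list(W1 = cb$dW1, b1 = cb$db1, W2 = cb$dW2, b2 = cb$db2)
    dh <- cb$dx
  }
  n2b <- instnorm_backward(dh, cache$n2)
  g$in2_gamma <- n2b$dgamma; g$in2_beta <- n2b$dbeta
  c2b <- conv2d_backward(n2b$dx, cache$c2)
  g$conv2_W <- c2b$dW; g$conv2_b <- c2b$db
  dr1 <- relu_backward(c2b$dx, cache$r1)
  n1b <- instnorm_backward(dr1, cache$n1)
  g$in1_gamma <- n1b$dgamma; g$in1_beta <- n1b$dbeta
  c1b <- conv2d_backward(n1b$dx, cache$c1)
  g$conv1_W <- c1b$dW; g$conv1_b <- c1b$db
  dx <- c1b$dx
  if (!is.null(cache$proj)) {
    pnb <- instnorm_backward(dsum, cache$proj$pn)
    g$projn_gamma <- pnb$dgamma; g$projn_beta <- pnb$dbeta
    pcb <- conv2d_backward(pnb$dx, cache$proj$pc)
    g$proj_W <- pcb$dW; g$proj_b <- pcb$db
    dx <- dx + pcb$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

#' Build a classifier
#'
#' Stem 3x3 convolution, `n_blocks` residual blocks (attention-augmented
#' iff `use_attention`), global average pooling and a fully connected
#' head producing two class scores. Initialisation is reproducible from
#' `config$init_seed`.
#'
#' @param config A [network_config()].
#' @return Object of class `bis_classifier` holding `config` and the
#'   parameter list.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  S <- config$stem_channels
  params <- with_local_seed(config$init_seed, {
    p <- list(
      stem_W = conv_init(3L, 1L, S), stem_b = rep(0, S),
      stemn_gamma = rep(1, S), stemn_beta = rep(0, S),
      blocks = lapply(seq_len(config$n_blocks), function(i) {
        residual_block_params(S, S, config)
      }),
      head_W = matrix(stats::rnorm(config$n_classes * S, 0, sqrt(1 / S)),
                      config$n_classes, S),
      head_b = rep(0, config$n_classes)
    )
    p
  })
  structure(list(config = config, params = params,
                 normalizer = NULL),
            class = "bis_classifier")
}

# Full forward pass. x: (H, W, 1, N). Returns logits, probs, caches.
model_forward <- function(model, x) {
  p <- model$params
  st <- conv2d_forward(x, p$stem_W, p$stem_b)
  sn <- instnorm_forward(st$out, p$stemn_gamma, p$stemn_beta)
  sr <- relu_forward(sn$out)
  h <- sr$out
  bcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bf <- residual_block_forward(h, p$blocks[[i]],
                                 model$config$use_attention)
    h <- bf$out
    bcaches[[i]] <- bf$cache
  }
  gp <- gap_forward(h)
  hd <- linear_forward(gp$out, p$head_W, p$head_b)
  logits <- hd$out
  e <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
  probs <- sweep(e, 2L, colSums(e), "/")
  list(logits = logits, probs = probs,
       cache = list(st = st$cache, sn = sn$cache, sr = sr$cache,
                    blocks = bcaches, gap = gp$cache, head = hd$cache))
}

model_backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  hb <- linear_backward(dlogits, cache$head)
  g$head_W <- hb$dW; g$head_b <- hb$db
  dh <- gap_backward(hb$dx, cache$gap)
  g$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bb <- residual_block_backward(dh, cache$blocks[[i]], p$blocks[[i]])
    g$blocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  drs <- relu_backward(dh, cache$sr)
  snb <- instnorm_backward(drs, cache$sn)
  g$stemn_gamma <- snb$dgamma; g$stemn_beta <- snb$dbeta
  stb <- conv2d_backward(snb$dx, cache$st)
  g$stem_W <- stb$dW; g$stem_b <- stb$db
  list(grads = g, dx = stb$dx)
}

#' Count trainable parameters
#'
#' @param model A `bis_classifier`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

#' Class probabilities for a batch of impedance matrices
#'
#' Applies the model's stored per-frequency standardisation (fitted on
#' training data only) and runs the forward pass. Each matrix is treated
#' as a 1-channel image; results are independent across batch elements.
#'
#' @param model A trained `bis_classifier` with a fitted normalizer.
#' @param matrices List of `impedance_matrix` objects (or plain numeric
#'   matrices of the configured input shape).
#' @return Matrix `n x 2` of class probabilities, columns
#'   `(healthy, nafld)`, rows summing to 1.
#' @export
predict_proba <- function(model, matrices) {
  stopifnot(inherits(model, "bis_classifier"))
  if (is.null(model$normalizer)) {
    stop("model has no fitted normalizer; train it first", call. = FALSE)
  }
  x <- batch_tensor(matrices, model$normalizer, model$config$in_shape)
  pr <- t(model_forward(model, x)$probs)
  colnames(pr) <- c("healthy", "nafld")
  pr
}

# Stack matrices into the (H, W, 1, N) input tensor, standardising each
# frequency column with the training-set statistics.
batch_tensor <- function(matrices, normalizer, in_shape) {
  if (inherits(matrices, "impedance_matrix")) matrices <- list(matrices)
  mats <- lapply(matrices, function(m) {
    if (inherits(m, "impedance_matrix")) m <- m$magnitudes
    if (!identical(dim(m), as.integer(in_shape))) {
      stop("matrix shape does not match the network input shape",
           call. = FALSE)
    }
    sweep(sweep(log10(m), 2L, normalizer$mu), 2L, normalizer$sd, "/")
  })
  x <- array(0, c(in_shape[1L], in_shape[2L], 1L, length(mats)))
  for (i in seq_along(mats)) x[, , 1L, i] <- mats[[i]]
  x
}

#' Fit the per-frequency normalizer
#'
#' Computes the mean and standard deviation of `log10` magnitude for each
#' frequency column over the supplied (training) matrices. Magnitudes
#' span decades across the sweep, so standardisation is done on the log
#' scale, column-wise.
#'
#' @param matrices List of `impedance_matrix` (training split only).
#' @return List with `mu` and `sd`, one value per frequency column.
#' @export
fit_normalizer <- function(matrices) {
  if (length(matrices) == 0L) stop("no training matrices", call. = FALSE)
  stk <- do.call(rbind, lapply(matrices, function(m) {
    log10(if (inherits(m, "impedance_matrix")) m$magnitudes else m)
  }))
  mu <- colMeans(stk)
  sd_ <- apply(stk, 2L, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  list(mu = mu, sd = sd_)
}
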