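test_that("attention gates are sigmoid-bounded and 0.5 at zero pre-activation", {
  set.seed(1)
  x <- array(rnorm(4 * 5 * 4 * 2), c(4, 5, 4, 2))
  ca <- channel_attention_params(4, 2)
  fw <- channel_attention_forward(x, ca)
  expect_true(all(fw$weights > 0 & fw$weights < 1))
  expect_identical(dim(fw$weights), c(4L, 2L))

  # all-zero input with zero biases: every gate is sigmoid(0) = 0.5
  z <- array(0, c(4, 5, 4, 2))
  fz <- channel_attention_forward(z, ca)
  expect_equal(as.vector(fz$weights), rep(0.5, 8))
  expect_equal(fz$out, z * 0.5)

  sa <- spatial_attention_params(3)
  sw <- spatial_attention_forward(x, sa)
  expect_identical(dim(sw$map), c(4L, 5L, 1L, 2L))
  expect_true(all(sw$map > 0 & sw$map < 1))
  sz <- spatial_attention_forward(z, sa)
  expect_equal(as.vector(sz$map), rep(0.5, 4 * 5 * 2))

  expect_error(channel_attention_params(4, 3), "divide")
  expect_error(spatial_attention_params(4), "odd")
})

test_that("channel attention matches a pencil-and-paper forward pass", {
  # 2 channels, 2x2 spatial, 1 sample; identity-like MLP (reduction 1):
  # W1 = I, W2 = I, zero biases -> logits = relu(avg) + relu(max)
  x <- array(c(1, 2, 3, 4,          # channel 1: avg 2.5, max 4
               -1, -2, -3, 0),      # channel 2: avg -1.5, max 0
             c(2, 2, 2, 1))
  p <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  fw <- channel_attention_forward(x, p)
  expected <- 1 / (1 + exp(-c(2.5 + 4, 0 + 0)))
  expect_equal(as.vector(fw$weights), expected, tolerance = 1e-12)
  expect_equal(fw$out[, , 1, 1], x[, , 1, 1] * expected[1])
  expect_equal(fw$out[, , 2, 1], x[, , 2, 1] * expected[2])
})

test_that("residual block reduces to a gated identity when F is zero", {
  cfg <- tiny_net_config(use_attention = FALSE)
  p <- residual_block_params(4L, 4L, cfg)
  p$conv1_W[] <- 0; p$conv2_W[] <- 0
  p$in1_gamma[] <- 0; p$in2_gamma[] <- 0   # kill the norm output too
  set.seed(2)
  x <- array(rnorm(5 * 6 * 4 * 2), c(5, 6, 4, 2))
  out <- residual_block_forward(x, p, use_attention = FALSE)$out
  expect_equal(out, pmax(x, 0), tolerance = 1e-12)
  expect_identical(dim(out), dim(x))
})

test_that("1x1 convolution block arithmetic matches hand computation", {
  # 1-channel 2x2 input through a 1x1 conv with weight 2, bias 1
  x <- array(c(1, -1, 0.5, 2), c(2, 2, 1, 1))
  W <- array(2, c(1, 1, 1, 1))
  out <- nafldbis:::conv2d_forward(x, W, 1)$out
  expect_equal(out, x * 2 + 1, tolerance = 1e-12)
})

test_that("model builds reproducibly and outputs normalised probabilities", {
  cfg <- tiny_net_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  set.seed(5)
  x <- array(rnorm(5 * 6 * 1 * 3), c(5, 6, 1, 3))
  f1 <- nafldbis:::model_forward(m1, x)
  f2 <- nafldbis:::model_forward(m2, x)
  expect_identical(f1$probs, f2$probs)
  expect_equal(colSums(f1$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(f1$probs >= 0 & f1$probs <= 1))

  m3 <- build_model(tiny_net_config(init_seed = 8L))
  expect_false(identical(nafldbis:::model_forward(m3, x)$probs, f1$probs))

  # attention strictly adds parameters over the baseline trunk
  n_attn <- count_params(build_model(tiny_net_config(TRUE)))
  n_base <- count_params(build_model(tiny_net_config(FALSE)))
  expect_gt(n_attn, n_base)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_net_config()
  model <- build_model(cfg)
  theta <- nafldbis:::flatten_params(model$params)
  # nudge all parameters off initialisation kinks (zero-mean norm output
  # sits exactly on the ReLU corner of the attention MLP)
  set.seed(11)
  theta <- theta + rnorm(length(theta), 0, 0.05)
  model$params <- nafldbis:::unflatten_into(model$params, theta)$p
  set.seed(42)
  x <- array(rnorm(5 * 6 * 1 * 3), c(5, 6, 1, 3))
  y <- c(1L, 2L, 1L)
  lossfun <- function(th) {
    m <- model
    m$params <- nafldbis:::unflatten_into(m$params, th)$p
    nafldbis:::softmax_ce(nafldbis:::model_forward(m, x)$logits, y)$loss
  }
  fw <- nafldbis:::model_forward(model, x)
  sc <- nafldbis:::softmax_ce(fw$logits, y)
  bw <- nafldbis:::model_backward(model, fw$cache, sc$dlogits)
  g <- nafldbis:::flatten_params(
    nafldbis:::align_grads(model$params, bw$grads))
  set.seed(9)
  idx <- sample(length(theta), 60)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta
    tp[i] <- tp[i] + eps; lp <- lossfun(tp)
    tp[i] <- theta[i] - eps; lm <- lossfun(tp)
    (lp - lm) / (2 * eps)
  }, 0)
  rel <- abs(num - g[idx]) / pmax(1e-4, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-5)

  # input gradient too (exercises every backward dx path)
  numx <- vapply(1:20, function(i) {
    xv <- as.vector(x)
    xv[i] <- xv[i] + eps
    lp <- nafldbis:::softmax_ce(
      nafldbis:::model_forward(model, array(xv, dim(x)))$logits, y)$loss
    xv[i] <- as.vector(x)[i] - eps
    lm <- nafldbis:::softmax_ce(
      nafldbis:::model_forward(model, array(xv, dim(x)))$logits, y)$loss
    (lp - lm) / (2 * eps)
  }, 0)
  expect_lt(max(abs(numx - as.vector(bw$dx)[1:20])), 1e-6)
})

test_that("gradient flows through the shortcut when the transform is frozen at zero", {
  cfg <- tiny_net_config(use_attention = FALSE)
  p <- residual_block_params(4L, 4L, cfg)
  p$conv1_W[] <- 0; p$conv2_W[] <- 0
  p$in1_gamma[] <- 0; p$in2_gamma[] <- 0
  set.seed(3)
  x <- array(abs(rnorm(5 * 6 * 4 * 2)) + 0.1, c(5, 6, 4, 2))  # all positive
  fw <- residual_block_forward(x, p, use_attention = FALSE)
  dout <- array(rnorm(length(x)), dim(x))
  bw <- nafldbis:::residual_block_backward(dout, fw$cache, p)
  # with x > 0 the output relu is the identity, so dx equals dout exactly
  expect_equal(bw$dx, dout, tolerance = 1e-12)
})

test_that("predictions are batch independent and order equivariant", {
  co <- small_cohort(seed = 2, n = 3L)
  cfg <- network_config(use_attention = TRUE, stem_channels = 4L,
                        n_blocks = 1L, reduction_ratio = 2L,
                        spatial_kernel = 3L)
  model <- build_model(cfg)
  model$normalizer <- fit_normalizer(co$matrices)
  p_all <- predict_proba(model, co$matrices)
  p_one <- predict_proba(model, co$matrices[2])
  expect_equal(p_all[2, ], p_one[1, ], tolerance = 1e-9)

  perm <- c(4, 1, 6, 2, 5, 3)
  p_perm <- predict_proba(model, co$matrices[perm])
  expect_equal(p_perm, p_all[perm, ], tolerance = 1e-9)
  expect_equal(rowSums(p_all), rep(1, 6), tolerance = 1e-6)

  model$normalizer <- NULL
  expect_error(predict_proba(model, co$matrices), "normalizer")
})

test_that("the attention model overfits a small noise-free separable set", {
  cfg_gen <- default_generator_config()
  cfg_gen$noise_sigma <- 0
  co <- generate_cohort(4, 4, cfg_gen, seed = 21)
  split <- structure(list(assignment = rep("train", 8),
                          fractions = c(1, 0, 0) + 0,
                          seed = 1L, subject_ids = co$subject_ids),
                     class = "split_assignment")
  cfg <- network_config(use_attention = TRUE, stem_channels = 8L,
                        n_blocks = 2L, reduction_ratio = 4L,
                        spatial_kernel = 7L)
  hp <- default_hyperparams()
  hp$max_epochs <- 150L
  fit <- train_model(cfg, split, co, hp, seed = 5)
  final <- fit$history[nrow(fit$history), ]
  expect_equal(final$train_acc, 1)
})
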