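# --- parameter flattening utilities (Adam works on one flat vector) ----

flatten_params <- function(p) {
  if (is.list(p)) {
    unlist(lapply(p, flatten_params), use.names = FALSE)
  } else {
    as.vector(p)
  }
}

# reorder a gradient structure to the parameter structure's ordering
align_grads <- function(p, g) {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    out <- lapply(keys, function(k) {
      if (is.null(g[[k]])) {
        stop("missing gradient for parameter '", k, "'", call. = FALSE)
      }
      align_grads(p[[k]], g[[k]])
    })
    out
  } else {
    g
  }
}

unflatten_into <- function(p, flat, pos = 1L) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- unflatten_into(p[[i]], flat, pos)
      p[[i]] <- r$p
      pos <- r$pos
    }
    list(p = p, pos = pos)
  } else {
    n <- length(p)
    p[] <- flat[pos:(pos + n - 1L)]
    list(p = p, pos = pos + n)
  }
}

#' Stratified train/validation/test split
#'
#' Assigns each subject to one of three partitions, stratified by class.
#' Within each class, sizes follow the fractions by the largest-remainder
#' rule (remainder ties broken in train, validation, test order), so a
#' balanced 40-subject cohort under fractions (0.5, 0.2, 0.3) always
#' yields 20/8/12 with 10/4/6 per class.
#'
#' @param cohort A `cohort_dataset`.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return Object of class `split_assignment`: list with `assignment`
#'   (character vector `train`/`validation`/`test`, one per subject),
#'   `fractions`, `seed`.
#' @export
split_dataset <- function(cohort, fractions = c(0.5, 0.2, 0.3), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  labels <- cohort$labels
  n <- length(labels)
  assignment <- character(n)
  parts <- c("train", "validation", "test")
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 3L) {
        warning("class '", cl, "' has fewer than 3 subjects; ",
                "best-effort stratification", call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      q <- length(idx) * fractions
      base <- floor(q)
      rem <- q - base
      left <- length(idx) - sum(base)
      if (left > 0) {
        give <- order(rem, -seq_along(rem), decreasing = TRUE)[seq_len(left)]
        base[give] <- base[give] + 1
      }
      bounds <- cumsum(base)
      assignment[idx[seq_len(bounds[1L])]] <- "train"
      if (base[2L] > 0) {
        assignment[idx[(bounds[1L] + 1L):bounds[2L]]] <- "validation"
      }
      if (base[3L] > 0) {
        assignment[idx[(bounds[2L] + 1L):bounds[3L]]] <- "test"
      }
    }
  })
  structure(list(assignment = assignment, fractions = fractions,
                 seed = as.integer(seed),
                 subject_ids = cohort$subject_ids),
            class = "split_assignment")
}

#' Default training hyperparameters
#'
#' Adaptive-moment (Adam) optimisation of the two-class cross-entropy on
#' the full training batch, with early stopping on validation loss. None
#' of these values are measured quantities; they are the package's
#' declared defaults for a 40-subject cohort.
#'
#' @return List with `lr`, `max_epochs`, `patience`, `beta1`, `beta2`,
#'   `eps`, `tol_loss` and `plateau` (training also stops once both the
#'   training and validation partitions are perfectly classified with a
#'   full-batch cross-entropy below `tol_loss` for `plateau` consecutive
#'   epochs).
#' @export
default_hyperparams <- function() {
  list(lr = 1e-3, max_epochs = 300L, patience = 30L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       tol_loss = 0.15, plateau = 5L)
}

#' Train a classifier on a split cohort
#'
#' Fits the per-frequency normalizer on the training partition only,
#' optimises the full-batch cross-entropy with Adam, evaluates the
#' validation loss every epoch, and returns the checkpoint with the best
#' validation loss (early stopping after `patience` epochs without
#' improvement). Training is a pure function of its arguments: fixed
#' seeds give bitwise-identical histories.
#'
#' @param config A [network_config()]; its `init_seed` is overridden by
#'   `seed`.
#' @param split A [split_dataset()] result for `cohort`.
#' @param cohort The `cohort_dataset` the split was made on.
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed controlling parameter initialisation.
#' @return A trained `bis_classifier` with elements `history` (per-epoch
#'   train/validation loss and accuracy) and `best_epoch` attached.
#' @export
train_model <- function(config, split, cohort,
                        hyperparams = default_hyperparams(), seed = 1L) {
  stopifnot(inherits(config, "network_config"),
            inherits(split, "split_assignment"),
            inherits(cohort, "cohort_dataset"))
  tr <- which(split$assignment == "train")
  va <- which(split$assignment == "validation")
  if (length(tr) == 0L) stop("empty training partition", call. = FALSE)

  config$init_seed <- as.integer(seed)
  model <- build_model(config)
  model$normalizer <- fit_normalizer(cohort$matrices[tr])

  ylab <- function(i) ifelse(cohort$labels[i] == "nafld", 2L, 1L)
  xtr <- batch_tensor(cohort$matrices[tr], model$normalizer,
                      config$in_shape)
  ytr <- ylab(tr)
  if (length(va)) {
    xva <- batch_tensor(cohort$matrices[va], model$normalizer,
                        config$in_shape)
    yva <- ylab(va)
  }

  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  theta <- flatten_params(model$params)
  m <- v <- numeric(length(theta))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- vector("list", hp$max_epochs)
  wait <- 0L
  streak <- 0L

  for (epoch in seq_len(hp$max_epochs)) {
    fw <- model_forward(model, xtr)
    sc <- softmax_ce(fw$logits, ytr)
    bw <- model_backward(model, fw$cache, sc$dlogits)
    gflat <- flatten_params(align_grads(model$params, bw$grads))

    m <- hp$beta1 * m + (1 - hp$beta1) * gflat
    v <- hp$beta2 * v + (1 - hp$beta2) * gflat^2
    mhat <- m / (1 - hp$beta1^epoch)
    vhat <- v / (1 - hp$beta2^epoch)
    theta <- theta - hp$lr * mhat / (sqrt(vhat) + hp$eps)
    model$params <- unflatten_into(model$params, theta)$p

    tr_acc <- mean(max.col(t(sc$probs)) == ytr)
    if (length(va)) {
      vf <- model_forward(model, xva)
      vs <- softmax_ce(vf$logits, yva)
      va_loss <- vs$loss
      va_acc <- mean(max.col(t(vs$probs)) == yva)
    } else {
      va_loss <- sc$loss
      va_acc <- tr_acc
    }
    history[[epoch]] <- c(epoch = epoch, train_loss = sc$loss,
                          train_acc = tr_acc, val_loss = va_loss,
                          val_acc = va_acc)
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, theta = theta, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
    # convergence stop: both partitions perfectly classified with a small
    # training loss for `plateau` consecutive epochs
    if (tr_acc == 1 && va_acc == 1 && sc$loss < hp$tol_loss) {
      streak <- streak + 1L
      if (streak >= hp$plateau) break
    } else {
      streak <- 0L
    }
  }

  model$params <- unflatten_into(model$params, best$theta)$p
  model$history <- as.data.frame(do.call(rbind, history[!vapply(
    history, is.null, TRUE)]))
  model$best_epoch <- best$epoch
  model$hyperparams <- hp
  model
}
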