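#' ROC curve and AUC
#'
#' Computes the receiver operating characteristic by sweeping the
#' decision threshold over the distinct scores (tied scores move
#' together) and the area under it by the trapezoidal rule. This equals
#' the rank statistic: the probability that a random positive outscores
#' a random negative, with ties counting one half.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary truth: logical, 0/1, or `"healthy"`/`"nafld"`
#'   (nafld = positive).
#' @return List with `auc` and `roc`, a data frame of `(fpr, tpr)` points
#'   starting at (0, 0) and ending at (1, 1), both coordinates
#'   non-decreasing.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # collapse ties so tied scores enter the curve as one diagonal segment
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("healthy", "nafld"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    as.integer(labels == "nafld")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be binary", call. = FALSE)
    }
    labels
  }
}

#' Confusion matrix, accuracy and per-class misclassification
#'
#' Thresholds the positive-class scores at `threshold` and tabulates
#' counts by (truth, prediction). Accuracy is the trace over the total;
#' each class's misclassification rate is its off-diagonal count over its
#' row sum.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the positive-class score
#'   (default 0.5).
#' @return List with `confusion` (2x2 matrix, rows = truth
#'   healthy/nafld, columns = prediction), `accuracy`, and
#'   `misclassification` (named per-class rates).
#' @export
confusion_and_accuracy <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  cm <- matrix(0L, 2L, 2L,
               dimnames = list(truth = c("healthy", "nafld"),
                               prediction = c("healthy", "nafld")))
  for (i in seq_along(y)) {
    cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  }
  rs <- rowSums(cm)
  mis <- ifelse(rs > 0, (rs - diag(cm)) / rs, NA_real_)
  names(mis) <- rownames(cm)
  list(confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm),
       misclassification = mis)
}

#' Evaluate a trained classifier on one partition
#'
#' @param model Trained `bis_classifier`.
#' @param cohort The `cohort_dataset`.
#' @param split The [split_dataset()] assignment.
#' @param partition One of `"train"`, `"validation"`, `"test"`.
#' @param threshold Decision threshold, default 0.5.
#' @return Object of class `eval_report`: accuracy, auc, roc points,
#'   confusion matrix, per-class misclassification, scores, labels,
#'   partition size.
#' @export
evaluate_model <- function(model, cohort, split, partition = "test",
                           threshold = 0.5) {
  partition <- match.arg(partition, c("train", "validation", "test"))
  idx <- which(split$assignment == partition)
  if (length(idx) == 0L) stop("empty partition", call. = FALSE)
  pr <- predict_proba(model, cohort$matrices[idx])
  scores <- pr[, "nafld"]
  labels <- cohort$labels[idx]
  ra <- roc_auc(scores, labels)
  ca <- confusion_and_accuracy(scores, labels, threshold)
  structure(list(partition = partition, n = length(idx),
                 accuracy = ca$accuracy, auc = ra$auc, roc = ra$roc,
                 confusion = ca$confusion,
                 misclassification = ca$misclassification,
                 scores = scores, labels = labels,
                 threshold = threshold,
                 subject_ids = cohort$subject_ids[idx]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s, n = %d): accuracy %.3f, AUC %.3f\n",
              x$partition, x$n, x$accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Repeated-seed end-to-end evaluation
#'
#' Runs the full protocol (generate cohort, stratified split, train,
#' evaluate on the test partition) once per seed for both the
#' attention-augmented model and the plain residual baseline. Single
#' 12-subject test splits are seed-sensitive, so headline metrics are
#' reported as the mean over seeds.
#'
#' @param n_seeds Number of repetitions (default 5).
#' @param base_seed Seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param generator_config Settings for [generate_cohort()].
#' @param net_config A [network_config()] (attention flag is set
#'   internally per arm).
#' @param hyperparams See [default_hyperparams()].
#' @param models Which arms to run, subset of
#'   `c("attention", "baseline")`.
#' @return Data frame with one row per (seed, model): test accuracy, AUC
#'   and per-class misclassification.
#' @export
evaluate_over_seeds <- function(n_seeds = 5L, base_seed = 1L,
                                generator_config = default_generator_config(),
                                net_config = network_config(),
                                hyperparams = default_hyperparams(),
                                models = c("attention", "baseline")) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed <- as.integer(base_seed) + s - 1L
    cohort <- generate_cohort(20L, 20L, generator_config, seed = seed)
    split <- split_dataset(cohort, seed = seed + 1000L)
    for (arm in models) {
      cfg <- net_config
      cfg$use_attention <- arm == "attention"
      fit <- train_model(cfg, split, cohort, hyperparams,
                         seed = seed + 2000L)
      rep_ <- evaluate_model(fit, cohort, split, "test")
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, model = arm, accuracy = rep_$accuracy,
        auc = rep_$auc,
        mis_healthy = rep_$misclassification[["healthy"]],
        mis_nafld = rep_$misclassification[["nafld"]])
    }
  }
  do.call(rbind, rows)
}
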