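# Patient-wise splitting, class balancing, and the evaluation metric suite
# (confusion matrix, per-class and macro sensitivity/specificity, F1, AUROC,
# bootstrap confidence intervals).

#' Patient-level 80/20 holdout split
#'
#' Patients (not windows) are shuffled with the seed and partitioned so the
#' training side holds `ceiling(train_fraction * P)` patients.  No patient
#' ever straddles the two sets.
#'
#' @param patient_ids character vector of patient IDs (duplicates allowed;
#'   the unique set is split).
#' @param train_fraction fraction of patients for training (default 0.8).
#' @param seed RNG seed.
#' @return a `split_plan`: list of folds, each
#'   `list(train = ids, test = ids)`.
#' @export
grouped_holdout <- function(patient_ids, train_fraction = 0.8, seed = 1L) {
  pats <- unique(as.character(patient_ids))
  if (length(pats) < 2L) stop("need at least 2 patients to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  .with_seed(seed, {
    pats <- sample(pats)
    n_train <- ceiling(train_fraction * length(pats))
    if (n_train >= length(pats)) n_train <- length(pats) - 1L
    structure(list(list(train = sort(pats[seq_len(n_train)]),
                        test = sort(pats[(n_train + 1L):length(pats)]))),
              class = "split_plan")
  })
}

#' Leave-one-subject-out folds
#'
#' One fold per patient: fold i tests patient i and trains on the other
#' P - 1, so the test sets partition the cohort and no fold shares a patient
#' between its sides.
#'
#' @param patient_ids character vector of patient IDs.
#' @return a `split_plan` with P folds.
#' @export
loso_splits <- function(patient_ids) {
  pats <- unique(as.character(patient_ids))
  if (length(pats) < 2L) stop("need at least 2 patients for LOSO")
  folds <- lapply(pats, function(p) {
    list(train = setdiff(pats, p), test = p)
  })
  structure(folds, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d fold(s)\n", length(x)))
  for (i in seq_along(head(x, 5))) {
    cat(sprintf("  fold %d: %d train / %d test patient(s)\n",
                i, length(x[[i]]$train), length(x[[i]]$test)))
  }
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

# Subset a window set by patient IDs.
.subset_ws <- function(ws, patients) {
  keep <- ws$patient_ids %in% patients
  window_set(ws$windows[keep, , drop = FALSE],
             ws$labels_onehot[keep, , drop = FALSE],
             ws$patient_ids[keep], ws$class_order)
}

#' Balance classes by seeded oversampling
#'
#' Minority classes are oversampled with replacement until every class count
#' equals the majority count.  Window contents and labels are never altered,
#' only multiplicity.  Callers apply this to training folds only; resampling
#' test data would bias the metrics.
#'
#' @param ws a [window_set()]; every class in `class_order` must be present.
#' @param seed RNG seed.
#' @return a balanced [window_set()].
#' @export
balance_classes <- function(ws, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  cls <- max.col(ws$labels_onehot, ties.method = "first")
  counts <- tabulate(cls, nbins = length(ws$class_order))
  if (any(counts == 0L)) {
    stop("class(es) absent from the window set: ",
         paste(ws$class_order[counts == 0L], collapse = ", "))
  }
  target <- max(counts)
  .with_seed(seed, {
    idx <- seq_along(cls)
    for (k in seq_along(counts)) {
      need <- target - counts[k]
      if (need > 0L) {
        pool <- which(cls == k)
        idx <- c(idx, sample(pool, need, replace = TRUE))
      }
    }
    window_set(ws$windows[idx, , drop = FALSE],
               ws$labels_onehot[idx, , drop = FALSE],
               ws$patient_ids[idx], ws$class_order)
  })
}

#' Rank-statistic AUROC
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted half: `P(s+ > s-) + P(s+ = s-)/2`, computed from midranks.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion matrix and the full metric suite
#'
#' Predicted class is the row argmax of `y_prob`.  Per class (one-vs-rest):
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total.
#' Global: accuracy = trace/total; sensitivity and specificity are macro
#' averages.  F1 and AUROC use the positive class `"Arrhythmia"` when the
#' label set is binary, and macro one-vs-rest averaging otherwise.  Rates
#' are reported in percent; AUROC on `[0, 1]`.
#'
#' @param y_true_onehot n x K one-hot truth matrix.
#' @param y_prob n x K probability matrix.
#' @param class_order K class names.
#' @param ci_B bootstrap resamples for the AUROC/F1 intervals (0 disables).
#' @param ci_seed seed for the bootstrap.
#' @return an object of class `eval_report`.
#' @export
evaluate_predictions <- function(y_true_onehot, y_prob,
                                 class_order = colnames(y_prob),
                                 ci_B = 0L, ci_seed = 1L) {
  y_true_onehot <- as.matrix(y_true_onehot)
  y_prob <- as.matrix(y_prob)
  if (!all(dim(y_true_onehot) == dim(y_prob))) {
    stop("y_true_onehot and y_prob must have identical dimensions")
  }
  K <- ncol(y_prob)
  if (is.null(class_order)) class_order <- paste0("class", seq_len(K))
  truth <- max.col(y_true_onehot, ties.method = "first")
  pred <- max.col(y_prob, ties.method = "first")
  n <- length(truth)
  confusion <- matrix(0L, K, K, dimnames = list(truth = class_order,
                                                predicted = class_order))
  for (i in seq_len(n)) {
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  per_class <- data.frame(class = class_order,
                          accuracy = numeric(K), sensitivity = numeric(K),
                          specificity = numeric(K))
  for (k in seq_len(K)) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- n - tp - fn - fp
    per_class$accuracy[k] <- 100 * (tp + tn) / n
    per_class$sensitivity[k] <- 100 * .safe_div(tp, tp + fn)
    per_class$specificity[k] <- 100 * .safe_div(tn, tn + fp)
  }
  binary <- identical(class_order, c("Normal", "Arrhythmia"))
  f1 <- 100 * .f1_score(truth, pred, K, binary)
  auc <- .auroc_score(truth, y_prob, K, binary)
  global <- list(accuracy = 100 * sum(diag(confusion)) / n,
                 sensitivity = mean(per_class$sensitivity),
                 specificity = mean(per_class$specificity),
                 f1 = f1, auroc = auc)
  cis <- NULL
  if (ci_B > 0L) {
    cis <- list(
      auroc = bootstrap_ci(y_true_onehot, y_prob, "auroc", B = ci_B,
                           seed = ci_seed, class_order = class_order),
      f1 = bootstrap_ci(y_true_onehot, y_prob, "f1", B = ci_B,
                        seed = ci_seed, class_order = class_order))
  }
  structure(list(confusion = confusion, per_class = per_class,
                 global = global, cis = cis, n = n,
                 class_order = class_order),
            class = "eval_report")
}

.safe_div <- function(a, b) if (b == 0) 0 else a / b

# Macro or binary-positive F1 on the [0, 1] scale.
.f1_score <- function(truth, pred, K, binary) {
  f1k <- function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec <- .safe_div(tp, tp + fp)
    rec <- .safe_div(tp, tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  if (binary) f1k(2L) else mean(vapply(seq_len(K), f1k, numeric(1)))
}

# Binary-positive or macro one-vs-rest AUROC on the [0, 1] scale.
.auroc_score <- function(truth, y_prob, K, binary) {
  if (binary) {
    if (length(unique(truth)) < 2L) return(NA_real_)
    return(auroc(y_prob[, 2L], truth == 2L))
  }
  vals <- vapply(seq_len(K), function(k) {
    y <- truth == k
    if (!any(y) || all(y)) return(NA_real_)
    auroc(y_prob[, k], y)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Bootstrap confidence interval for AUROC or F1
#'
#' B seeded resamples of the evaluated windows with replacement; the metric
#' is recomputed on each resample and the 2.5th/97.5th percentiles returned.
#' A degenerate resample (only one truth class) is redrawn; the redraw count
#' is attached as attribute `n_redrawn`.
#'
#' @param y_true_onehot,y_prob as in [evaluate_predictions()].
#' @param metric `"auroc"` or `"f1"`.
#' @param B number of resamples (default 1000).
#' @param seed RNG seed.
#' @param class_order class names (decides binary vs. macro averaging).
#' @return numeric `c(lower, upper)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(y_true_onehot, y_prob, metric = c("auroc", "f1"),
                         B = 1000L, seed = 1L,
                         class_order = colnames(y_prob)) {
  metric <- match.arg(metric)
  stopifnot(B >= 1)
  y_true_onehot <- as.matrix(y_true_onehot)
  y_prob <- as.matrix(y_prob)
  K <- ncol(y_prob)
  if (is.null(class_order)) class_order <- paste0("class", seq_len(K))
  binary <- identical(class_order, c("Normal", "Arrhythmia"))
  truth <- max.col(y_true_onehot, ties.method = "first")
  n <- length(truth)
  if (length(unique(truth)) < 2L) {
    # the metric itself is undefined on a single-class truth set
    ci <- c(NA_real_, NA_real_)
    attr(ci, "n_redrawn") <- 0L
    return(ci)
  }
  compute <- function(idx) {
    tr <- truth[idx]
    pp <- y_prob[idx, , drop = FALSE]
    if (metric == "auroc") {
      .auroc_score(tr, pp, K, binary)
    } else {
      .f1_score(tr, max.col(pp, ties.method = "first"), K, binary)
    }
  }
  .with_seed(seed, {
    vals <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(truth[idx])) >= 2L || n < 2L) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * B) stop("bootstrap cannot draw two classes")
      }
      vals[b] <- compute(idx)
    }
    ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
    attr(ci, "n_redrawn") <- redrawn
    ci
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d windows, %d classes\n", x$n,
              length(x$class_order)))
  print(x$confusion)
  cat(sprintf("global: accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.2f%%  AUROC %s\n",
              x$global$accuracy, x$global$sensitivity, x$global$specificity,
              x$global$f1,
              ifelse(is.na(x$global$auroc), "NA",
                     sprintf("%.4f", x$global$auroc))))
  print(x$per_class, row.names = FALSE, digits = 4)
  if (!is.null(x$cis)) {
    cat(sprintf("95%% bootstrap CI  AUROC: %.4f-%.4f  F1: %.4f-%.4f\n",
                x$cis$auroc[1], x$cis$auroc[2],
                x$cis$f1[1] / 100, x$cis$f1[2] / 100))
  }
  invisible(x)
}

#' Leave-one-subject-out training and pooled evaluation
#'
#' For each LOSO fold the model is trained on all other patients' windows
#' (optionally class-balanced first) and predicts the held-out patient's
#' windows.  Predictions are pooled across folds and scored once, so the
#' report reflects every window exactly once and no fold ever sees its test
#' patient during training.
#'
#' @param spec a [model_spec()].
#' @param ws a [window_set()] covering >= 2 patients.
#' @param train_cfg a [train_config()]; fold seeds are derived from
#'   `train_cfg$seed`.
#' @param balance apply [balance_classes()] to each fold's training windows.
#' @param ci_B bootstrap resamples for the pooled report.
#' @param verbose print per-fold progress.
#' @return an `eval_report` with extra fields `pooled_prob`,
#'   `pooled_truth_onehot`, `pooled_patients` and `fold_models` (final
#'   training-history row per fold).
#' @export
evaluate_loso <- function(spec, ws, train_cfg = train_config(),
                          balance = FALSE, ci_B = 0L, verbose = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  plan <- loso_splits(ws$patient_ids)
  prob <- NULL
  truth <- NULL
  pats <- character(0)
  fold_hist <- list()
  for (i in seq_along(plan)) {
    fold <- plan[[i]]
    tr <- .subset_ws(ws, fold$train)
    te <- .subset_ws(ws, fold$test)
    if (balance) {
      tr <- balance_classes(tr, seed = train_cfg$seed + 7919L * i)
    }
    cfg_i <- train_cfg
    cfg_i$seed <- train_cfg$seed + i
    model <- fit_model(spec, tr, cfg_i)
    p <- predict(model, te)
    prob <- rbind(prob, p)
    truth <- rbind(truth, te$labels_onehot)
    pats <- c(pats, te$patient_ids)
    fold_hist[[i]] <- utils::tail(model$history, 1)
    if (verbose) {
      message(sprintf("fold %d/%d (%s): %d train / %d test windows",
                      i, length(plan), fold$test, nrow(tr$windows),
                      nrow(te$windows)))
    }
  }
  rep <- evaluate_predictions(truth, prob, ws$class_order, ci_B = ci_B,
                              ci_seed = train_cfg$seed)
  rep$pooled_prob <- prob
  rep$pooled_truth_onehot <- truth
  rep$pooled_patients <- pats
  rep$fold_history <- do.call(rbind, fold_hist)
  rep
}
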