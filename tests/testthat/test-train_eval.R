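test_that("grouped holdout splits patients, not windows", {
  pats <- sprintf("P%02d", 1:10)
  plan <- grouped_holdout(pats, 0.8, seed = 4)
  expect_length(plan, 1L)
  expect_length(plan[[1]]$train, 8L)
  expect_length(plan[[1]]$test, 2L)
  expect_length(intersect(plan[[1]]$train, plan[[1]]$test), 0L)
  expect_identical(plan, grouped_holdout(pats, 0.8, seed = 4))
  expect_false(identical(plan, grouped_holdout(pats, 0.8, seed = 5)))
  expect_error(grouped_holdout("P1", 0.8, 1), "at least 2")
  # ceiling rule: 3 patients at 0.5 -> 2 train
  expect_length(grouped_holdout(c("a", "b", "c"), 0.5, 1)[[1]]$train, 2L)
})

test_that("LOSO folds partition the cohort exactly once each", {
  plan <- loso_splits(c("a", "b", "c"))
  expect_length(plan, 3L)
  for (f in plan) {
    expect_length(f$train, 2L)
    expect_length(f$test, 1L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  tests <- unlist(lapply(plan, `[[`, "test"))
  expect_setequal(tests, c("a", "b", "c"))
  expect_equal(anyDuplicated(tests), 0L)
  expect_length(loso_splits(sprintf("S%02d", 1:37)), 37L)
  expect_error(loso_splits("solo"), "at least 2")
})

test_that("class balancing equalizes counts by duplication only", {
  set.seed(10)
  n <- 100
  lab <- c(rep("Normal", 30), rep("Arrhythmia", 70))
  enc <- encode_labels(lab, "binary")
  ws <- window_set(matrix(rnorm(n * 20), n), enc$onehot,
                   rep(sprintf("P%d", 1:5), each = 20), enc$class_order)
  bal <- balance_classes(ws, seed = 2)
  counts <- colSums(bal$labels_onehot)
  expect_equal(unname(counts), c(70, 70))
  # every balanced window is an exact copy of an original of the same class
  key <- function(m) apply(round(m, 12), 1, paste, collapse = ",")
  expect_true(all(key(bal$windows) %in% key(ws$windows)))
  expect_identical(balance_classes(ws, seed = 2), bal)
  already <- balance_classes(bal, seed = 3)
  expect_equal(unname(colSums(already$labels_onehot)), c(70, 70))
  solo <- window_set(ws$windows[1:30, ], enc$onehot[1:30, ],
                     ws$patient_ids[1:30], enc$class_order)
  expect_error(balance_classes(solo), "absent")
})

test_that("AUROC equals the exhaustive pairwise oracle", {
  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(F, F, T, T)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(T, F, T, F, T, F)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auroc(scores, labels), pairwise_auc(scores, labels))
  }
})

test_that("the metric suite matches hand-computed counts", {
  # binary confusion [[8,2],[1,9]] (rows truth Normal, Arrhythmia)
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), rep(2, 2), rep(2, 9), 1)
  onehot <- matrix(0, 20, 2)
  onehot[cbind(1:20, truth)] <- 1
  prob <- matrix(0.1, 20, 2)
  prob[cbind(1:20, pred)] <- 0.9
  rep_ <- evaluate_predictions(onehot, prob, c("Normal", "Arrhythmia"))
  expect_equal(unname(rep_$confusion[1, ]), c(8L, 2L))
  expect_equal(unname(rep_$confusion[2, ]), c(1L, 9L))
  expect_equal(rep_$global$accuracy, 85)
  expect_equal(rep_$per_class$sensitivity[2], 90)  # sens(Arrhythmia)
  expect_equal(rep_$per_class$specificity[2], 80)  # spec(Arrhythmia)
  expect_equal(rep_$per_class$sensitivity[1], rep_$per_class$specificity[2])
  expect_equal(rep_$per_class$specificity[1], rep_$per_class$sensitivity[2])
  expect_equal(sum(rep_$confusion), 20)
  # F1 for the positive class: precision 9/11, recall 9/10
  expect_equal(rep_$global$f1, 100 * 2 * (9 / 11) * (9 / 10) /
                 (9 / 11 + 9 / 10))
})

test_that("perfect predictions score 100 everywhere, any K", {
  for (K in c(2L, 5L)) {
    n <- 4L * K
    truth <- rep(seq_len(K), length.out = n)
    onehot <- matrix(0, n, K)
    onehot[cbind(seq_len(n), truth)] <- 1
    rep_ <- evaluate_predictions(onehot, onehot + 1e-6,
                                 paste0("c", seq_len(K)))
    expect_equal(rep_$global$accuracy, 100)
    expect_true(all(rep_$per_class$sensitivity == 100))
    expect_true(all(rep_$per_class$specificity == 100))
  }
})

test_that("binary sensitivity/specificity mirror across classes always", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    truth <- sample(1:2, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    onehot <- matrix(0, n, 2)
    onehot[cbind(1:n, truth)] <- 1
    prob <- matrix(runif(2 * n), n)
    prob <- prob / rowSums(prob)
    r <- evaluate_predictions(onehot, prob, c("Normal", "Arrhythmia"))
    expect_equal(r$per_class$sensitivity[1], r$per_class$specificity[2])
    expect_equal(r$per_class$sensitivity[2], r$per_class$specificity[1])
    expect_equal(sum(r$confusion), n)
  }
})

test_that("bootstrap CIs are seeded, degenerate-safe and cover the point", {
  n <- 100
  set.seed(31)
  truth <- c(rep(1, 50), rep(2, 50))
  onehot <- matrix(0, n, 2)
  onehot[cbind(1:n, truth)] <- 1
  prob2 <- c(rnorm(50, 0.4, 0.15), rnorm(50, 0.7, 0.15))
  prob <- cbind(1 - prob2, prob2)
  ci <- bootstrap_ci(onehot, prob, "auroc", B = 200, seed = 5,
                     class_order = c("Normal", "Arrhythmia"))
  expect_identical(ci, bootstrap_ci(onehot, prob, "auroc", B = 200, seed = 5,
                                    class_order = c("Normal", "Arrhythmia")))
  expect_lt(ci[1], ci[2])
  # perfectly constant metric -> collapsed interval at the point value
  perfect <- cbind(c(rep(0.9, 50), rep(0.1, 50)),
                   c(rep(0.1, 50), rep(0.9, 50)))
  ci0 <- bootstrap_ci(onehot, perfect, "auroc", B = 50, seed = 1,
                      class_order = c("Normal", "Arrhythmia"))
  expect_equal(unname(ci0[1]), 1)
  expect_equal(unname(ci0[2]), 1)
  # the point estimate lies inside its own bootstrap interval across
  # repeated draws from a known sampling distribution
  inside <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    p2 <- c(rnorm(40, 0.45, 0.2), rnorm(40, 0.65, 0.2))
    oh <- matrix(0, 80, 2)
    oh[cbind(1:80, c(rep(1, 40), rep(2, 40)))] <- 1
    pr <- cbind(1 - p2, p2)
    point <- auroc(p2, c(rep(FALSE, 40), rep(TRUE, 40)))
    ci_r <- bootstrap_ci(oh, pr, "auroc", B = 200, seed = r,
                         class_order = c("Normal", "Arrhythmia"))
    if (point >= ci_r[1] && point <= ci_r[2]) inside <- inside + 1L
  }
  expect_gte(inside / reps, 0.95)
})

test_that("the engine overfits a separable toy and is seed-deterministic", {
  ws <- toy_window_set(10)
  spec <- tiny_spec()
  cfg <- train_config(epochs = 30, batch_size = 8, seed = 2)
  m1 <- fit_model(spec, ws, cfg)
  expect_gte(tail(m1$history$accuracy, 1), 0.99)
  pred <- predict(m1, ws, type = "class")
  truth <- ws$class_order[max.col(ws$labels_onehot)]
  expect_gte(mean(pred == truth), 0.99)
  # aggregate loss decreases over training
  expect_lte(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- fit_model(spec, ws, cfg)
  expect_identical(predict(m1, ws), predict(m2, ws))
  m3 <- fit_model(spec, ws, train_config(epochs = 30, batch_size = 8,
                                         seed = 3))
  expect_false(identical(predict(m1, ws), predict(m3, ws)))
})

test_that("probability outputs are calibrated softmax rows", {
  ws <- toy_window_set(4)
  m <- fit_model(tiny_spec(), ws, train_config(epochs = 2, batch_size = 8,
                                               seed = 1))
  p <- predict(m, ws)
  expect_equal(ncol(p), 2L)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_error(predict(m, matrix(0, 2, 50)), "does not match")
  expect_error(fit_model(tiny_spec(n_classes = 5), ws,
                         train_config(epochs = 1)), "label width")
})

test_that("realized models match the analytic parameter count and shapes", {
  ws <- toy_window_set(2, len = 1000)
  specs <- list(reference_spec("mitbih_multiclass"),
                reference_spec("simband_binary"),
                ablation_spec(reference_spec("simband_binary"), "three_conv"),
                ablation_spec(reference_spec("simband_binary"),
                              "kernel_plus_two"))
  for (spec in specs) {
    layers <- ecgcnn:::.with_seed(1, ecgcnn:::.realize_layers(spec))
    realized <- sum(vapply(layers, function(ly) {
      if (is.null(ly$W)) 0 else length(ly$W) + length(ly$b)
    }, numeric(1)))
    expect_identical(as.integer(realized), as.integer(count_parameters(spec)))
    # layer-by-layer forward shapes agree with the analytic trace
    fw <- ecgcnn:::.net_forward(layers, spec, ws$windows[1:2, ],
                                training = FALSE, keep_activations = TRUE)
    tr <- propagate_shapes(spec)
    for (i in seq_along(layers)) {
      a <- fw$activations[[i]]
      if (!is.null(dim(a)) && length(dim(a)) == 3L) {
        expect_equal(dim(a)[1], tr$out_len[i])
        expect_equal(dim(a)[2], tr$out_channels[i])
      } else if (!is.null(dim(a))) {
        expect_equal(ncol(a), tr$out_len[i])
      }
    }
  }
})

test_that("pooled LOSO evaluation conserves windows and avoids leakage", {
  ws <- smoke_window_set()
  sub <- ecgcnn:::.subset_ws(ws, c("P01", "P02", "P03", "P05"))
  rep_ <- evaluate_loso(tiny_spec(input_len = 1000L), sub,
                        train_config(epochs = 2, seed = 11))
  expect_equal(sum(rep_$confusion), nrow(sub$windows))
  expect_equal(nrow(rep_$pooled_prob), nrow(sub$windows))
  expect_setequal(unique(rep_$pooled_patients), unique(sub$patient_ids))
  # each patient's windows appear exactly once in the pooled predictions
  expect_equal(sort(table(rep_$pooled_patients)),
               sort(table(sub$patient_ids)))
})
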