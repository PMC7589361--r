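# Leave-one-subject-out evaluation harness and the macro metric formulas.
#
# All metrics are derived from an l x l confusion matrix (rows = true,
# columns = predicted) through the per-class one-vs-rest counts TP_i, TN_i,
# FP_i, FN_i. Accuracy here is the macro average of the one-vs-rest
# accuracies (the pooled trace/total accuracy is exposed separately as
# `pooled_accuracy`).

#' Build a confusion matrix
#'
#' @param truth,predicted Character vectors of true and predicted labels.
#' @param labels Ordered label set for rows/columns.
#' @return l x l integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, labels) {
  stopifnot(length(truth) == length(predicted))
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  matrix(as.integer(m), nrow = length(labels),
         dimnames = list(truth = labels, predicted = labels))
}

cm_counts <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       p = tp + fn, n = tn + fp, total = total, l = nrow(cm))
}

#' Macro one-vs-rest accuracy
#'
#' Mean over classes of (TP_i + TN_i) / (TP_i + TN_i + FP_i + FN_i).
#'
#' @param cm Confusion matrix (rows = truth).
#' @return Number in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  k <- cm_counts(cm)
  if (k$total == 0) stop("empty confusion matrix")
  mean((k$tp + k$tn) / (k$tp + k$tn + k$fp + k$fn))
}

#' Pooled (micro) accuracy: trace over total
#' @inheritParams accuracy
#' @export
pooled_accuracy <- function(cm) {
  k <- cm_counts(cm)
  if (k$total == 0) stop("empty confusion matrix")
  sum(k$tp) / k$total
}

#' Macro precision and recall
#'
#' Class-averaged TP/(TP+FP) and TP/(TP+FN). A class with a zero
#' denominator (never predicted, resp. never present) contributes 0 with a
#' warning.
#'
#' @inheritParams accuracy
#' @return Named numeric vector `c(precision=, recall=)`.
#' @export
precision_recall <- function(cm) {
  k <- cm_counts(cm)
  safe <- function(num, den, what) {
    z <- den == 0
    if (any(z))
      warning("zero denominator for ", what, " in class(es) ",
              paste(rownames(as.matrix(cm))[z], collapse = ", "),
              "; contributing 0")
    ifelse(z, 0, num / den)
  }
  c(precision = mean(safe(k$tp, k$tp + k$fp, "precision")),
    recall = mean(safe(k$tp, k$tp + k$fn, "recall")))
}

#' Macro F1 score
#'
#' Harmonic mean of the macro precision and macro recall; 0 (with a
#' warning) when both are 0.
#'
#' @inheritParams accuracy
#' @export
f1 <- function(cm) {
  pr <- precision_recall(cm)
  if (pr[["precision"]] + pr[["recall"]] == 0) {
    warning("precision and recall both 0; F1 set to 0")
    return(0)
  }
  2 * pr[["precision"]] * pr[["recall"]] /
    (pr[["precision"]] + pr[["recall"]])
}

#' Balanced accuracy
#'
#' (sum_i TP_i/P_i + sum_i TN_i/N_i) / (2 l): the average of per-class
#' true-positive and true-negative rates.
#'
#' @inheritParams accuracy
#' @export
balanced_accuracy <- function(cm) {
  k <- cm_counts(cm)
  if (any(k$p == 0))
    stop("class(es) with zero positive samples: ",
         paste(rownames(as.matrix(cm))[k$p == 0], collapse = ", "))
  if (any(k$n == 0))
    stop("class(es) with zero negative samples")
  (sum(k$tp / k$p) + sum(k$tn / k$n)) / (2 * k$l)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 divisor) divided by the mean; used to
#' compare the fold-to-fold consistency of a metric across LOSO folds.
#'
#' @param metric_values At least 2 numbers with non-zero mean.
#' @export
cov_metric <- function(metric_values) {
  if (length(metric_values) < 2L) stop("need at least 2 values")
  mu <- mean(metric_values)
  if (mu == 0) stop("CoV undefined: mean is 0")
  stats::sd(metric_values) / mu
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; the test split holds all and only that subject's
#' episodes.
#'
#' @param dataset A [make_dataset] object with at least 2 subjects.
#' @return List of `list(test_subject, train_idx, test_idx)` in subject
#'   sort order.
#' @export
loso_splits <- function(dataset) {
  subj <- dataset_subjects(dataset)
  u <- sort(unique(subj))
  if (length(u) < 2L)
    stop("LOSO requires at least 2 subjects; found ", length(u))
  lapply(u, function(s)
    list(test_subject = s,
         train_idx = which(subj != s),
         test_idx = which(subj == s)))
}

#' Kruskal-Wallis comparison of two metric groups
#'
#' Rank test for a difference between two sets of CoV (or other metric)
#' values, as used to compare classifier families across body sites.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return The Kruskal-Wallis p-value (tie-corrected).
#' @export
kruskal_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  vals <- c(group_a, group_b)
  if (length(unique(vals)) == 1L)
    stop("degenerate statistic: all values identical across both groups")
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  stats::kruskal.test(vals, g)$p.value
}

fold_metrics <- function(cm) {
  pr <- suppressWarnings(precision_recall(cm))
  c(accuracy = accuracy(cm),
    precision = pr[["precision"]], recall = pr[["recall"]],
    f1 = suppressWarnings(f1(cm)),
    balanced_accuracy = tryCatch(balanced_accuracy(cm),
                                 error = function(e) NA_real_))
}

# train the requested model on the fold's training episodes and predict the
# held-out episodes
fit_and_predict <- function(model_spec, train_eps, train_lab, test_eps,
                            vocab, seed, adalstm_epochs = NULL) {
  switch(model_spec,
    ensemble = {
      w <- training_window_length(train_eps)
      spec <- windowing_spec(w)
      Xtr <- t(vapply(train_eps, episode_meta_features, numeric(48),
                      spec = spec))
      Xte <- t(vapply(test_eps, episode_meta_features, numeric(48),
                      spec = spec))
      mdl <- train_ensemble(Xtr, train_lab, n_trees = 100L, seed = seed,
                            label_vocabulary = vocab)
      predict_ensemble(mdl, Xte)
    },
    lda = {
      mdl <- train_baseline("lda_means", train_eps, train_lab,
                            label_vocabulary = vocab, reg = 1e-6)
      predict_baseline(mdl, test_eps)
    },
    svm = {
      mdl <- train_baseline("svm_linear_means", train_eps, train_lab,
                            label_vocabulary = vocab)
      predict_baseline(mdl, test_eps)
    },
    adalstm = ,
    lstm_fixed = {
      cfg <- adalstm_config(
        classes = vocab, seed = seed,
        lr_schedule = if (model_spec == "adalstm") "piecewise" else "constant",
        max_epochs = adalstm_epochs %||% 100L)
      mdl <- build_adalstm(cfg)
      fit <- adalstm_train(mdl, train_eps, train_lab)
      adalstm_predict(fit$model, test_eps)
    },
    stop("unknown model_spec: ", model_spec))
}

#' Run leave-one-subject-out evaluation of a model at one body site
#'
#' Episodes at the site are magnitude-normalized, split into LOSO folds,
#' and the requested model is trained on each fold's training split
#' (meta-features with the window length recomputed from that fold's
#' training episodes only, mean features, or raw sequences, as the model
#' requires) and evaluated on the held-out subject. Folds whose training
#' split contains a single class are skipped with a warning.
#'
#' @param dataset A [make_dataset] object.
#' @param model_spec One of `"ensemble"`, `"adalstm"`, `"lda"`, `"svm"`,
#'   `"lstm_fixed"`.
#' @param site Body site to evaluate.
#' @param seed Integer seed covering all of the run's randomness.
#' @param adalstm_epochs Optional epoch override for the sequence models
#'   (reduced-scale runs).
#' @param normalize Magnitude-normalize episodes first (default `TRUE`).
#' @return List: `folds` (per-fold list with test_subject, confusion matrix
#'   and metrics), `summary` (data frame of mean, sd and CoV per metric),
#'   `confusion` (summed confusion matrix).
#' @export
run_loso <- function(dataset, model_spec, site, seed,
                     adalstm_epochs = NULL, normalize = TRUE) {
  ds <- filter_sites(dataset, site)
  if (!n_episodes(ds)) stop("no episodes at site ", site)
  if (normalize) ds$episodes <- lapply(ds$episodes, normalize_episode)
  vocab <- intersect(ds$label_vocabulary, unique(dataset_postures(ds)))
  splits <- loso_splits(ds)
  labs <- dataset_postures(ds)
  folds <- list()
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    train_lab <- labs[sp$train_idx]
    if (length(unique(train_lab)) < 2L) {
      warning("fold for subject ", sp$test_subject,
              " skipped: single-class training split")
      next
    }
    pred <- fit_and_predict(model_spec, ds$episodes[sp$train_idx], train_lab,
                            ds$episodes[sp$test_idx], vocab,
                            seed = seed + k, adalstm_epochs = adalstm_epochs)
    cm <- confusion_matrix(labs[sp$test_idx], pred, vocab)
    folds[[length(folds) + 1L]] <- list(test_subject = sp$test_subject,
                                        confusion = cm,
                                        metrics = fold_metrics(cm))
  }
  if (!length(folds)) stop("no usable LOSO folds")
  mt <- t(vapply(folds, `[[`, numeric(5), "metrics"))
  summarise <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = stats::sd(v),
      cov = if (length(v) >= 2 && mean(v) != 0) stats::sd(v) / mean(v)
            else NA_real_)
  }
  sm <- t(apply(mt, 2, summarise))
  summary <- data.frame(metric = rownames(sm), sm, row.names = NULL)
  confusion <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  list(model_spec = model_spec, site = site, seed = seed,
       folds = folds, summary = summary, confusion = confusion)
}
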