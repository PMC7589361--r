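# Linear baselines operating on the 3 per-axis episode means: an LDA
# classifier and a one-vs-rest linear-kernel SVM. Both stand in for the
# simplest published single-accelerometer posture detectors, which classify
# the episode-mean gravity direction.

#' Per-axis mean features of episodes
#'
#' @param episodes List of episodes.
#' @return n x 3 matrix of per-axis episode means.
#' @export
episode_axis_means <- function(episodes) {
  t(vapply(episodes, function(ep) colMeans(ep$samples), numeric(3)))
}

#' Train a linear baseline on per-axis episode means
#'
#' `kind = "lda_means"`: Gaussian equal-covariance discriminant analysis on
#' the 3 mean features, with an optional ridge term on the pooled
#' within-class covariance. `kind = "svm_linear_means"`: multi-class linear
#' SVM (one-vs-rest, squared hinge loss, L2 penalty) trained by gradient
#' descent on the same 3 features.
#'
#' @param kind `"lda_means"` or `"svm_linear_means"`.
#' @param episodes List of episodes.
#' @param labels Posture label per episode.
#' @param label_vocabulary Ordered vocabulary (tie-break order).
#' @param reg LDA ridge regularization added to the within-class covariance
#'   diagonal (default 0: a singular covariance is an error suggesting
#'   `reg`).
#' @param svm_lambda,svm_iter,svm_lr SVM L2 weight, gradient-descent
#'   iterations and learning rate.
#' @return A `baseline_model` object.
#' @export
train_baseline <- function(kind = c("lda_means", "svm_linear_means"),
                           episodes, labels, label_vocabulary = POSTURES,
                           reg = 0, svm_lambda = 1e-3, svm_iter = 500L,
                           svm_lr = 0.1) {
  kind <- match.arg(kind)
  X <- episode_axis_means(episodes)
  labels <- as.character(labels)
  vocab <- intersect(label_vocabulary, unique(labels))
  if (length(vocab) < 2L) stop("need at least 2 classes")
  yi <- match(labels, vocab)
  K <- length(vocab)
  fit <- if (kind == "lda_means") {
    counts <- tabulate(yi, nbins = K)
    if (any(counts < 2L))
      stop("LDA requires at least 2 episodes per class")
    means <- t(vapply(seq_len(K), function(k)
      colMeans(X[yi == k, , drop = FALSE]), numeric(3)))
    centered <- X - means[yi, ]
    W <- crossprod(centered) / (nrow(X) - K) + diag(reg, 3)
    Winv <- tryCatch(solve(W), error = function(e)
      stop("singular within-class covariance; pass a small ridge via ",
           "`reg` (e.g. reg = 1e-6) to regularize", call. = FALSE))
    if (kappa(W) > 1e12 && reg == 0)
      stop("near-singular within-class covariance; pass a small ridge via ",
           "`reg` (e.g. reg = 1e-6) to regularize", call. = FALSE)
    priors <- counts / sum(counts)
    list(means = means, Winv = Winv, priors = priors)
  } else {
    # one-vs-rest squared-hinge SVM, full-batch gradient descent
    mu <- colMeans(X); sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- scale(X, center = mu, scale = sdev)
    Wt <- matrix(0, K, 3); b <- numeric(K)
    for (k in seq_len(K)) {
      y <- ifelse(yi == k, 1, -1)
      w <- numeric(3); b0 <- 0
      for (it in seq_len(svm_iter)) {
        f <- drop(Xs %*% w) + b0
        slack <- pmax(0, 1 - y * f)
        gw <- svm_lambda * w - crossprod(Xs, 2 * slack * y) / nrow(Xs)
        gb <- -mean(2 * slack * y)
        w <- w - svm_lr * gw
        b0 <- b0 - svm_lr * gb
      }
      Wt[k, ] <- w; b[k] <- b0
    }
    list(W = Wt, b = b, center = mu, scale = sdev)
  }
  structure(list(kind = kind, fit = fit, label_vocabulary = vocab),
            class = "baseline_model")
}

#' Predict postures with a linear baseline
#'
#' @param model A [train_baseline] model.
#' @param episodes List of episodes to classify.
#' @return Character vector of predicted labels (vocabulary-order
#'   tie-break).
#' @export
predict_baseline <- function(model, episodes) {
  X <- episode_axis_means(episodes)
  vocab <- model$label_vocabulary
  scores <- if (model$kind == "lda_means") {
    f <- model$fit
    t(apply(X, 1, function(x)
      vapply(seq_along(vocab), function(k) {
        m <- f$means[k, ]
        drop(x %*% f$Winv %*% m) - 0.5 * drop(m %*% f$Winv %*% m) +
          log(f$priors[k])
      }, numeric(1))))
  } else {
    f <- model$fit
    Xs <- scale(X, center = f$center, scale = f$scale)
    Xs %*% t(f$W) + rep(f$b, each = nrow(Xs))
  }
  vocab[apply(scores, 1, which.max)]
}
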