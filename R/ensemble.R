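# Bagged decision-tree ensemble with majority voting.
#
# Trees are grown on one-hot-coded class indicators with a variance-reduction
# (sum-of-squared-error) split criterion, so that the "mean squared error
# decrease" feature importance is well-defined for classification. Each tree
# sees a bootstrap resample and a random subset of the features, drawn once
# per tree.

# node impurity: SSE of one-hot indicators = n - sum(counts^2)/n
node_sse <- function(counts, n) if (n == 0) 0 else n - sum(counts^2) / n

grow_tree <- function(X, yi, K, min_leaf = 1L, max_depth = Inf) {
  # X: n x p numeric; yi: integer class indices 1..K
  nodes <- list()
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx, depth) {
    n <- length(idx)
    counts <- tabulate(yi[idx], nbins = K)
    sse <- node_sse(counts, n)
    make_leaf <- function() add_node(list(
      leaf = TRUE, counts = counts, pred = which.max(counts)))
    if (sse == 0 || n < 2L * min_leaf || depth >= max_depth)
      return(make_leaf())
    best <- list(gain = 0)
    for (j in seq_len(ncol(X))) {
      x <- X[idx, j]
      o <- order(x)
      xs <- x[o]; ys <- yi[idx][o]
      cum <- matrix(0, n, K)
      cum[cbind(seq_len(n), ys)] <- 1
      cum <- apply(cum, 2, cumsum)
      sq1 <- rowSums(cum^2)
      totals <- cum[n, ]
      sq2 <- rowSums((rep(totals, each = n) - cum)^2)
      split_ok <- seq_len(n - 1L)
      split_ok <- split_ok[xs[split_ok] < xs[split_ok + 1L] &
                             split_ok >= min_leaf &
                             (n - split_ok) >= min_leaf]
      if (!length(split_ok)) next
      gains <- sq1[split_ok] / split_ok +
        sq2[split_ok] / (n - split_ok) - sum(counts^2) / n
      b <- which.max(gains)
      if (gains[b] > best$gain + 1e-12) {
        s <- split_ok[b]
        best <- list(gain = gains[b], feature = j,
                     threshold = (xs[s] + xs[s + 1L]) / 2)
      }
    }
    if (best$gain <= 0) return(make_leaf())
    go_left <- X[idx, best$feature] <= best$threshold
    # the midpoint of two adjacent floating-point values can round up onto
    # the larger one, leaving an empty child; treat as unsplittable
    if (all(go_left) || !any(go_left)) return(make_leaf())
    self <- add_node(list(leaf = FALSE, feature = best$feature,
                          threshold = best$threshold, gain = best$gain,
                          left = NA, right = NA))
    l <- build(idx[go_left], depth + 1L)
    r <- build(idx[!go_left], depth + 1L)
    nodes[[self]]$left <<- l
    nodes[[self]]$right <<- r
    self
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, x) {
  i <- tree$root
  repeat {
    nd <- tree$nodes[[i]]
    if (nd$leaf) return(nd$pred)
    i <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
  }
}

# per-tree importance: sum of split SSE decreases per feature, divided by
# the number of branch (internal) nodes of that tree
tree_importance <- function(tree, p) {
  imp <- numeric(p)
  n_branch <- 0L
  for (nd in tree$nodes) {
    if (!nd$leaf) {
      imp[nd$feature] <- imp[nd$feature] + nd$gain
      n_branch <- n_branch + 1L
    }
  }
  if (n_branch > 0L) imp / n_branch else imp
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  as.matrix(features)
}

#' Train a bagged decision-tree ensemble
#'
#' Fits `n_trees` decision trees, each on a bootstrap resample of the
#' episodes (same size as the training set, with replacement) restricted to a
#' random feature subset drawn once per tree. Prediction is by majority vote.
#'
#' @param features Matrix (episodes x features), data frame, or list of
#'   meta-feature vectors.
#' @param labels Posture label per episode.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; training is fully reproducible given it.
#' @param label_vocabulary Ordered vocabulary; its order breaks voting ties.
#' @param mtry Features per tree; default `floor(sqrt(p))` (7 of the 48).
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param max_depth Maximum tree depth (default unlimited).
#' @return An `ensemble_model` object.
#' @export
train_ensemble <- function(features, labels, n_trees = 100L, seed,
                           label_vocabulary = POSTURES, mtry = NULL,
                           min_leaf = 1L, max_depth = Inf) {
  X <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    stop("features and labels disagree in length")
  vocab <- intersect(label_vocabulary, unique(labels))
  if (length(vocab) < 2L)
    stop("training data must contain at least 2 distinct labels")
  yi <- match(labels, vocab)
  p <- ncol(X)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  rng <- local_rng(seed)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- rng$sample_int(nrow(X), nrow(X), replace = TRUE)
    feats <- sort(rng$sample_int(p, min(mtry, p)))
    fit <- grow_tree(X[boot, feats, drop = FALSE], yi[boot],
                     K = length(vocab), min_leaf = min_leaf,
                     max_depth = max_depth)
    trees[[b]] <- list(tree = fit, features = feats, bootstrap = boot)
  }
  structure(list(trees = trees, n_trees = n_trees, p = p,
                 label_vocabulary = vocab, seed = seed, mtry = mtry),
            class = "ensemble_model")
}

#' Predict postures by majority vote over the ensemble's trees
#'
#' Ties are broken in favour of the label earliest in the vocabulary order.
#'
#' @param model An [train_ensemble] model.
#' @param features One 48-vector, or a matrix/data frame of rows to classify.
#' @return Character vector of predicted labels.
#' @export
predict_ensemble <- function(model, features) {
  if (!inherits(model, "ensemble_model")) stop("model is not trained")
  X <- as_feature_matrix(if (is.null(dim(features)) && !is.list(features))
    matrix(features, nrow = 1) else features)
  K <- length(model$label_vocabulary)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    votes <- tabulate(vapply(model$trees, function(tr)
      predict_tree(tr$tree, X[i, tr$features]), integer(1)), nbins = K)
    out[i] <- model$label_vocabulary[which.max(votes)]
  }
  out
}

#' Ensemble feature importance
#'
#' For each tree, every split's decrease in the one-hot-indicator sum of
#' squared errors is credited to the split feature; per-tree credits are
#' divided by that tree's branch-node count, then averaged across trees.
#' Features never used by any tree score 0.
#'
#' @param model An [train_ensemble] model.
#' @param feature_names Optional names for the report.
#' @return List with `importance` (numeric, length p) and `ranking`
#'   (feature indices, most important first).
#' @export
feature_importance <- function(model, feature_names = NULL) {
  if (!inherits(model, "ensemble_model")) stop("model is not trained")
  imp <- numeric(model$p)
  for (tr in model$trees) {
    ti <- tree_importance(tr$tree, length(tr$features))
    imp[tr$features] <- imp[tr$features] + ti
  }
  imp <- imp / model$n_trees
  if (is.null(feature_names) && model$p == 48L)
    feature_names <- FEATURE_NAMES
  if (!is.null(feature_names)) names(imp) <- feature_names
  list(importance = imp, ranking = order(imp, decreasing = TRUE))
}
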