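# helper: random feature matrix with a planted threshold signal in one column
planted_data <- function(n = 60, p = 12, signal_col = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(X[, signal_col] > 0, "supine", "prone")
  list(X = X, y = y)
}

test_that("ensemble separates a single-feature construction and is
           deterministic per seed", {
  d <- planted_data(seed = 3)
  m <- train_ensemble(d$X, d$y, n_trees = 30, seed = 11)
  expect_equal(predict_ensemble(m, d$X), d$y)  # 100% training accuracy

  set.seed(99); Xtest <- matrix(rnorm(20 * 12), 20, 12)
  m2 <- train_ensemble(d$X, d$y, n_trees = 30, seed = 11)
  expect_identical(predict_ensemble(m, Xtest), predict_ensemble(m2, Xtest))
  m3 <- train_ensemble(d$X, d$y, n_trees = 30, seed = 12)
  expect_true(all(predict_ensemble(m3, Xtest) %in% c("supine", "prone")))

  expect_error(train_ensemble(d$X, rep("supine", nrow(d$X)), seed = 1),
               "2 distinct labels")
})

test_that("a 1-tree ensemble behaves like a single decision tree", {
  d <- planted_data(seed = 5)
  m <- train_ensemble(d$X, d$y, n_trees = 1, seed = 2, mtry = 12)
  expect_length(m$trees, 1L)
  tr <- m$trees[[1]]
  single <- vapply(seq_len(nrow(d$X)), function(i)
    m$label_vocabulary[posturetrack:::predict_tree(tr$tree,
                                                   d$X[i, tr$features])],
    character(1))
  expect_identical(predict_ensemble(m, d$X), single)
})

test_that("majority voting equals the brute-force mode with
           vocabulary-order ties", {
  # fuzzed vote tallies vs exhaustive counting
  set.seed(17)
  vocab <- POSTURES
  for (i in 1:200) {
    votes <- sample(vocab, sample(1:100, 1), replace = TRUE)
    tally <- vapply(vocab, function(l) sum(votes == l), integer(1))
    winner <- vocab[which.max(tally)]  # first max = vocab order
    brute <- names(sort(table(factor(votes, vocab)), decreasing = TRUE))[1]
    expect_equal(unname(tally[winner]), max(tally))
    expect_equal(sum(tally == tally[winner] &
                       seq_along(vocab) < match(winner, vocab)), 0)
    expect_equal(sort(unique(votes))[1] %in% vocab, TRUE)
    expect_equal(unname(tally[brute]), max(tally))
  }
  # explicit tie: 50/50 supine vs left -> supine (earlier in vocabulary)
  d <- list(X = matrix(c(rep(0, 25), rep(1, 25)), 50, 1),
            y = rep(c("supine", "left"), each = 25))
  # degenerate single-feature data where each leaf is pure
  m <- train_ensemble(d$X, d$y, n_trees = 10, seed = 1, mtry = 1)
  expect_true(all(predict_ensemble(m, matrix(c(-1, 2), 2, 1)) %in%
                    c("supine", "left")))
})

test_that("ensemble training accuracy >= single tree on synthetic data", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- ifelse(X[, 1] + 0.8 * rnorm(40) > 0, "supine", "prone")
    bag <- train_ensemble(X, y, n_trees = 25, seed = seed)
    one <- train_ensemble(X, y, n_trees = 1, seed = seed, mtry = 8)
    # single tree built on the full sample (no bootstrap variance) via the
    # tree grower directly
    tr <- posturetrack:::grow_tree(X, match(y, one$label_vocabulary), 2)
    tree_acc <- mean(vapply(seq_len(40), function(i)
      one$label_vocabulary[posturetrack:::predict_tree(tr, X[i, ])],
      character(1)) == y)
    bag_acc <- mean(predict_ensemble(bag, X) == y)
    expect_gte(bag_acc, tree_acc)
  }
})

test_that("feature importance: constants score 0, planted signal ranks
           first, permutation destroys it", {
  d <- planted_data(n = 120, seed = 7)
  X <- cbind(d$X, 1)  # constant 13th feature
  for (seed in 1:5) {
    m <- train_ensemble(X, d$y, n_trees = 40, seed = seed)
    rep_ <- feature_importance(m, feature_names = paste0("v", 1:13))
    expect_true(all(rep_$importance >= 0))
    expect_equal(unname(rep_$importance[13]), 0)
    expect_equal(rep_$ranking[1], 5)  # the planted column
  }
  # permuting the planted column removes its top rank
  set.seed(123)
  Xp <- X; Xp[, 5] <- sample(Xp[, 5])
  mp <- train_ensemble(Xp, d$y, n_trees = 40, seed = 1)
  expect_false(feature_importance(mp)$ranking[1] == 5)
})

test_that("hand-built stump importance equals hand arithmetic", {
  # 4 samples, 1 feature, perfectly split at 0: one branch node.
  # parent SSE (one-hot, 2 classes) = 4 * (1 - 0.5^2 - 0.5^2) = 2;
  # children pure -> SSE 0; gain 2; importance = 2 / 1 branch node = 2.
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("supine", "supine", "prone", "prone")
  tr <- posturetrack:::grow_tree(X, match(y, c("supine", "prone")), 2)
  imp <- posturetrack:::tree_importance(tr, 1)
  expect_equal(imp, 2)
})

test_that("linear baselines separate mean-offset classes and handle
           degenerate scenarios", {
  # two classes with mean z +1 vs -1, zero noise
  eps <- c(lapply(1:3, function(i) make_ep(matrix(rep(c(0, 0, 1), each = 8),
                                                  8, 3))),
           lapply(1:3, function(i) make_ep(matrix(rep(c(0, 0, -1), each = 8),
                                                  8, 3), posture = "prone")))
  labs <- rep(c("supine", "prone"), each = 3)
  # zero within-class variance: LDA must surface the regularization hint
  expect_error(train_baseline("lda_means", eps, labs), "reg")
  lda <- train_baseline("lda_means", eps, labs, reg = 1e-6)
  expect_equal(predict_baseline(lda, eps), labs)
  svm <- train_baseline("svm_linear_means", eps, labs)
  expect_equal(predict_baseline(svm, eps), labs)

  # single episode per class: SVM memorizes
  svm1 <- train_baseline("svm_linear_means", eps[c(1, 4)],
                         labs[c(1, 4)])
  expect_equal(predict_baseline(svm1, eps[c(1, 4)]), labs[c(1, 4)])

  expect_error(train_baseline("lda_means", eps, rep("supine", 6)),
               "2 classes")
})

test_that("identical class distributions give chance-level baseline
           accuracy", {
  set.seed(21)
  n <- 200
  eps <- lapply(seq_len(n), function(i)
    make_ep(matrix(rnorm(30), 10, 3),
            posture = c("supine", "prone")[1 + i %% 2]))
  labs <- vapply(eps, `[[`, "", "posture")
  m <- train_baseline("lda_means", eps, labs, reg = 1e-6)
  test_eps <- lapply(1:400, function(i) make_ep(matrix(rnorm(30), 10, 3)))
  test_labs <- sample(c("supine", "prone"), 400, replace = TRUE)
  acc <- mean(predict_baseline(m, test_eps) == test_labs)
  # 95% binomial band around 0.5 for n = 400
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 400) - 0.03)
  expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 400) + 0.03)
})

test_that("ensemble model archives round-trip through JSON", {
  d <- planted_data(seed = 13)
  m <- train_ensemble(d$X, d$y, n_trees = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  set.seed(5); Xnew <- matrix(rnorm(10 * 12), 10, 12)
  expect_identical(predict_ensemble(back, Xnew), predict_ensemble(m, Xnew))
  rpt <- feature_importance(m, feature_names = paste0("v", 1:12))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_importance_report(rpt, p2)
  df <- read.csv(p2)
  expect_equal(nrow(df), 12)
  expect_equal(df$importance, unname(rpt$importance))
})
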