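# AdaLSTM: bidirectional LSTM sequence classifier for raw tri-axial
# accelerometer episodes. One LSTM scans the sequence forward and one
# backward; the two terminal hidden states (forward state at the last true
# sample, backward state at the first sample) are concatenated and passed
# through three fully connected layers and a softmax, giving one posture
# label per episode. Training minimizes a length-weighted cross-entropy (the
# loss of sequence i is scaled by its length m_i) with Adam and a decaying
# learning-rate schedule. Everything -- forward pass, backpropagation
# through time, Adam -- is implemented here in plain R and is deterministic
# for a fixed seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' AdaLSTM configuration
#'
#' @param classes Ordered label vocabulary (K >= 2); order breaks argmax
#'   ties.
#' @param hidden_units LSTM hidden units per direction (default 10).
#' @param fc_hidden Sizes of the first two fully connected layers (the third
#'   maps to the K classes); default `c(10, 10)`.
#' @param max_epochs Training epochs (default 100).
#' @param initial_lr Initial Adam learning rate (default 0.01).
#' @param squared_grad_decay Decay rate of the squared-gradient moving
#'   average, Adam's beta2 (default 0.99).
#' @param batch_size Mini-batch size (default 27); batches are formed after
#'   sorting episodes by length to shorten padding.
#' @param lr_schedule `"piecewise"` (multiply by `drop_factor` every
#'   `drop_every_epochs` epochs) or `"constant"`. The constant schedule with
#'   the defaults reproduces the fixed-learning-rate LSTM baseline.
#' @param drop_factor,drop_every_epochs Piecewise schedule parameters
#'   (defaults 0.5 and 20).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An `adalstm_config` list.
#' @export
adalstm_config <- function(classes, hidden_units = 10L, fc_hidden = c(10L, 10L),
                           max_epochs = 100L, initial_lr = 0.01,
                           squared_grad_decay = 0.99, batch_size = 27L,
                           lr_schedule = c("piecewise", "constant"),
                           drop_factor = 0.5, drop_every_epochs = 20L,
                           seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  if (length(classes) < 2L) stop("need at least 2 classes")
  stopifnot(hidden_units >= 1, max_epochs >= 1, batch_size >= 1,
            initial_lr > 0, squared_grad_decay > 0, squared_grad_decay < 1)
  structure(list(classes = classes, hidden_units = as.integer(hidden_units),
                 fc_hidden = as.integer(fc_hidden),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr,
                 squared_grad_decay = squared_grad_decay,
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, drop_factor = drop_factor,
                 drop_every_epochs = as.integer(drop_every_epochs),
                 seed = as.integer(seed)),
            class = "adalstm_config")
}

init_mat <- function(rng, nr, nc, fan_in) {
  r <- 1 / sqrt(fan_in)
  matrix(rng$runif(nr * nc, -r, r), nr, nc)
}

#' Build an (untrained) AdaLSTM model
#'
#' Parameter initialization is uniform in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' with forget-gate biases set to 1, and is deterministic under the config
#' seed.
#'
#' @param config An [adalstm_config].
#' @return An `adalstm_model` with untrained parameters.
#' @export
build_adalstm <- function(config) {
  H <- config$hidden_units
  K <- length(config$classes)
  rng <- local_rng(config$seed)
  dir_params <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget gate bias
    list(Wx = init_mat(rng, 3, 4 * H, 3),
         Wh = init_mat(rng, H, 4 * H, H),
         b = b)
  }
  sizes <- c(2 * H, config$fc_hidden, K)
  fc <- lapply(seq_len(length(sizes) - 1L), function(l)
    list(W = init_mat(rng, sizes[l], sizes[l + 1L], sizes[l]),
         b = numeric(sizes[l + 1L])))
  structure(list(config = config, fwd = dir_params(), bwd = dir_params(),
                 fc = fc, trained = FALSE),
            class = "adalstm_model")
}

# ---- batching -------------------------------------------------------------

# Pad episodes into a [T, B, 3] array with a B x T validity mask.
prep_batch <- function(episodes, classes, labels = NULL) {
  B <- length(episodes)
  lens <- vapply(episodes, episode_length, integer(1))
  T_ <- max(lens)
  X <- array(0, c(T_, B, 3))
  mask <- matrix(0, B, T_)
  for (i in seq_len(B)) {
    X[seq_len(lens[i]), i, ] <- episodes[[i]]$samples
    mask[i, seq_len(lens[i])] <- 1
  }
  Y <- NULL
  if (!is.null(labels)) {
    yi <- match(as.character(labels), classes)
    if (anyNA(yi)) stop("label outside the model's class vocabulary")
    Y <- matrix(0, B, length(classes))
    Y[cbind(seq_len(B), yi)] <- 1
  }
  list(X = X, mask = mask, lengths = lens, Y = Y, B = B, T = T_)
}

# ---- forward / backward through one LSTM direction ------------------------

lstm_scan <- function(batch, par, reverse = FALSE, keep_cache = TRUE) {
  T_ <- batch$T; B <- batch$B; H <- ncol(par$Wh) / 4L
  ord <- if (reverse) T_:1 else 1:T_
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (s in seq_len(T_)) {
    t <- ord[s]
    Xt <- matrix(batch$X[t, , ], nrow = B)
    Z <- Xt %*% par$Wx + h %*% par$Wh +
      rep(par$b, each = B)
    i_ <- sigmoid(Z[, 1:H, drop = FALSE])
    f_ <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_hat <- f_ * c_ + i_ * g_
    hc <- tanh(c_hat)
    h_hat <- o_ * hc
    m <- batch$mask[, t]
    if (keep_cache)
      cache[[s]] <- list(Xt = Xt, h_prev = h, c_prev = c_, i = i_, f = f_,
                         g = g_, o = o_, hc = hc, m = m)
    h <- m * h_hat + (1 - m) * h
    c_ <- m * c_hat + (1 - m) * c_
  }
  list(h_final = h, cache = cache, ord = ord)
}

lstm_backward <- function(scan, par, dh_final) {
  H <- ncol(par$Wh) / 4L
  gWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  gWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  gb <- numeric(length(par$b))
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), H)
  for (s in rev(seq_along(scan$cache))) {
    st <- scan$cache[[s]]
    m <- st$m
    dh_hat <- m * dh
    dh_pass <- (1 - m) * dh
    dc_hat <- m * dc
    dc_pass <- (1 - m) * dc
    do_ <- dh_hat * st$hc
    dhc <- dh_hat * st$o
    dc_hat <- dc_hat + dhc * (1 - st$hc^2)
    df <- dc_hat * st$c_prev
    di <- dc_hat * st$g
    dg <- dc_hat * st$i
    dc_prev <- dc_hat * st$f + dc_pass
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    gWx <- gWx + crossprod(st$Xt, dZ)
    gWh <- gWh + crossprod(st$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- dh_pass + dZ %*% t(par$Wh)
    dc <- dc_prev
  }
  list(Wx = gWx, Wh = gWh, b = gb)
}

# ---- full network forward and gradients -----------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

adalstm_forward <- function(model, batch, keep_cache = FALSE) {
  fwd <- lstm_scan(batch, model$fwd, reverse = FALSE, keep_cache = keep_cache)
  bwd <- lstm_scan(batch, model$bwd, reverse = TRUE, keep_cache = keep_cache)
  A <- list(cbind(fwd$h_final, bwd$h_final))
  Zs <- list()
  for (l in seq_along(model$fc)) {
    Z <- A[[l]] %*% model$fc[[l]]$W + rep(model$fc[[l]]$b, each = batch$B)
    Zs[[l]] <- Z
    A[[l + 1L]] <- if (l < length(model$fc)) tanh(Z) else Z
  }
  probs <- softmax_rows(A[[length(A)]])
  list(probs = probs, A = A, Zs = Zs, fwd = fwd, bwd = bwd)
}

#' Length-weighted cross-entropy loss
#'
#' The sequence-classification objective: the cross-entropy between one-hot
#' labels and predicted class probabilities, with each sequence's term
#' multiplied by its length weight, summed (not averaged) over the batch.
#' True-class probabilities below 1e-12 are clamped with a warning.
#'
#' @param predictions Numeric B x K matrix; each row a probability vector.
#' @param labels_onehot Numeric B x K one-hot matrix.
#' @param weights Numeric length-B vector of sequence lengths m_i.
#' @return Non-negative scalar; 0 iff every true-class probability is 1.
#' @export
weighted_cross_entropy <- function(predictions, labels_onehot, weights) {
  predictions <- as.matrix(predictions)
  labels_onehot <- as.matrix(labels_onehot)
  stopifnot(nrow(predictions) == nrow(labels_onehot),
            nrow(predictions) == length(weights))
  p_true <- rowSums(predictions * labels_onehot)
  if (any(p_true < 1e-12)) {
    warning("true-class probability below 1e-12 clamped")
    p_true <- pmax(p_true, 1e-12)
  }
  -sum(weights * log(p_true))
}

# loss + full analytic gradient for one batch (same parameter layout as the
# model); used by the Adam loop and by the numerical gradient check
adalstm_loss_grads <- function(model, batch) {
  fw <- adalstm_forward_cached(model, batch)
  loss <- weighted_cross_entropy(fw$probs, batch$Y, batch$lengths)
  dZ <- (fw$probs - batch$Y) * batch$lengths  # row-scaled by m_i
  grads <- list(fc = vector("list", length(model$fc)))
  dA <- dZ
  for (l in rev(seq_along(model$fc))) {
    if (l < length(model$fc)) dA <- dA * (1 - tanh(fw$Zs[[l]])^2)
    grads$fc[[l]] <- list(W = crossprod(fw$A[[l]], dA),
                          b = colSums(dA))
    dA <- dA %*% t(model$fc[[l]]$W)
  }
  H <- model$config$hidden_units
  grads$fwd <- lstm_backward(fw$fwd, model$fwd, dA[, 1:H, drop = FALSE])
  grads$bwd <- lstm_backward(fw$bwd, model$bwd,
                             dA[, (H + 1):(2 * H), drop = FALSE])
  list(loss = loss, grads = grads)
}

adalstm_forward_cached <- function(model, batch)
  adalstm_forward(model, batch, keep_cache = TRUE)

# ---- Adam over the nested parameter list ----------------------------------

param_walk <- function(model, fun) {
  model$fwd <- Map(fun, model$fwd, list("fwd.Wx", "fwd.Wh", "fwd.b"))
  model$bwd <- Map(fun, model$bwd, list("bwd.Wx", "bwd.Wh", "bwd.b"))
  for (l in seq_along(model$fc))
    model$fc[[l]] <- Map(fun, model$fc[[l]],
                         as.list(paste0("fc", l, ".", c("W", "b"))))
  model
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(theta, g, key) {
    m <- state$m[[key]] %||% (theta * 0)
    v <- state$v[[key]] %||% (theta * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[key]] <<- m
    state$v[[key]] <<- v
    theta - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  grad_of <- function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] %in% c("fwd", "bwd")) grads[[parts[1]]][[parts[2]]]
    else grads$fc[[as.integer(sub("fc", "", parts[1]))]][[parts[2]]]
  }
  model <- param_walk(model, function(theta, key)
    upd(theta, grad_of(key), key))
  list(model = model, state = state)
}

epoch_lr <- function(config, epoch) {
  if (config$lr_schedule == "constant") return(config$initial_lr)
  config$initial_lr *
    config$drop_factor^((epoch - 1L) %/% config$drop_every_epochs)
}

#' Train an AdaLSTM model
#'
#' Episodes are sorted by length and cut into mini-batches of
#' `config$batch_size` (minimizing padding); batch order is reshuffled every
#' epoch. Optimization is Adam with beta2 equal to the configured
#' squared-gradient decay, under the configured learning-rate schedule,
#' minimizing the length-weighted cross-entropy summed over sequences.
#' Fully deterministic for a fixed config seed.
#'
#' @param model A [build_adalstm] model.
#' @param episodes Training episodes (at least one per class).
#' @param labels Posture label per episode.
#' @param max_epochs Optional override of the config's epoch count.
#' @return List: `model` (trained), `trace` (data frame with epoch, lr,
#'   sum_loss, mean_loss).
#' @export
adalstm_train <- function(model, episodes, labels,
                          max_epochs = model$config$max_epochs) {
  config <- model$config
  labels <- as.character(labels)
  if (length(episodes) != length(labels))
    stop("episodes and labels disagree in length")
  if (!all(labels %in% config$classes))
    stop("labels outside configured classes")
  lens <- vapply(episodes, episode_length, integer(1))
  ord <- order(lens)
  episodes <- episodes[ord]; labels <- labels[ord]
  n <- length(episodes)
  starts <- seq.int(1L, n, by = config$batch_size)
  batches <- lapply(starts, function(s) {
    idx <- s:min(s + config$batch_size - 1L, n)
    prep_batch(episodes[idx], config$classes, labels[idx])
  })
  rng <- local_rng(config$seed + 1L)
  state <- list(t = 0L, m = list(), v = list())
  trace <- data.frame(epoch = integer(), lr = numeric(),
                      sum_loss = numeric(), mean_loss = numeric())
  for (epoch in seq_len(max_epochs)) {
    lr <- epoch_lr(config, epoch)
    total <- 0
    for (bi in rng$sample_int(length(batches), length(batches))) {
      lg <- adalstm_loss_grads(model, batches[[bi]])
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      total <- total + lg$loss
      st <- adam_step(model, lg$grads, state, lr,
                      beta2 = config$squared_grad_decay)
      model <- st$model; state <- st$state
    }
    trace <- rbind(trace, data.frame(epoch = epoch, lr = lr,
                                     sum_loss = total,
                                     mean_loss = total / n))
  }
  model$trained <- TRUE
  list(model = model, trace = trace)
}

#' Predict posture labels for episodes
#'
#' Each episode gets the argmax of its softmax output; exact ties go to the
#' label earliest in the class vocabulary. Predictions are independent of
#' how episodes are grouped into batches.
#'
#' @param model An [build_adalstm] (trained or freshly initialized) model.
#' @param episodes List of episodes; empty list gives empty output.
#' @param batch_size Inference batch size.
#' @return Character vector of predicted labels.
#' @export
adalstm_predict <- function(model, episodes,
                            batch_size = model$config$batch_size) {
  if (!length(episodes)) return(character())
  probs <- adalstm_probs(model, episodes, batch_size)
  model$config$classes[apply(probs, 1, which.max)]
}

#' @rdname adalstm_predict
#' @return For `adalstm_probs`: an n x K matrix of class probabilities.
#' @export
adalstm_probs <- function(model, episodes,
                          batch_size = model$config$batch_size) {
  n <- length(episodes)
  out <- matrix(NA_real_, n, length(model$config$classes))
  for (s in seq.int(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- prep_batch(episodes[idx], model$config$classes)
    out[idx, ] <- adalstm_forward(model, batch)$probs
  }
  out
}
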