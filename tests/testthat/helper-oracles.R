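# Independent oracles, deliberately coded straight from the defining
# formulas (scalar loops, no shared code with R/): a second implementation
# of the 48-feature catalogue, and a brute-force one-vs-rest metric oracle.

make_ep <- function(samples, subject = "S01", site = "chest",
                    posture = "supine", rate = 30) {
  episode(subject, site, posture, rate, samples)
}

rand_window <- function(n = 96, scale = 1) {
  matrix(stats::rnorm(n * 3, 0, scale), n, 3)
}

# --- feature oracle --------------------------------------------------------

oracle_axis_entropy <- function(v) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(0)
  edges <- lo + (hi - lo) * (0:16) / 16
  counts <- integer(16)
  for (s in v) {
    b <- 16
    for (j in 1:16) if (s <= edges[j + 1]) { b <- j; break }
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / length(v)
      h <- h - p * log(p)
    }
  }
  h
}

oracle_axis_zcr <- function(v) {
  ch <- 0
  if (length(v) >= 2)
    for (i in 2:length(v))
      if (sign(v[i]) * sign(v[i - 1]) < 0) ch <- ch + 1
  ch / length(v)
}

oracle_features <- function(W) {
  n <- nrow(W)
  out <- numeric(48)
  for (a in 1:3) {
    v <- W[, a]
    mu <- sum(v) / n
    vr <- if (n > 1) sum((v - mu)^2) / (n - 1) else 0
    sg <- sqrt(vr)
    out[a] <- max(v) - mu                              # AMP
    out[3 + a] <- stats::median(v)                     # MED
    out[6 + a] <- mu                                   # MEAN
    out[9 + a] <- max(v)                               # MAX
    out[12 + a] <- min(v)                              # MIN
    out[15 + a] <- vr                                  # VAR
    out[18 + a] <- sg                                  # STD
    out[21 + a] <- sqrt(sum(v^2) / n)                  # RMS
    out[24 + a] <- max(v) - min(v)                     # P2P
    out[27 + a] <- oracle_axis_zcr(v)                  # ZCR
    out[30 + a] <- oracle_axis_entropy(v)              # ENT
    out[33 + a] <- if (sg == 0) 0 else sum((v - mu)^3) / n / sg^3  # SKN
    out[36 + a] <- if (sg == 0) 0 else sum((v - mu)^4) / n / sg^4  # KRT
    out[41 + a] <- max(v) - min(v)                     # RNG
    out[45 + a] <- sum(abs(v - mu)) / n                # MAD
  }
  mag <- 0; eng <- 0; ang <- -Inf
  for (i in 1:n) {
    mag <- mag + sqrt(W[i, 1]^2 + W[i, 2]^2 + W[i, 3]^2)
    eng <- eng + W[i, 1]^2 + W[i, 2]^2 + W[i, 3]^2
    ang <- max(ang, atan2(W[i, 3], sqrt(W[i, 1]^2 + W[i, 2]^2)))
  }
  out[40] <- mag / n
  out[41] <- eng
  out[45] <- ang
  out
}

# --- metric oracle ---------------------------------------------------------

# one-vs-rest counts computed by explicit relabeling, then the formula
oracle_metrics <- function(cm) {
  l <- nrow(cm)
  acc <- prec <- rec <- tpr <- tnr <- numeric(l)
  total <- sum(cm)
  for (i in 1:l) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    acc[i] <- (tp + tn) / (tp + tn + fp + fn)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    tpr[i] <- tp / (tp + fn)
    tnr[i] <- tn / (tn + fp)
  }
  p <- mean(prec); r <- mean(rec)
  list(accuracy = mean(acc), precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       balanced_accuracy = (sum(tpr) + sum(tnr)) / (2 * l))
}

# small zero-noise simulation config used across tests
noiseless_config <- function(n_subjects = 3, sites = "chest", seed = 11,
                             ...) {
  simulation_config(n_subjects = n_subjects, sites = sites, seed = seed,
                    jitter_sd = 0, subject_rotation_sd_deg = 0,
                    movement_burst_rate = 0, ...)
}
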