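# Sliding-window segmentation and the 48 time-domain features used by the
# classical posture classifier. Feature indices/names follow the fixed
# catalogue below; within each per-axis triple the order is (x, y, z).

#' Names of the 48 time-domain features, in catalogue order
#' @export
FEATURE_NAMES <- c(
  sprintf("f%02d_%s_%s", 1:39,
          rep(c("amp", "med", "mean", "max", "min", "var", "std", "rms",
                "p2p", "zcr", "ent", "skn", "krt"), each = 3),
          rep(c("x", "y", "z"), 13)),
  "f40_mag", "f41_eng",
  sprintf("f%02d_rng_%s", 42:44, c("x", "y", "z")),
  "f45_ang",
  sprintf("f%02d_mad_%s", 46:48, c("x", "y", "z")))

#' Windowing specification for feature extraction
#'
#' @param window_samples Window length in samples.
#' @param overlap_fraction Fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0.5 (50% overlap). The step is
#'   `round(window_samples * (1 - overlap_fraction))`, at least 1.
#' @return A `windowing_spec` object.
#' @export
windowing_spec <- function(window_samples, overlap_fraction = 0.5) {
  stopifnot(window_samples >= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  step <- max(1L, as.integer(round(window_samples * (1 - overlap_fraction))))
  structure(list(window_samples = as.integer(window_samples),
                 overlap_fraction = overlap_fraction, step = step),
            class = "windowing_spec")
}

#' Window length from a training set
#'
#' The window size is set to the minimum episode length over the training
#' episodes, so that every training episode yields at least one full window.
#'
#' @param training_episodes Non-empty list of episodes.
#' @return Integer minimum length.
#' @export
training_window_length <- function(training_episodes) {
  if (!length(training_episodes)) stop("training episode list is empty")
  min(vapply(training_episodes, episode_length, integer(1)))
}

#' Slice an episode into sliding windows
#'
#' Windows start at sample 1, 1+step, 1+2*step, ... and are all full length.
#' An episode shorter than the window (possible for held-out test episodes,
#' since the window length is fixed on the training set) yields exactly one
#' window covering the whole episode.
#'
#' @param ep An [episode].
#' @param spec A [windowing_spec].
#' @return List of N x 3 sample matrices.
#' @export
sliding_windows <- function(ep, spec) {
  n <- episode_length(ep)
  w <- spec$window_samples
  if (n < w) return(list(ep$samples))
  starts <- seq.int(1L, n - w + 1L, by = spec$step)
  lapply(starts, function(s) ep$samples[s:(s + w - 1L), , drop = FALSE])
}

entropy16 <- function(v) {
  # histogram entropy over the window's own range, 16 bins, natural log
  r <- range(v)
  if (r[1] == r[2]) return(0)
  b <- seq(r[1], r[2], length.out = 17L)
  counts <- tabulate(findInterval(v, b, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = 16L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

zcr_axis <- function(v, literal = FALSE) {
  n <- length(v)
  if (literal) return(sum(v == 0) / n)
  if (n < 2L) return(0)
  s <- sign(v)
  sum(s[-1] * s[-n] < 0) / n
}

#' Compute the 48 time-domain features of one window
#'
#' Per axis: peak amplitude (max - mean), median, mean, max, min, sample
#' variance, standard deviation, RMS, peak-to-peak, zero-crossing rate,
#' histogram entropy, skewness, kurtosis, range and mean absolute deviation;
#' plus three scalars: mean vector magnitude, total signal energy, and the
#' maximum elevation angle of the acceleration vector above the x-y plane.
#' Skewness/kurtosis use the population third/fourth moments over the sample
#' standard deviation and are defined as 0 for constant windows.
#'
#' @param window N x 3 numeric matrix (one sliding window's samples).
#' @param literal_zcr If `TRUE`, use the literal exact-zero counting rate
#'   instead of the sign-change rate (the standard definition, default).
#' @return Named numeric vector of length 48 ([FEATURE_NAMES]).
#' @export
compute_window_features <- function(window, literal_zcr = FALSE) {
  window <- as.matrix(window)
  n <- nrow(window)
  if (n < 1L) stop("window must contain at least one sample")
  per_axis <- function(fn) vapply(1:3, function(a) fn(window[, a]), numeric(1))
  mu <- colMeans(window)
  mx <- apply(window, 2, max)
  mn <- apply(window, 2, min)
  v <- if (n > 1) apply(window, 2, stats::var) else c(0, 0, 0)
  sdv <- sqrt(v)
  skn <- vapply(1:3, function(a) {
    if (sdv[a] == 0) return(0)
    mean((window[, a] - mu[a])^3) / sdv[a]^3
  }, numeric(1))
  krt <- vapply(1:3, function(a) {
    if (sdv[a] == 0) return(0)
    mean((window[, a] - mu[a])^4) / sdv[a]^4
  }, numeric(1))
  mags <- sqrt(rowSums(window^2))
  out <- c(
    mx - mu,                                   # AMP 1-3
    per_axis(stats::median),                   # MED 4-6
    mu,                                        # MEAN 7-9
    mx,                                        # MAX 10-12
    mn,                                        # MIN 13-15
    v,                                         # VAR 16-18
    sdv,                                       # STD 19-21
    sqrt(colMeans(window^2)),                  # RMS 22-24
    mx - mn,                                   # P2P 25-27
    per_axis(function(x) zcr_axis(x, literal_zcr)),  # ZCR 28-30
    per_axis(entropy16),                       # ENT 31-33
    skn,                                       # SKN 34-36
    krt,                                       # KRT 37-39
    mean(mags),                                # MAG 40
    sum(window^2),                             # ENG 41
    mx - mn,                                   # RNG 42-44
    max(atan2(window[, 3],
              sqrt(window[, 1]^2 + window[, 2]^2))),  # ANG 45
    colMeans(abs(sweep(window, 2, mu))))       # MAD 46-48
  names(out) <- FEATURE_NAMES
  out
}

#' Per-episode meta-features
#'
#' The component-wise mean of the window feature vectors over an episode's
#' sliding windows; one 48-vector per episode, the input to the classical
#' models.
#'
#' @param ep An [episode].
#' @param spec A [windowing_spec].
#' @inheritParams compute_window_features
#' @return Named numeric vector of length 48.
#' @export
episode_meta_features <- function(ep, spec, literal_zcr = FALSE) {
  wins <- sliding_windows(ep, spec)
  feats <- vapply(wins, compute_window_features, numeric(48),
                  literal_zcr = literal_zcr)
  rowMeans(feats)
}

#' Meta-feature table for a whole dataset
#'
#' @param dataset A [make_dataset] object.
#' @param spec A [windowing_spec]; if `NULL`, the window length is the
#'   minimum episode length in `dataset` with 50% overlap.
#' @return Data frame: subject, site, posture keys plus the 48 feature
#'   columns `f01_amp_x` ... `f48_mad_z`.
#' @export
dataset_feature_table <- function(dataset, spec = NULL) {
  if (is.null(spec))
    spec <- windowing_spec(training_window_length(dataset$episodes))
  feats <- t(vapply(dataset$episodes, episode_meta_features, numeric(48),
                    spec = spec))
  cbind(data.frame(subject = dataset_subjects(dataset),
                   site = dataset_sites(dataset),
                   posture = dataset_postures(dataset),
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}
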