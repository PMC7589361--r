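#' @keywords internal
"_PACKAGE"

#' Recognized body sites and posture labels
#'
#' Nine wearing sites for a single tri-axial accelerometer and the four major
#' lying postures the package classifies.
#'
#' @format Character vectors.
#' @export
BODY_SITES <- c("chest", "thigh_L", "thigh_R", "ankle_L", "ankle_R",
                "arm_L", "arm_R", "wrist_L", "wrist_R")

#' @rdname BODY_SITES
#' @export
POSTURES <- c("supine", "prone", "left", "right")

#' Construct a lying-posture episode
#'
#' An episode is one subject's contiguous tri-axial accelerometer recording
#' while holding a single lying posture at one body site; it is the unit of
#' classification throughout the package.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param body_site One of [BODY_SITES].
#' @param posture Posture label, normally one of [POSTURES].
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param samples Numeric N x 3 matrix of accelerations in g units,
#'   columns (ax, ay, az). N >= 1, no missing values.
#' @return An object of class `"episode"`.
#' @export
episode <- function(subject_id, body_site, posture, sampling_rate_hz, samples) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L)
    stop("`samples` must be a numeric N x 3 matrix (ax, ay, az)")
  if (nrow(samples) < 1L)
    stop("episode must contain at least one sample")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("episode samples must be finite and non-missing")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a positive number")
  if (!body_site %in% BODY_SITES)
    stop("unknown body site: ", body_site)
  colnames(samples) <- c("ax", "ay", "az")
  structure(
    list(subject_id = as.character(subject_id),
         body_site = body_site,
         posture = as.character(posture),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         samples = unname(samples)),
    class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> subject %s | %s | %s | %d samples @ %g Hz\n",
              x$subject_id, x$body_site, x$posture,
              nrow(x$samples), x$sampling_rate_hz))
  invisible(x)
}

#' Number of samples in an episode
#' @param ep An [episode].
#' @export
episode_length <- function(ep) nrow(ep$samples)

#' Construct a dataset of episodes
#'
#' @param episodes List of [episode] objects.
#' @param name Dataset name.
#' @param label_vocabulary Ordered posture vocabulary; every episode's posture
#'   must be a member. The order is used for deterministic tie-breaking in
#'   classifiers.
#' @return An object of class `"posture_dataset"`.
#' @export
make_dataset <- function(episodes, name = "dataset",
                         label_vocabulary = POSTURES) {
  stopifnot(is.list(episodes))
  for (ep in episodes) {
    if (!inherits(ep, "episode")) stop("all elements must be episodes")
    if (!ep$posture %in% label_vocabulary)
      stop("episode posture '", ep$posture, "' not in label vocabulary")
  }
  structure(
    list(name = name, episodes = episodes,
         label_vocabulary = label_vocabulary),
    class = "posture_dataset")
}

#' @export
print.posture_dataset <- function(x, ...) {
  tab <- table(factor(vapply(x$episodes, `[[`, "", "posture"),
                      levels = x$label_vocabulary))
  cat(sprintf("<posture_dataset> '%s': %d episodes\n", x$name,
              length(x$episodes)))
  if (length(x$episodes)) print(tab)
  invisible(x)
}

#' Dataset accessors
#'
#' Episode count and per-episode posture/subject/site vectors of a dataset.
#'
#' @param ds A [make_dataset] object.
#' @export
n_episodes <- function(ds) length(ds$episodes)

#' @rdname n_episodes
#' @export
dataset_postures <- function(ds)
  vapply(ds$episodes, `[[`, character(1), "posture")

#' @rdname n_episodes
#' @export
dataset_subjects <- function(ds)
  vapply(ds$episodes, `[[`, character(1), "subject_id")

#' @rdname n_episodes
#' @export
dataset_sites <- function(ds)
  vapply(ds$episodes, `[[`, character(1), "body_site")

#' Restrict a dataset to selected body sites
#'
#' @param dataset A [make_dataset] object.
#' @param sites Character vector of body sites to keep.
#' @return A `posture_dataset` containing only matching episodes.
#' @export
filter_sites <- function(dataset, sites) {
  keep <- dataset_sites(dataset) %in% sites
  make_dataset(dataset$episodes[keep], name = dataset$name,
               label_vocabulary = dataset$label_vocabulary)
}

#' Normalize an episode by scalar magnitude rescaling
#'
#' Rescales all three axes by a single scalar so that the median per-sample
#' vector magnitude equals `target_gravity`. Axis ratios -- hence the
#' gravity-orientation information the classifiers rely on -- are unchanged.
#' This removes subject- or device-level gain differences (e.g. a sensor
#' reporting in raw analog units rather than g).
#'
#' @param ep An [episode].
#' @param target_gravity Target median magnitude, in g (default 1).
#' @return A rescaled copy of the episode.
#' @export
normalize_episode <- function(ep, target_gravity = 1.0) {
  mags <- sqrt(rowSums(ep$samples^2))
  med <- stats::median(mags)
  if (med <= 0)
    stop("degenerate episode: median sample magnitude is zero")
  ep$samples <- ep$samples * (target_gravity / med)
  ep
}

#' Segment a continuous recording into posture episodes by its label track
#'
#' Splits a raw recording at every change of label; each maximal run of a
#' constant non-null label becomes one episode, and null-labeled samples
#' (`NA`) are discarded.
#'
#' @param raw An [episode]-like recording (its `posture` field is ignored).
#' @param labels Character vector of per-sample posture labels, `NA` for
#'   unlabeled samples; must have one entry per sample.
#' @return List of episodes, in temporal order. All-null tracks give an
#'   empty list.
#' @export
segment_by_labels <- function(raw, labels) {
  n <- episode_length(raw)
  if (length(labels) != n)
    stop("label track length (", length(labels),
         ") does not match recording length (", n, ")")
  if (all(is.na(labels))) return(list())
  # run-length encode, keeping NA runs distinct
  key <- ifelse(is.na(labels), "\r<null>", labels)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == "\r<null>") next
    out[[length(out) + 1L]] <- episode(
      raw$subject_id, raw$body_site, r$values[k], raw$sampling_rate_hz,
      raw$samples[starts[k]:ends[k], , drop = FALSE])
  }
  out
}

#' Re-segment an episode into fixed-duration chunks
#'
#' Cuts an episode into consecutive non-overlapping segments of exactly
#' `floor(segment_seconds * rate)` samples, inheriting all metadata. A
#' trailing remainder shorter than one segment is dropped. Used to bring long
#' constant-posture recordings (e.g. 300 s activity-protocol runs) to the
#' typical in-bed episode duration before dataset integration.
#'
#' @param ep An [episode].
#' @param segment_seconds Segment duration in seconds.
#' @return List of episodes; empty if the episode is shorter than one segment.
#' @export
resegment_episode <- function(ep, segment_seconds) {
  w <- floor(segment_seconds * ep$sampling_rate_hz)
  if (w < 1) stop("segment_seconds * sampling_rate_hz must be >= 1")
  n <- episode_length(ep)
  k <- n %/% w
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    episode(ep$subject_id, ep$body_site, ep$posture, ep$sampling_rate_hz,
            ep$samples[((i - 1L) * w + 1L):(i * w), , drop = FALSE])
  })
}

#' Merge a secondary dataset into a primary one
#'
#' Resegments every secondary episode into `resegment_seconds` chunks, then
#' per label draws a uniform random subsample without replacement of the
#' requested size, and merges the result with the primary episodes restricted
#' to the shared body sites. Deterministic for a fixed seed.
#'
#' @param primary,secondary [make_dataset] objects.
#' @param shared_sites Body sites present in both datasets; the output is
#'   restricted to these.
#' @param resegment_seconds Chunk length applied to secondary episodes.
#' @param subsample_counts Named integer vector, label -> number of secondary
#'   chunks to retain. Labels absent from the map are dropped entirely.
#' @param seed Integer seed for the subsampling draw.
#' @return Integrated `posture_dataset`.
#' @export
integrate_datasets <- function(primary, secondary, shared_sites,
                               resegment_seconds, subsample_counts, seed) {
  prim <- filter_sites(primary, shared_sites)
  sec <- filter_sites(secondary, shared_sites)
  chunks <- unlist(lapply(sec$episodes, resegment_episode,
                          segment_seconds = resegment_seconds),
                   recursive = FALSE)
  lab <- vapply(chunks, `[[`, character(1), "posture")
  picked <- list()
  rng <- local_rng(seed)
  for (l in names(subsample_counts)) {
    idx <- which(lab == l)
    k <- subsample_counts[[l]]
    if (k > length(idx))
      stop("requested ", k, " episodes of label '", l, "' but only ",
           length(idx), " available after resegmentation")
    picked <- c(picked, chunks[sort(rng$sample(idx, k))])
  }
  make_dataset(c(prim$episodes, picked),
               name = paste0(primary$name, "+", secondary$name),
               label_vocabulary = union(primary$label_vocabulary,
                                        secondary$label_vocabulary))
}

#' Per-posture axis summary at one body site
#'
#' For each posture and axis, the mean and standard deviation of the
#' acceleration pooled over all samples of all matching episodes. This is the
#' raw-data inspection that reveals the per-posture gravity signatures: for a
#' chest sensor the horizontal axis carries supine/prone (~ +0.92 / -0.78 g)
#' and the lateral axis carries the side postures.
#'
#' @param dataset A [make_dataset] object.
#' @param site Body site to summarize.
#' @return Data frame with columns posture, axis, mean, sd (population sd,
#'   0 for a single pooled sample). Empty when no episodes match.
#' @export
posture_axis_summary <- function(dataset, site) {
  eps <- dataset$episodes[dataset_sites(dataset) == site]
  out <- data.frame(posture = character(), axis = character(),
                    mean = numeric(), sd = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(eps)) return(out)
  postures <- vapply(eps, `[[`, character(1), "posture")
  for (p in intersect(dataset$label_vocabulary, unique(postures))) {
    pooled <- do.call(rbind, lapply(eps[postures == p], `[[`, "samples"))
    for (a in 1:3) {
      v <- pooled[, a]
      out <- rbind(out, data.frame(
        posture = p, axis = c("x", "y", "z")[a],
        mean = mean(v),
        sd = sqrt(mean((v - mean(v))^2)),
        stringsAsFactors = FALSE))
    }
  }
  out
}
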