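# Dataset I/O: one CSV per episode (columns t, ax, ay, az) plus a manifest
# CSV (file, subject, site, posture, rate_hz). The `t` column is written for
# human inspection and ignored on read.

#' Read a dataset from a manifest of episode CSV files
#'
#' @param manifest_path Path to a manifest CSV with columns
#'   `file,subject,site,posture,rate_hz`; `file` is relative to the manifest's
#'   directory.
#' @param label_vocabulary Allowed posture labels.
#' @param scale Optional scalar divisor applied to all accelerations on read,
#'   for datasets recorded on a raw (non-g) scale, e.g. `scale = 10` for a
#'   sensor whose gravity-aligned axis reads about +/-10.
#' @param name Dataset name; defaults to the manifest file name.
#' @return A [make_dataset] object; row order of each CSV is sample order.
#' @export
read_dataset <- function(manifest_path, label_vocabulary = POSTURES,
                         scale = 1.0, name = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("file", "subject", "site", "posture", "rate_hz")
  if (!all(needed %in% names(man)))
    stop("manifest must have columns ", paste(needed, collapse = ","))
  base <- dirname(manifest_path)
  eps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$file[i])
    if (!file.exists(f)) stop("episode file not found: ", f)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("ax", "ay", "az") %in% names(d)))
      stop("episode file ", f, " must have columns ax,ay,az")
    m <- as.matrix(d[, c("ax", "ay", "az")])
    if (!is.numeric(m) || anyNA(m)) {
      bad <- which(is.na(suppressWarnings(
        matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
      stop("non-numeric acceleration in ", f, " at row ",
           if (nrow(bad)) bad[1, 1] else NA)
    }
    if (!man$posture[i] %in% label_vocabulary)
      stop("unknown posture label '", man$posture[i], "' in manifest row ", i)
    eps[[i]] <- episode(man$subject[i], man$site[i], man$posture[i],
                        as.numeric(man$rate_hz[i]), m / scale)
  }
  make_dataset(eps, name = name %||% basename(manifest_path),
               label_vocabulary = label_vocabulary)
}

#' Write a dataset as episode CSVs plus a manifest
#'
#' Lossless round-trip partner of [read_dataset]: accelerations are printed
#' with 12 significant digits.
#'
#' @param dataset A [make_dataset] object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  n <- n_episodes(dataset)
  files <- character(n)
  for (i in seq_len(n)) {
    ep <- dataset$episodes[[i]]
    files[i] <- sprintf("episode_%04d.csv", i)
    tm <- (seq_len(episode_length(ep)) - 1L) / ep$sampling_rate_hz
    df <- data.frame(t = format(tm, digits = 12, trim = TRUE),
                     ax = format(ep$samples[, 1], digits = 12, trim = TRUE),
                     ay = format(ep$samples[, 2], digits = 12, trim = TRUE),
                     az = format(ep$samples[, 3], digits = 12, trim = TRUE))
    utils::write.csv(df, file.path(out_dir, files[i]),
                     row.names = FALSE, quote = FALSE)
  }
  man <- data.frame(
    file = files,
    subject = if (n) dataset_subjects(dataset) else character(),
    site = if (n) dataset_sites(dataset) else character(),
    posture = if (n) dataset_postures(dataset) else character(),
    rate_hz = vapply(dataset$episodes, `[[`, numeric(1), "sampling_rate_hz"),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Read a JSON run configuration
#'
#' Configuration files carry dataset-level conventions (axis roles, raw-unit
#' scale, label vocabulary) and optional model/simulation sub-configurations.
#'
#' @param path Path to a JSON file.
#' @return Named list with defaults filled in (`axis_roles`, `scale`,
#'   `label_vocabulary`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$axis_roles <- cfg$axis_roles %||%
    c(x = "lateral", y = "vertical", z = "horizontal")
  cfg$scale <- cfg$scale %||% 1.0
  cfg$label_vocabulary <- cfg$label_vocabulary %||% POSTURES
  cfg
}
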