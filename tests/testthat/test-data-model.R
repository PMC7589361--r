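test_that("episode construction validates its invariants", {
  m <- matrix(c(0, 0, 1), 1, 3)
  ep <- episode("S01", "chest", "supine", 25, m)
  expect_s3_class(ep, "episode")
  expect_equal(episode_length(ep), 1L)
  expect_error(episode("S01", "chest", "supine", 0, m), "positive")
  expect_error(episode("S01", "chest", "supine", 25, m[0, , drop = FALSE]),
               "at least one sample")
  expect_error(episode("S01", "nowhere", "supine", 25, m), "body site")
  expect_error(episode("S01", "chest", "supine", 25,
                       matrix(c(NA, 0, 1), 1, 3)), "finite")
})

test_that("dataset round-trip I/O is lossless", {
  synth <- simulate_dataset(simulation_config(n_subjects = 5, sites = "chest",
                                              episodes_per_posture = 2,
                                              duration_mean_s = 3,
                                              duration_sd_s = 1, seed = 4))
  ds <- synth$dataset
  expect_equal(n_episodes(ds), 40L)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  back <- read_dataset(manifest)
  expect_equal(n_episodes(back), n_episodes(ds))
  for (i in seq_len(n_episodes(ds))) {
    a <- ds$episodes[[i]]; b <- back$episodes[[i]]
    expect_identical(a$subject_id, b$subject_id)
    expect_identical(a$body_site, b$body_site)
    expect_identical(a$posture, b$posture)
    expect_equal(a$sampling_rate_hz, b$sampling_rate_hz)
    expect_equal(a$samples, b$samples, tolerance = 1e-10)
  }
})

test_that("empty dataset round-trips and read errors are specific", {
  dir <- withr::local_tempdir()
  manifest <- write_dataset(make_dataset(list()), dir)
  expect_equal(n_episodes(read_dataset(manifest)), 0L)

  # missing episode file
  man2 <- file.path(dir, "bad_manifest.csv")
  writeLines(c("file,subject,site,posture,rate_hz",
               "missing.csv,S01,chest,supine,25"), man2)
  expect_error(read_dataset(man2), "missing.csv")

  # non-numeric acceleration
  writeLines(c("t,ax,ay,az", "0,0,0,oops"), file.path(dir, "ep.csv"))
  man3 <- file.path(dir, "man3.csv")
  writeLines(c("file,subject,site,posture,rate_hz",
               "ep.csv,S01,chest,supine,25"), man3)
  expect_error(read_dataset(man3), "non-numeric")

  # unknown posture
  writeLines(c("t,ax,ay,az", "0,0,0,1"), file.path(dir, "ep2.csv"))
  man4 <- file.path(dir, "man4.csv")
  writeLines(c("file,subject,site,posture,rate_hz",
               "ep2.csv,S01,chest,sideways,25"), man4)
  expect_error(read_dataset(man4), "posture")
})

test_that("read_dataset applies the raw-unit scale option", {
  dir <- withr::local_tempdir()
  writeLines(c("t,ax,ay,az", "0,0,0,9.2", "0.04,0,0,9.2"),
             file.path(dir, "ep.csv"))
  writeLines(c("file,subject,site,posture,rate_hz",
               "ep.csv,S01,chest,supine,25"), file.path(dir, "man.csv"))
  ds <- read_dataset(file.path(dir, "man.csv"), scale = 10)
  expect_equal(ds$episodes[[1]]$samples[, 3], c(0.92, 0.92))
})

test_that("normalize_episode is a pure scalar rescale: idempotent and
           scale-invariant", {
  ep <- make_ep(matrix(c(0, 0, 9.81), 1, 3))
  out <- normalize_episode(ep)
  expect_equal(out$samples, matrix(c(0, 0, 1), 1, 3))

  set.seed(42)
  ep2 <- make_ep(rand_window(60) + rep(c(0, 0, 1), each = 60))
  n1 <- normalize_episode(ep2)
  # already-normalized input is unchanged; scaling the input changes nothing
  expect_equal(normalize_episode(n1)$samples, n1$samples, tolerance = 1e-12)
  ep3 <- ep2; ep3$samples <- ep3$samples * 3.7
  expect_equal(normalize_episode(ep3)$samples, n1$samples, tolerance = 1e-9)
  # orientation (axis ratios) preserved
  expect_equal(n1$samples[5, ] / ep2$samples[5, ],
               rep(n1$samples[5, 1] / ep2$samples[5, 1], 3))
  expect_error(normalize_episode(make_ep(matrix(0, 4, 3))), "degenerate")
})

test_that("segment_by_labels splits on label runs and conserves samples", {
  raw <- make_ep(matrix(seq_len(300), 100, 3))
  out <- segment_by_labels(raw, rep("supine", 100))
  expect_length(out, 1L)
  expect_equal(episode_length(out[[1]]), 100L)

  labels <- c(rep("supine", 50), rep(NA, 10), rep("prone", 40))
  out <- segment_by_labels(raw, labels)
  expect_length(out, 2L)
  expect_equal(vapply(out, episode_length, integer(1)), c(50L, 40L))
  expect_equal(vapply(out, `[[`, "", "posture"), c("supine", "prone"))
  # concatenation reproduces the labeled subsequence in order
  expect_equal(do.call(rbind, lapply(out, `[[`, "samples")),
               raw$samples[!is.na(labels), ])

  expect_equal(segment_by_labels(raw, rep(NA_character_, 100)), list())
  expect_error(segment_by_labels(raw, rep("supine", 99)), "length")

  # fuzz: total output length == count of non-null labels
  set.seed(7)
  for (case in 1:100) {
    n <- sample(5:80, 1)
    rawf <- make_ep(matrix(rnorm(3 * n), n, 3))
    labs <- sample(c(POSTURES, NA), n, replace = TRUE)
    segs <- segment_by_labels(rawf, labs)
    expect_equal(sum(vapply(segs, episode_length, integer(1))),
                 sum(!is.na(labs)))
  }
})

test_that("resegment_episode cuts exact segments and drops the remainder", {
  ep <- make_ep(matrix(rnorm(7500 * 3), 7500, 3), rate = 25)
  segs <- resegment_episode(ep, 20)
  expect_length(segs, 15L)
  expect_true(all(vapply(segs, episode_length, integer(1)) == 500L))
  expect_identical(segs[[3]]$posture, ep$posture)

  expect_length(resegment_episode(make_ep(matrix(0.5, 500, 3), rate = 25), 20),
                1L)
  ep2 <- make_ep(matrix(rnorm(7499 * 3), 7499, 3), rate = 25)
  expect_length(resegment_episode(ep2, 20), 14L)
  # conservation: segments + remainder = input
  segs2 <- resegment_episode(ep2, 20)
  expect_equal(sum(vapply(segs2, episode_length, integer(1))) + 7499 %% 500,
               7499)
  expect_equal(resegment_episode(make_ep(matrix(1, 10, 3), rate = 25), 20),
               list())
})

test_that("integrate_datasets resegments, subsamples and merges
           deterministically", {
  # 8 DAS-style 300 s episodes each of supine and right side, 25 Hz
  das <- simulate_dataset(simulation_config(
    n_subjects = 8, sites = "chest", duration_fixed_s = 300,
    sampling_rate_hz = 25, postures = c("supine", "right"),
    jitter_sd = 0.02, movement_burst_rate = 0, seed = 9))$dataset
  primary <- simulate_dataset(simulation_config(
    n_subjects = 4, sites = c("chest", "thigh_L"),
    postures = c("supine", "prone", "left"), seed = 10))$dataset

  counts <- c(right = 80L, supine = 8L)
  out <- integrate_datasets(primary, das, shared_sites = "chest",
                            resegment_seconds = 20,
                            subsample_counts = counts, seed = 3)
  tab <- table(dataset_postures(out))
  prim_chest <- filter_sites(primary, "chest")
  expect_equal(unname(tab[["right"]]), 80L)
  expect_equal(unname(tab[["supine"]]),
               8L + sum(dataset_postures(prim_chest) == "supine"))
  expect_true(all(dataset_sites(out) == "chest"))

  out2 <- integrate_datasets(primary, das, "chest", 20, counts, seed = 3)
  expect_identical(out, out2)  # same seed -> identical
  out3 <- integrate_datasets(primary, das, "chest", 20, counts, seed = 4)
  expect_equal(table(dataset_postures(out3)), tab)  # counts seed-invariant

  expect_error(
    integrate_datasets(primary, das, "chest", 20, c(right = 1000L), seed = 1),
    "1000")
})

test_that("posture_axis_summary pools samples per posture and axis", {
  ep1 <- make_ep(matrix(rep(c(0, 0, 1), each = 5), 5, 3))
  ds <- make_dataset(list(ep1))
  s <- posture_axis_summary(ds, "chest")
  z <- s[s$posture == "supine" & s$axis == "z", ]
  expect_equal(z$mean, 1); expect_equal(z$sd, 0)

  ep2 <- make_ep(matrix(rep(c(0, 0, 0), each = 5), 5, 3))
  ep3 <- make_ep(matrix(rep(c(0, 0, 2), each = 5), 5, 3))
  s2 <- posture_axis_summary(make_dataset(list(ep2, ep3)), "chest")
  expect_equal(s2[s2$axis == "z", "mean"], 1)

  expect_equal(nrow(posture_axis_summary(ds, "wrist_L")), 0L)
})

test_that("noise-free simulation reproduces the orientation table through
           posture_axis_summary", {
  orient <- default_orientation_model()
  synth <- simulate_dataset(noiseless_config(n_subjects = 2))
  s <- posture_axis_summary(synth$dataset, "chest")
  for (p in POSTURES) {
    expected <- orient[[paste0("chest.", p)]]
    got <- s[s$posture == p, ]
    expect_equal(got$mean[match(c("x", "y", "z"), got$axis)], expected,
                 tolerance = 1e-9)
    expect_equal(got$sd, rep(0, 3), tolerance = 1e-9)
  }
})
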