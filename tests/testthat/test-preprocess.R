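test_that("anomaly replacement fixes isolated spikes and leaves clean data alone", {
  # all-zero sequence: nothing to flag
  z <- make_seq(array(0L, c(2, 20, 20)))
  expect_identical(replace_anomalies(z)$frames, z$frames)

  # single 255 spike in a plateau of 10s becomes the 8-neighbour mean (10)
  f <- array(0L, c(1, 20, 20))
  f[1, 5:7, 5:7] <- 10L
  f[1, 6, 6] <- 255L
  fixed <- replace_anomalies(make_seq(f))$frames
  expect_equal(fixed[1, 6, 6], 10L)
  expect_equal(fixed[1, 5, 5], 10L)  # neighbours untouched

  # spike on silent background is zeroed
  g <- array(0L, c(1, 20, 20))
  g[1, 10, 10] <- 255L
  expect_equal(replace_anomalies(make_seq(g))$frames[1, 10, 10], 0L)

  # a smooth noiseless footprint passes through unchanged
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 2, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  expect_identical(replace_anomalies(s)$frames, s$frames)
})

test_that("anomaly replacement removes injected spikes from a real walk", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                     anomaly_rate = 2e-4, seed = 11)
  clean <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                         anomaly_rate = 0, seed = 11)
  expect_gt(sum(s$frames == 255), 0)  # spikes were injected
  fixed <- replace_anomalies(s)
  # residual differences from the spike-free walk are small and sparse
  dif <- abs(fixed$frames - clean$frames)
  expect_lt(max(dif), 64)
  expect_lt(mean(dif > 0), 1e-3)
})

test_that("pressure accumulation is the explicit cellwise sum", {
  f <- array(7L, c(3, 10, 10))
  expect_equal(accumulate_pressure(make_seq(f)),
               matrix(21, 10, 10))

  one <- array(sample.int(255, 100, replace = TRUE), c(1, 10, 10))
  expect_equal(accumulate_pressure(make_seq(one)), one[1, , ] * 1.0)

  set.seed(5)
  r <- array(sample.int(255, 300, replace = TRUE), c(3, 10, 10))
  brute <- r[1, , ] + r[2, , ] + r[3, , ]
  expect_equal(accumulate_pressure(make_seq(r)), brute * 1.0)

  expect_error(accumulate_pressure(make_seq(array(0L, c(0, 5, 5)))), "empty")
})

test_that("ROI extraction recovers every scheduled contact with its side and onset", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 4, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  summed <- accumulate_pressure(s)
  rois <- extract_rois(summed, s)
  expect_length(rois, 4)
  onsets <- vapply(rois, `[[`, 0, "onset_frame")
  expect_equal(onsets, s$truth$onset_frame)
  expect_equal(vapply(rois, `[[`, "", "side"), s$truth$side)
  expect_true(all(diff(onsets) > 0))
  for (r in rois) {
    expect_lte(r$onset_frame, r$offset_frame)
    # active cells lie inside the 32 x 16 window
    expect_true(all(r$cells[, 1] >= r$row & r$cells[, 1] <= r$row + 31))
    expect_true(all(r$cells[, 2] >= r$col & r$cells[, 2] <= r$col + 15))
  }

  # empty mat
  e <- make_seq(array(0L, c(2, 192, 40)))
  expect_length(extract_rois(accumulate_pressure(e), e), 0)

  # mask-correlation variant agrees on count, sides and onsets
  rois2 <- extract_rois(summed, s, method = "mask")
  expect_length(rois2, 4)
  expect_equal(vapply(rois2, `[[`, 0, "onset_frame"), onsets)
  expect_equal(vapply(rois2, `[[`, "", "side"), s$truth$side)
})

test_that("footprints larger than the 32 x 16 mask are rejected", {
  f <- array(0L, c(1, 192, 40))
  f[1, 50:100, 10:30] <- 50L  # 51 x 21 blob
  s <- make_seq(f)
  expect_error(extract_rois(accumulate_pressure(s), s), "32 x 16")
})

test_that("N ordered contacts yield N-1 gait cycles with positive durations", {
  p <- tiny_profile()
  for (n in c(1, 2, 3, 4)) {
    s <- simulate_walk(p, walk_condition(0), n_steps = n, noise_sd = 0,
                       anomaly_rate = 0, seed = 1)
    s <- replace_anomalies(s)
    rois <- extract_rois(accumulate_pressure(s), s)
    cycles <- detect_gait_cycles(rois)
    expect_length(cycles, max(n - 1, 0))
    for (cy in cycles) expect_gte(cy$duration_frames, 1)
  }
  # interior cycles span onset i to onset i+2 (one full stride)
  s <- simulate_walk(p, walk_condition(0), n_steps = 4, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  cycles <- detect_gait_cycles(extract_rois(accumulate_pressure(s), s))
  expect_equal(cycles[[1]]$end_frame - cycles[[1]]$start_frame,
               s$truth$onset_frame[3] - s$truth$onset_frame[1])
})

test_that("average maps are the windowed per-cycle mean (hand-built oracle)", {
  # two frames, one left and one right contact, values 4 then 6 -> mean 5
  f <- array(0L, c(2, 192, 40))
  f[1, 10:20, 5:12] <- 4L;  f[2, 10:20, 5:12] <- 6L    # left foot
  f[1, 42:52, 25:32] <- 4L; f[2, 42:52, 25:32] <- 6L   # right foot
  s <- make_seq(f)
  roiL <- structure(list(row = 5L, col = 3L, side = "left",
                         onset_frame = 1L, offset_frame = 2L),
                    class = "footprint_roi")
  roiR <- structure(list(row = 37L, col = 23L, side = "right",
                         onset_frame = 1L, offset_frame = 2L),
                    class = "footprint_roi")
  cy <- structure(list(index = 1L, start_frame = 1L, end_frame = 3L,
                       duration_frames = 2L, rois = list(roiL, roiR)),
                  class = "gait_cycle")
  m <- compute_average_map(s, cy)
  expect_equal(dim(m$grid), c(32L, 32L))
  expect_true(all(m$grid >= 0))
  expect_equal(m$grid[6, 3], 5)    # left half: window cell (10,5) -> (6,3)
  expect_equal(m$grid[6, 16 + 3], 5)  # right half shifted by 16 columns
  expect_equal(sum(m$grid[, 1:16] > 0), 11 * 8)

  # constant pressure over the cycle reproduces the constant
  f2 <- f; f2[2, , ] <- f2[1, , ]
  m2 <- compute_average_map(make_seq(f2), cy)
  expect_equal(m2$grid[6, 3], 4)
})

test_that("average maps conserve pressure mass over the cycle", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 4, noise_sd = 2,
                     anomaly_rate = 0, seed = 13)
  rois <- extract_rois(accumulate_pressure(s), s)
  cycles <- detect_gait_cycles(rois)
  for (cy in cycles) {
    m <- compute_average_map(s, cy)
    tt <- cy$start_frame:(min(cy$end_frame - 1, dim(s$frames)[1]))
    for (k in 1:2) {
      roi <- cy$rois[[k]]
      win <- colSums(s$frames[tt, roi$row:(roi$row + 31),
                              roi$col:(roi$col + 15), drop = FALSE] * 1.0,
                     dims = 1)
      half <- if (roi$side == "left") m$grid[, 1:16] else m$grid[, 17:32]
      expect_equal(half * cy$duration_frames, win, tolerance = 1e-10)
    }
  }
})

test_that("flip augmentation mirrors columns, doubles the set, and is an involution", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  maps <- preprocess_sequence(s)
  aug <- augment_flip(maps)
  expect_length(aug, 2 * length(maps))
  expect_false(any(vapply(maps, `[[`, TRUE, "augmented")))
  expect_true(all(vapply(aug[-seq_along(maps)], `[[`, TRUE, "augmented")))

  # single hot column c maps to column 33 - c
  hot <- maps[[1]]
  hot$grid <- matrix(0, 32, 32); hot$grid[, 7] <- 1
  flipped <- augment_flip(list(hot))[[2]]
  expect_equal(which(colSums(flipped$grid) > 0), 33 - 7)

  # flipping twice restores the original grid
  twice <- augment_flip(augment_flip(list(maps[[1]]))[2])[[2]]
  expect_equal(twice$grid, maps[[1]]$grid)
})

test_that("mirroring the mat yields the flipped maps (side symmetry)", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                     anomaly_rate = 0, seed = 21)
  m <- preprocess_sequence(s)
  sm <- s
  sm$frames <- s$frames[, , dim(s$frames)[3]:1]  # mirror mat width
  mm <- preprocess_sequence(sm)
  expect_length(mm, length(m))
  for (i in seq_along(m))
    expect_equal(mm[[i]]$grid, m[[i]]$grid[, 32:1], tolerance = 1e-10)
})

test_that("dataset partitions follow the round/condition protocol without leakage", {
  cohort <- generate_cohort(2, c("4" = 1, "7" = 1), seed = 2)
  seqs <- schedule_cohort_trials(cohort, rounds_type1 = 3, rounds_type2 = 1,
                                 unit_steps_per_round = 6, noise_sd = 0,
                                 anomaly_rate = 0, seed = 3, frames = TRUE)
  maps <- unlist(lapply(seqs, preprocess_sequence), recursive = FALSE)
  ds <- build_datasets(maps, task = "closed")
  expect_equal(nrow(ds$train), 2 * 2 * 6)
  expect_equal(nrow(ds$test), 2 * 2 * 6)
  expect_setequal(unique(ds$train$condition), "I")
  expect_setequal(unique(ds$train$round_id), c(1, 2))
  key <- function(d) paste(d$subject_id, d$condition, d$round_id,
                           d$cycle_index)
  expect_length(intersect(key(ds$train), key(ds$test)), 0)

  open <- build_datasets(maps, task = "open", unknown_subjects = 2)
  expect_equal(nrow(open$train), 1 * 2 * 6)
  expect_equal(nrow(open$test), 4 * 2 * 6 - 12)
  expect_false(any(open$train$subject_id == 2))
  expect_length(intersect(key(open$train), key(open$test)), 0)

  # flip augmentation applies to the training partition only
  dsa <- build_datasets(maps, task = "closed", augment = TRUE)
  expect_equal(nrow(dsa$train), 2 * 2 * 2 * 6)
  expect_equal(nrow(dsa$test), 2 * 2 * 6)
  expect_false(any(dsa$test$augmented))

  expect_error(build_datasets(maps, task = "open"), "unknown_subjects")
  expect_error(build_datasets(maps, task = "closed",
                              test_rounds_type1 = c(2, 3)),
               "overlapping")
})
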