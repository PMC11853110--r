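test_that("cohort generation honours the shoe-size histogram and the seed", {
  cohort <- generate_cohort(60, c("3" = 2, "4" = 15, "7" = 19, "10" = 24),
                            seed = 1)
  expect_length(cohort, 60)
  sizes <- table(vapply(cohort, `[[`, 0, "shoe_size_us"))
  expect_equal(unname(sizes[c("3", "4", "7", "10")]),
               as.table(c(2L, 15L, 19L, 24L)), ignore_attr = TRUE)
  expect_equal(vapply(cohort, `[[`, 0, "subject_id"), 1:60)

  again <- generate_cohort(60, c("3" = 2, "4" = 15, "7" = 19, "10" = 24),
                           seed = 1)
  expect_identical(cohort, again)

  expect_length(generate_cohort(0, c(), seed = 1), 0)
  expect_error(generate_cohort(5, c("7" = 3), seed = 1), "sum")
})

test_that("the scaled shoe-size mix preserves proportions and totals", {
  expect_equal(shoe_size_mix(60), c("3" = 2L, "4" = 15L, "7" = 19L,
                                    "10" = 24L))
  for (n in c(1, 5, 12, 48))
    expect_equal(sum(shoe_size_mix(n)), n)
})

test_that("cohort profiles are mutually distinct unless a collision is requested", {
  cohort <- generate_cohort(8, c("7" = 8), seed = 3)
  tpl <- lapply(cohort, `[[`, "template_left")
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(isTRUE(all.equal(tpl[[i]], tpl[[j]])))

  clones <- generate_cohort(4, c("7" = 4), seed = 3,
                            identical_templates = TRUE)
  expect_identical(clones[[1]]$template_left, clones[[4]]$template_left)
  expect_identical(clones[[1]]$weight_kg, clones[[4]]$weight_kg)
})

test_that("simulated frames have mat geometry, 8-bit range and a silent lead-in", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 2,
                     anomaly_rate = 1e-4, seed = 4)
  expect_equal(dim(s$frames)[2:3], c(192L, 40L))
  expect_true(all(s$frames >= 0 & s$frames <= 255))
  expect_true(all(s$frames[1, , ] == 0))  # starts 1 m before the mat

  again <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 2,
                         anomaly_rate = 1e-4, seed = 4)
  expect_identical(s$frames, again$frames)

  other <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 2,
                         anomaly_rate = 1e-4, seed = 5)
  expect_false(identical(s$frames, other$frames))
})

test_that("a clean walk leaves exactly n_steps disjoint footprint regions", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 4, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  summed <- accumulate_pressure(s)
  lab <- brute_components(summed > 0)
  expect_equal(max(lab), 4L)
  expect_equal(s$truth$side, rep(c("left", "right"), 2))
  expect_true(all(diff(s$truth$onset_frame) > 0))
})

test_that("walks that do not fit on the mat are rejected", {
  p <- tiny_profile()
  expect_error(simulate_walk(p, walk_condition(0), n_steps = 40, seed = 1),
               "exceed")
})

test_that("stance occupies 55-65% of the gait cycle across the cohort", {
  cohort <- generate_cohort(10, c("4" = 5, "10" = 5), seed = 6)
  for (p in cohort) {
    s <- simulate_walk(p, walk_condition(0), n_steps = 2, noise_sd = 0,
                       anomaly_rate = 0, seed = 1)
    tr <- s$truth
    # active frames of step 1 within its window = stance duration
    w <- s$frames[, tr$window_row[1]:(tr$window_row[1] + 31),
                  tr$window_col[1]:(tr$window_col[1] + 15)]
    stance <- sum(rowSums(w, dims = 1) > 0)
    cycle <- p$cadence_frames
    expect_gte(stance / cycle, 0.55)
    expect_lte(stance / cycle, 0.65)
    # double support: consecutive contacts overlap in time
    expect_lt(tr$onset_frame[2], tr$onset_frame[1] + stance)
  }
})

test_that("heel-to-toe progression shifts pressure forward through stance", {
  p <- tiny_profile()
  s <- simulate_walk(p, walk_condition(0), n_steps = 2, noise_sd = 0,
                     anomaly_rate = 0, seed = 1)
  tr <- s$truth
  rr <- tr$window_row[1]:(tr$window_row[1] + 31)
  cc <- tr$window_col[1]:(tr$window_col[1] + 15)
  cop_row <- function(t) {
    m <- s$frames[t, rr, cc]
    sum(row(m) * m) / sum(m)
  }
  early <- cop_row(tr$onset_frame[1] + 1)
  late <- cop_row(tr$onset_frame[1] + tr$stance_frames[1] - 2)
  expect_gt(late, early)  # toes are at higher row indices than the heel
})

test_that("doubling body weight never decreases frame pressure (pre-clipping)", {
  p <- tiny_profile()
  heavier <- p
  scale <- (40 + 1.6 * 2 * p$weight_kg) / (40 + 1.6 * p$weight_kg)
  for (f in c("template_left", "template_right")) heavier[[f]] <- p[[f]] * scale
  heavier$lobes_left <- lapply(p$lobes_left, `*`, scale)
  heavier$lobes_right <- lapply(p$lobes_right, `*`, scale)
  s1 <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                      anomaly_rate = 0, seed = 1)
  s2 <- simulate_walk(heavier, walk_condition(0), n_steps = 3, noise_sd = 0,
                      anomaly_rate = 0, seed = 1)
  sums1 <- rowSums(s1$frames, dims = 1)
  sums2 <- rowSums(pmin(s2$frames, 255), dims = 1)
  expect_true(all(sums2 >= sums1 - 1e-9))
})

test_that("a 500 g load shifts each step's center of pressure by exactly the configured cells", {
  p <- tiny_profile()
  s0 <- simulate_walk(p, walk_condition(0), n_steps = 3, noise_sd = 0,
                      anomaly_rate = 0, seed = 9)
  cond <- walk_condition(500)
  s1 <- simulate_walk(p, cond, n_steps = 3, noise_sd = 0,
                      anomaly_rate = 0, seed = 9)
  expect_equal(s1$condition, "II")
  for (k in 1:3) {
    cop <- function(s) {
      tr <- s$truth
      rr <- tr$window_row[k]:(tr$window_row[k] + 31)
      cc <- tr$window_col[k]:(tr$window_col[k] + 15)
      m <- colSums(s$frames[, rr, cc] * 1.0, dims = 1)
      sum((rr)[row(m)] * m) / sum(m)
    }
    # exact up to 8-bit rounding of the load-scaled template
    expect_equal(cop(s1) - cop(s0), cond$load_cop_shift_cells,
                 tolerance = 1e-3)
  }
})

test_that("walk_condition enforces the no-load invariant", {
  expect_error(walk_condition(0, load_cop_shift_cells = 2), "zero")
  expect_error(walk_condition(0, load_scale = 1.1), "unit")
  c2 <- walk_condition(500)
  expect_gt(c2$load_scale, 1)
  expect_gt(c2$load_cop_shift_cells, 0)
})

test_that("the trial scheduler delivers the demanded unit steps per round", {
  cohort <- generate_cohort(3, c("4" = 1, "7" = 1, "10" = 1), seed = 2)
  plan <- schedule_cohort_trials(cohort, rounds_type1 = 3, rounds_type2 = 1,
                                 unit_steps_per_round = 40, frames = FALSE)
  expect_equal(sum(plan$n_unit_steps), 3 * 4 * 40)
  per_round <- aggregate(n_unit_steps ~ subject_id + round_id, plan, sum)
  expect_true(all(per_round$n_unit_steps == 40))
  expect_setequal(unique(plan$condition[plan$round_id <= 3]), "I")
  expect_setequal(unique(plan$condition[plan$round_id == 4]), "II")

  single <- schedule_cohort_trials(cohort[1], rounds_type1 = 1,
                                   rounds_type2 = 0,
                                   unit_steps_per_round = 40,
                                   frames = FALSE)
  expect_equal(sum(single$n_unit_steps), 40)
  expect_setequal(unique(single$condition), "I")
})

test_that("scheduler frame mode matches its plan and tags Type II with the load", {
  cohort <- generate_cohort(1, c("7" = 1), seed = 2)
  seqs <- schedule_cohort_trials(cohort, rounds_type1 = 1, rounds_type2 = 1,
                                 unit_steps_per_round = 5, noise_sd = 0,
                                 anomaly_rate = 0, seed = 3, frames = TRUE)
  plan <- attr(seqs, "plan")
  expect_length(seqs, nrow(plan))
  for (i in seq_along(seqs)) {
    expect_equal(nrow(seqs[[i]]$truth), plan$n_steps[i])
    expect_equal(seqs[[i]]$condition, plan$condition[i])
  }
  type2 <- seqs[vapply(seqs, `[[`, "", "condition") == "II"]
  expect_true(all(vapply(type2, `[[`, 0, "load_g") == 500))
})
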