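test_that("generated trials are deterministic and respect the stated design", {
  pr <- test_profile(height = 1.535)
  t1 <- quick_trial(pr, "normal", noise = zero_noise(), seed = 11)
  t2 <- quick_trial(pr, "normal", noise = zero_noise(), seed = 11)
  expect_identical(t1$heel, t2$heel)
  expect_identical(t1$force, t2$force)
  expect_identical(t1$cog, t2$cog)
  expect_identical(t1$moments, t2$moments)

  # obstacle height is 15% of body height
  expect_equal(t1$truth$obstacle$height, 0.15 * 1.535, tolerance = 1e-12)

  # quasi-static start: no marker motion before onset
  pre <- t1$heel[t1$heel$time < t1$truth$onset, ]
  disp <- sqrt((pre$x - pre$x[1])^2 + (pre$y - pre$y[1])^2 + (pre$z - pre$z[1])^2)
  expect_lt(max(disp), 5e-4)

  # force is zero before contact and ramps through 10 N at landing
  expect_true(all(t1$force$fz[t1$force$time < t1$truth$contact] == 0))
  expect_gt(max(t1$force$fz), 10)

  expect_error(quick_trial(pr, "sideways"), class = "latstep_bad_condition")
})

test_that("leaning conditions start the COG at 70% of the configured LOS", {
  pr <- test_profile()
  for (cond in c("leaning", "leaning_fast")) {
    tr <- quick_trial(pr, cond, noise = zero_noise(), seed = 2)
    expect_equal(tr$cog$x[1], 0.70 * 0.10, tolerance = 1e-12)
  }
  tr <- quick_trial(pr, "normal", noise = zero_noise(), seed = 2)
  expect_equal(tr$cog$x[1], 0)

  # configurable LOS excursion
  des <- study_design(los_excursion = 0.2)
  tr <- quick_trial(pr, "leaning", design = des, noise = zero_noise(), seed = 2)
  expect_equal(tr$cog$x[1], 0.70 * 0.2, tolerance = 1e-12)
})

test_that("noisy swing arcs never intersect the obstacle box", {
  pr <- test_profile()
  noisy <- noise_model(trajectory_sd = 0.03, landing_sd_x = 0.04,
                       landing_sd_y = 0.03, timing_sd = 0.08)
  for (seed in 1:25) {
    tr <- quick_trial(pr, "fast", noise = noisy, seed = seed)
    obs <- tr$truth$obstacle
    over <- tr$heel$x >= obs$x_range[1] & tr$heel$x <= obs$x_range[2]
    if (any(over)) expect_gt(min(tr$heel$z[over]), obs$height)
  }
})

test_that("cohort generation enforces the design and is reproducible", {
  des <- study_design(n_per_group = 1, conditions = "normal",
                      trials_per_condition = 1)
  pr <- subject_profiles(1, seed = 3)
  co <- generate_cohort(des, pr, zero_noise(), seed = 5,
                        pre_time = 0.35, post_time = 0.05)
  expect_equal(nrow(co), 2L)

  co2 <- generate_cohort(des, pr, zero_noise(), seed = 5,
                         pre_time = 0.35, post_time = 0.05)
  expect_identical(co, co2)

  expect_error(generate_cohort(des, subject_profiles(2, seed = 3)),
               class = "latstep_bad_profiles")
})

test_that("a full-design cohort has 10 trials per condition block, 1600 total", {
  des <- study_design()
  co <- generate_cohort(des, subject_profiles(20, seed = 1), zero_noise(),
                        seed = 9, pre_time = 0.31, post_time = 0.02)
  expect_equal(nrow(co), 1600L)
  counts <- dplyr::count(co, subject_id, condition)
  expect_true(all(counts$n == 10L))
  expect_equal(dplyr::n_distinct(co$subject_id), 40L)
})

test_that("zero-noise blocks repeat the identical trial", {
  des <- study_design(n_per_group = 1, conditions = "leaning",
                      trials_per_condition = 5)
  co <- generate_cohort(des, subject_profiles(1, seed = 2), zero_noise(),
                        seed = 7, pre_time = 0.35, post_time = 0.05)
  block <- co$trial[co$condition == "leaning" & co$subject_id == "o01"]
  for (k in 2:length(block)) {
    expect_identical(block[[k]]$heel, block[[1]]$heel)
    expect_identical(block[[k]]$force, block[[1]]$force)
  }
})

test_that("exact_moment_sample hits the requested moments exactly", {
  x <- exact_moment_sample(20, 0.78, 0.10, seed = 42)
  expect_equal(mean(x), 0.78, tolerance = 1e-12)
  expect_equal(sd(x), 0.10, tolerance = 1e-12)

  y <- exact_moment_sample(5, 0, 1, seed = 1)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)

  z <- exact_moment_sample(3, 2, 0, seed = 1)
  expect_identical(z, rep(2, 3))

  expect_error(exact_moment_sample(1, 0, 1), class = "latstep_bad_n")
  expect_identical(exact_moment_sample(12, -3, 0.4, seed = 9),
                   exact_moment_sample(12, -3, 0.4, seed = 9))
})

test_that("scalar cohorts reproduce every calibration cell's moments", {
  des <- study_design()
  sc <- simulate_scalar_cohort(des, seed = 3, exact = TRUE)
  cells <- sc |>
    dplyr::group_by(parameter, condition, group) |>
    dplyr::summarise(m = mean(value), s = sd(value), .groups = "drop") |>
    dplyr::inner_join(default_calibration(),
                      by = c("parameter", "condition", "group"))
  expect_equal(nrow(cells), 80L)
  expect_lt(max(abs(cells$m - cells$mean)), 1e-10)
  expect_lt(max(abs(cells$s - cells$sd)), 1e-10)
})
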