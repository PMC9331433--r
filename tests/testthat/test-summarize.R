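test_that("COG displacement maxima are relative to heel-off and exhaustive", {
  t <- (0:100) / 100
  flat <- tibble::tibble(time = t, x = 0.3, y = -0.1, z = 0.9)
  expect_equal(unname(cog_max_displacement(flat, 0.2, 0.9)), c(0, 0, 0))

  # monotone vertical rise of 0.08 m across the swing
  rise <- tibble::tibble(time = t, x = 0, y = 0,
                         z = 0.9 + 0.08 * pmin(pmax((t - 0.2) / 0.7, 0), 1))
  expect_equal(cog_max_displacement(rise, 0.2, 0.9)[["z"]], 0.08,
               tolerance = 1e-12)

  # invariance: adding a constant to the whole series changes nothing
  shifted <- dplyr::mutate(rise, x = x + 5, y = y - 2, z = z + 11)
  expect_equal(cog_max_displacement(shifted, 0.2, 0.9),
               cog_max_displacement(rise, 0.2, 0.9), tolerance = 1e-12)

  # random series: equals an exhaustive per-sample maximum
  withr::with_seed(6, {
    rnd <- tibble::tibble(time = t, x = cumsum(rnorm(101, 0, 0.01)),
                          y = cumsum(rnorm(101, 0, 0.01)),
                          z = cumsum(rnorm(101, 0, 0.01)))
  })
  got <- cog_max_displacement(rnd, 0.25, 0.80)
  w <- which(t >= 0.25 & t <= 0.80)
  ref <- which(t <= 0.25); ref <- ref[length(ref)]
  for (a in c("x", "y", "z")) {
    best <- 0
    for (i in w) best <- max(best, abs(rnd[[a]][i] - rnd[[a]][ref]))
    expect_equal(got[[a]], best, tolerance = 1e-12)
  }
})

test_that("moment maxima take the global window maximum per channel", {
  t <- (0:100) / 100
  zero <- tibble::tibble(time = t, hip_ext = 0, knee_ext = 0, ankle_pf = 0)
  expect_equal(unname(moment_maxima(zero, 0, 1)), c(0, 0, 0))

  # two-peak series: the global maximum wins, not the first peak
  two_peak <- tibble::tibble(
    time = t,
    hip_ext = 0.3 * exp(-((t - 0.3) / 0.05)^2) + 0.5 * exp(-((t - 0.7) / 0.05)^2),
    knee_ext = 0.2, ankle_pf = t
  )
  m <- moment_maxima(two_peak, 0, 1)
  expect_equal(m[["hip_ext"]], max(two_peak$hip_ext), tolerance = 1e-12)
  expect_gt(m[["hip_ext"]], 0.45)
  expect_equal(m[["ankle_pf"]], 1)

  # generator with a programmed knee peak recovers it within tolerance
  pr <- test_profile()
  tr <- quick_trial(pr, "leaning", noise = zero_noise(), seed = 2,
                    targets = list(knee_moment = 0.44))
  sw <- extract_swing(tr)
  got <- moment_maxima(tr$moments, sw$heel_off_time, sw$landing_time)
  expect_equal(got[["knee_ext"]], 0.44, tolerance = 0.01)
})

test_that("the tenth-trial rule selects trial 10 and needs a complete block", {
  sums <- tibble::tibble(trial_index = 1:10,
                         step_time = seq(0.74, 0.83, by = 0.01))
  expect_equal(select_scalar_trial(sums, "step_time"), 0.83)

  const <- tibble::tibble(trial_index = 1:10, step_time = 0.7)
  expect_equal(select_scalar_trial(const, "step_time"), 0.7)

  expect_error(select_scalar_trial(sums[1:9, ], "step_time"),
               class = "latstep_incomplete_block")
  expect_error(select_scalar_trial(sums, "bogus"))

  # perturbing trials 1-9 leaves the selected value unchanged
  perturbed <- sums
  perturbed$step_time[1:9] <- perturbed$step_time[1:9] + 100
  expect_equal(select_scalar_trial(perturbed, "step_time"), 0.83)
})

test_that("group samples cover all cells with n = 20 and exact moments", {
  sc <- simulate_scalar_cohort(study_design(), seed = 5, exact = TRUE)
  gs <- build_group_samples(sc, n_per_group = 20)
  expect_equal(nrow(gs), 80L)  # 10 parameters x 4 conditions x 2 groups
  expect_true(all(gs$n == 20L))
  expect_true(all(lengths(gs$values) == 20L))

  cal <- default_calibration()
  for (i in c(1L, 17L, 80L)) {
    cell <- calibration_row <- cal[cal$parameter == gs$parameter[i] &
                                     cal$condition == gs$condition[i] &
                                     cal$group == gs$group[i], ]
    expect_equal(mean(gs$values[[i]]), cell$mean, tolerance = 1e-10)
    expect_equal(sd(gs$values[[i]]), cell$sd, tolerance = 1e-10)
  }

  # a subject missing one condition block is named in the error
  broken <- sc[!(sc$subject_id == "o03" & sc$condition == "leaning"), ]
  expect_error(build_group_samples(broken, 20), "o03",
               class = "latstep_incomplete_block")
})

test_that("cohort summarisation produces all ten parameters per block", {
  des <- study_design(n_per_group = 1, conditions = c("normal", "leaning"),
                      trials_per_condition = 4)
  co <- generate_cohort(des, subject_profiles(1, seed = 2),
                        noise_model(trajectory_sd = 0.005,
                                    landing_sd_x = 0.01, landing_sd_y = 0.01,
                                    timing_sd = 0.02),
                        seed = 11, pre_time = 0.35, post_time = 0.05)
  sc <- summarize_cohort(co)
  expect_equal(sort(unique(sc$parameter)),
               sort(c("step_time", "cog_x", "cog_y", "cog_z", "hip_moment",
                      "knee_moment", "ankle_moment", "error_distance",
                      "sd_x", "sd_y")))
  expect_equal(nrow(sc), 2 * 2 * 10)  # 2 subjects x 2 conditions x 10 params
  expect_true(all(is.finite(sc$value)))
  expect_true(all(sc$value[sc$parameter %in% c("sd_x", "sd_y",
                                               "error_distance")] >= 0))
  # step times stay near the calibrated group means for the condition
  st <- sc[sc$parameter == "step_time", ]
  expect_true(all(st$value > 0.3 & st$value < 1.3))
})
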