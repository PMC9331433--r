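test_that("resampling reproduces knots and preserves linear paths", {
  # swing already sampled at exactly 101 uniform times: output equals input
  n <- 101L
  sw <- tibble::tibble(time = seq(0.5, 1.3, length.out = n),
                       x = cumsum(runif(n, 0, 0.005)),
                       y = sin(seq(0, 2, length.out = n)) / 10,
                       z = 0.02 + 0.2 * sin(pi * seq(0, 1, length.out = n))^2)
  p <- normalize_and_resample(sw, n_points = n)
  expect_equal(p$x, sw$x, tolerance = 1e-12)
  expect_equal(p$y, sw$y, tolerance = 1e-12)
  expect_equal(p$z, sw$z, tolerance = 1e-12)
  expect_equal(p$u, seq(0, 1, length.out = n))

  # linear data stay linear under a cubic interpolating spline
  lin <- tibble::tibble(time = seq(0, 1, length.out = 37),
                        x = 2 * seq(0, 1, length.out = 37) - 1,
                        y = 0.5, z = seq(0.02, 0.3, length.out = 37))
  p <- normalize_and_resample(lin, n_points = 50)
  expect_equal(p$x, 2 * p$u - 1, tolerance = 1e-12)
  expect_equal(p$z, 0.02 + (0.3 - 0.02) * p$u, tolerance = 1e-12)

  # endpoints always reproduce the raw boundary samples
  expect_equal(p$x[1], lin$x[1])
  expect_equal(p$x[50], lin$x[37])

  expect_error(normalize_and_resample(lin[1:3, ]),
               class = "latstep_too_few_samples")
})

test_that("natural-spline resampling matches an independent tridiagonal oracle", {
  withr::with_seed(11, {
    t <- sort(runif(23, 0, 1))
    t <- (t - min(t)) / diff(range(t))
    sw <- tibble::tibble(time = t,
                         x = sin(3 * t) + 0.2 * cos(11 * t),
                         y = t^2 - 0.3 * t,
                         z = exp(-t) * sin(7 * t))
  })
  p <- normalize_and_resample(sw, n_points = 101)
  for (axis in c("x", "y", "z")) {
    oracle <- natural_spline_oracle(sw$time, sw[[axis]], p$u)
    expect_equal(p[[axis]], oracle, tolerance = 1e-9)
  }
})

test_that("average trajectory is the pointwise mean", {
  p0 <- line_path()
  same <- replicate(10, p0, simplify = FALSE)
  expect_equal(average_trajectory(same), p0, ignore_attr = TRUE)

  # two paths mirrored about a midline average to the midline
  up <- line_path(dy = 0.05)
  down <- line_path(dy = -0.05)
  expect_equal(average_trajectory(list(up, down))$y, rep(0, 101))

  withr::with_seed(4, {
    paths <- replicate(7, {
      p <- line_path()
      p$x <- p$x + rnorm(101, 0, 0.01)
      p$z <- p$z + rnorm(101, 0, 0.01)
      p
    }, simplify = FALSE)
  })
  avg <- average_trajectory(paths)
  # brute-force accumulation
  acc <- rep(0, 101)
  for (p in paths) acc <- acc + p$x
  expect_equal(avg$x, acc / 7, tolerance = 1e-12)

  bad <- line_path(n_points = 51)
  expect_error(average_trajectory(list(p0, bad)),
               class = "latstep_grid_mismatch")
})

test_that("error distance: zero, closed form, homogeneity, invariance", {
  p0 <- line_path()
  expect_equal(error_distance(replicate(5, p0, simplify = FALSE)), 0)
  expect_error(error_distance(list(p0)), class = "latstep_too_few_paths")

  # two straight paths offset +/- d from their midline: each is d away from
  # the average at every grid point, so the mean-per-point error distance is d
  d <- 0.013
  pair <- list(line_path(dy = d), line_path(dy = -d))
  expect_equal(error_distance(pair), d, tolerance = 1e-12)
  # literal sum over points and trials
  expect_equal(error_distance(pair, "sum_point"), d * 101 * 2, tolerance = 1e-9)

  withr::with_seed(9, {
    paths <- replicate(6, {
      p <- line_path()
      p$x <- p$x + rnorm(101, 0, 0.02)
      p$y <- p$y + rnorm(101, 0, 0.02)
      p$z <- p$z + rnorm(101, 0, 0.02)
      p
    }, simplify = FALSE)
  })
  e <- error_distance(paths)
  # uniform scaling scales the statistic linearly
  scaled <- lapply(paths, function(p) { p$x <- 3 * p$x; p$y <- 3 * p$y; p$z <- 3 * p$z; p })
  expect_equal(error_distance(scaled), 3 * e, tolerance = 1e-12)
  # rigid translation leaves it unchanged
  moved <- lapply(paths, function(p) { p$x <- p$x + 5; p$z <- p$z - 2; p })
  expect_equal(error_distance(moved), e, tolerance = 1e-9)
})

test_that("landing coordinates come from the marker sample at/before landing", {
  pr <- test_profile()
  tr <- quick_trial(pr, "normal", noise = zero_noise(), seed = 2,
                    targets = list(landing_x = 0.32, landing_y = 0.015))
  sw <- extract_swing(tr)
  pos <- landing_position(sw)
  expect_equal(pos[["x"]], 0.32, tolerance = 1e-6)
  expect_equal(pos[["y"]], 0.015, tolerance = 1e-6)
})

test_that("landing SDs recover programmed scatter", {
  # hand-computed two-point case via explicit swing segments
  mk <- function(xl) {
    heel <- tibble::tibble(time = (0:9) / 100,
                           x = seq(0, xl, length.out = 10),
                           y = 0.02, z = 0.02)
    fake_swing(heel)
  }
  two <- landing_sd(list(mk(0), mk(0.02)))
  expect_equal(two$sd_x, sqrt(sum((c(0, 0.02) - 0.01)^2) / 1), tolerance = 1e-12)
  expect_equal(two$sd_x, 0.0141421356, tolerance = 1e-8)
  expect_equal(two$sd_y, 0)
  expect_error(landing_sd(list(mk(0))), class = "latstep_too_few_paths")

  # identical landings give exactly zero scatter
  same <- landing_sd(replicate(5, mk(0.3), simplify = FALSE))
  expect_equal(c(same$sd_x, same$sd_y), c(0, 0))

  # generator with programmed landing scatter sigma: the mean recovered SD
  # over replicates stays within 3 standard errors of sigma
  sigma <- 0.02
  pr <- test_profile()
  noise <- noise_model(trajectory_sd = 0, landing_sd_x = sigma,
                       landing_sd_y = 0, timing_sd = 0)
  reps <- 20L
  sds <- vapply(seq_len(reps), function(r) {
    segs <- lapply(1:10, function(k) {
      extract_swing(quick_trial(pr, "normal", noise = noise,
                                seed = 1000 * r + k))
    })
    landing_sd(segs)$sd_x
  }, numeric(1))
  se <- sigma / sqrt(2 * (10 - 1)) / sqrt(reps)
  expect_lt(abs(mean(sds) - sigma), 3 * se + 0.0006)  # 0.0006 = c4 bias of sd at n=10
})

test_that("landing SDs are translation-invariant and rotation-covariant", {
  withr::with_seed(21, {
    segs <- lapply(1:8, function(k) {
      heel <- tibble::tibble(time = (0:9) / 100,
                             x = seq(0, 0.3 + rnorm(1, 0, 0.02), length.out = 10),
                             y = rnorm(1, 0.02, 0.01), z = 0.02)
      fake_swing(heel)
    })
  })
  base <- landing_sd(segs)
  shifted <- lapply(segs, function(s) {
    s$trial$heel$x <- s$trial$heel$x + 2
    s$trial$heel$y <- s$trial$heel$y - 1
    s
  })
  expect_equal(landing_sd(shifted), base, tolerance = 1e-12)
  # a 90-degree rotation swaps the two horizontal SDs
  rot <- lapply(segs, function(s) {
    x <- s$trial$heel$x
    s$trial$heel$x <- -s$trial$heel$y
    s$trial$heel$y <- x
    s
  })
  r <- landing_sd(rot)
  expect_equal(r$sd_x, base$sd_y, tolerance = 1e-12)
  expect_equal(r$sd_y, base$sd_x, tolerance = 1e-12)
})
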