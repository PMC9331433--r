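test_that("log posterior matches the closed form and its invariances", {
  # two zero observations at mu = 0, sigma = 1: -2 * (1/2) log(2 pi)
  expect_equal(log_posterior(c(0, 0), 0, 0), -log(2 * pi), tolerance = 1e-9)

  # translation invariance: shift data and mu together
  withr::with_seed(2, y <- rnorm(15, 3, 2))
  expect_equal(log_posterior(y, 2.5, 0.3),
               log_posterior(y + 7, 9.5, 0.3), tolerance = 1e-9)

  # sigma -> infinity drives the density to -Inf
  expect_lt(log_posterior(y, 2.5, 50), -600)
  expect_gt(log_posterior(y, 2.5, 1), log_posterior(y, 2.5, 40))
})

test_that("retained draw counts follow the settings identity", {
  expect_equal(retained_draws(mcmc_settings()), 6000L)
  expect_equal(retained_draws(mcmc_settings(iterations = 1000, burn_in = 200,
                                            thin = 4, chains = 3)), 600L)
  expect_error(mcmc_settings(iterations = 100, burn_in = 200))
  expect_error(mcmc_settings(iterations = 1000, burn_in = 200, thin = 3))

  post <- sample_posterior(exact_moment_sample(10, 1, 0.5, 1),
                           tiny_mcmc(seed = 4))
  expect_equal(nrow(post$draws), retained_draws(tiny_mcmc()))
})

test_that("the sampler is seed-deterministic and rejects degenerate input", {
  y <- exact_moment_sample(12, 0.5, 0.2, seed = 3)
  p1 <- sample_posterior(y, tiny_mcmc(seed = 9))
  p2 <- sample_posterior(y, tiny_mcmc(seed = 9))
  expect_identical(p1$draws, p2$draws)
  p3 <- sample_posterior(y, tiny_mcmc(seed = 10))
  expect_false(identical(p1$draws$mu, p3$draws$mu))

  expect_error(sample_posterior(rep(1, 10), tiny_mcmc()),
               class = "latstep_zero_variance")
  expect_error(sample_posterior(c(1), tiny_mcmc()),
               class = "latstep_bad_sample")
})

test_that("flat-prior posterior mean tracks the sample mean", {
  y <- exact_moment_sample(20, 0.78, 0.10, seed = 1)
  post <- sample_posterior(y, mcmc_settings(seed = 21))
  mu_mat <- matrix(post$draws$mu, ncol = post$settings$chains)
  expect_lt(abs(mean(post$draws$mu) - 0.78), 3 * mcse_mean(mu_mat))
  expect_lt(max(post$rhat), 1.05)
})

test_that("posterior draws are exactly location and scale equivariant", {
  y <- exact_moment_sample(14, 2, 0.7, seed = 5)
  st <- tiny_mcmc(seed = 13)
  base <- sample_posterior(y, st)
  shifted <- sample_posterior(y + 3.25, st)
  expect_equal(shifted$draws$mu, base$draws$mu + 3.25, tolerance = 1e-9)
  expect_equal(shifted$draws$sigma, base$draws$sigma, tolerance = 1e-9)

  scaled <- sample_posterior(y * 2.5, st)
  expect_equal(scaled$draws$mu, base$draws$mu * 2.5, tolerance = 1e-9)
  expect_equal(scaled$draws$sigma, base$draws$sigma * 2.5, tolerance = 1e-9)
})

test_that("split Rhat separates mixed from unmixed chains", {
  # exact copies of a half-balanced sequence add no between-chain variance
  withr::with_seed(8, v <- rnorm(250))
  balanced <- c(v, rev(v))   # equal half means by construction
  copies <- matrix(rep(balanced, 4), ncol = 4)
  expect_lte(rhat(copies), 1 + 1e-6)
  expect_gt(var(balanced), 0)

  # well-mixed chains from one target
  withr::with_seed(9, mixed <- matrix(rnorm(4000), ncol = 4))
  expect_lt(rhat(mixed), 1.05)

  # chains centred at -10 and +10 are far from converged
  withr::with_seed(10, {
    apart <- cbind(rnorm(500, -10), rnorm(500, 10))
  })
  expect_gt(rhat(apart), 5)

  expect_error(rhat(matrix(1:8, ncol = 1)), class = "latstep_bad_chains")
})

test_that("the conjugate oracle gives the textbook scaled-t interval", {
  o <- conjugate_oracle(20, 0, 1)
  ci <- oracle_ci(o)
  expect_equal(ci[2], qt(0.975, 19) / sqrt(20), tolerance = 1e-12)
  expect_equal(ci[2], 0.468, tolerance = 1e-3)
  expect_equal(ci[1], -ci[2], tolerance = 1e-12)

  # df -> infinity approaches the normal interval
  big <- conjugate_oracle(1e6, 0, 1)
  expect_equal(oracle_quantile(big, 0.975) * sqrt(1e6), qnorm(0.975),
               tolerance = 1e-3)
})

test_that("MCMC intervals agree with the conjugate oracle", {
  cells <- list(c(8, -1.2, 0.6), c(25, 0.4, 1.8), c(40, 10, 3))
  for (cell in cells) {
    n <- cell[1]
    y <- exact_moment_sample(n, cell[2], cell[3], seed = n)
    post <- sample_posterior(y, tiny_mcmc(seed = n + 1))
    o <- conjugate_oracle(n, cell[2], cell[3])
    mu_mat <- matrix(post$draws$mu, ncol = 4)
    for (p in c(0.025, 0.975)) {
      q_mcmc <- quantile(post$draws$mu, p, names = FALSE)
      expect_lt(abs(q_mcmc - oracle_quantile(o, p)),
                3 * quantile_mcse(mu_mat, p, o))
    }
  }
})

test_that("group comparisons respect symmetry and the zero-exclusion rule", {
  y <- exact_moment_sample(20, 0.5, 0.1, seed = 2)
  same <- compare_groups(y, y, tiny_mcmc(seed = 3))
  expect_true(same$ci_low < 0 && same$ci_high > 0)
  expect_false(same$significant)
  expect_true(same$converged)

  old <- exact_moment_sample(20, 0.78, 0.10, seed = 4)
  young <- exact_moment_sample(20, 0.69, 0.08, seed = 5)
  fwd <- compare_groups(old, young, tiny_mcmc(seed = 6))
  rev <- compare_groups(young, old, tiny_mcmc(seed = 6))
  expect_true(fwd$significant)
  expect_identical(fwd$significant, rev$significant)
  # CI approximately negates under label swap (Monte-Carlo noise only):
  # 3 x combined MCSE of two independent empirical 2.5% quantiles, with the
  # tail density approximated by the normal at its 2.5% point
  f <- dnorm(qnorm(0.025)) / sd(fwd$difference)
  tol <- 3 * sqrt(2 * 0.025 * 0.975 / 1000) / f
  expect_lt(abs(fwd$ci_low + rev$ci_high), tol)
  expect_lt(abs(fwd$ci_high + rev$ci_low), tol)
})

test_that("the random-walk fallback sampler honours the same contract", {
  y <- exact_moment_sample(20, 0.78, 0.10, seed = 1)
  st <- mcmc_settings(sampler = "rw_metropolis", seed = 31)
  post <- sample_posterior(y, st)
  expect_equal(nrow(post$draws), 6000L)
  expect_lt(max(post$rhat), 1.05)
  mu_mat <- matrix(post$draws$mu, ncol = 4)
  expect_lt(abs(mean(post$draws$mu) - 0.78), 3 * mcse_mean(mu_mat))
})

test_that("cell-wise comparison assembles a complete results table", {
  des <- study_design(conditions = "leaning")
  sc <- simulate_scalar_cohort(des, seed = 2, exact = TRUE)
  sc <- sc[sc$parameter %in% c("step_time", "error_distance"), ]
  gs <- build_group_samples(sc, 20)
  res <- compare_cells(gs, tiny_mcmc(seed = 7))
  expect_s3_class(res, "latstep_results")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$ci_low <= res$ci_high))
  expect_true(all(res$rhat > 0))
  st_row <- res[res$parameter == "step_time", ]
  expect_equal(st_row$older_mean, 0.78, tolerance = 1e-10)
  expect_equal(st_row$young_sd, 0.08, tolerance = 1e-10)
})
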