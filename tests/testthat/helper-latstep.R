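# Shared fixtures and independent oracles for the test suite.

# short MCMC settings for tests that only need the statistical contract
tiny_mcmc <- function(seed = 1L, iterations = 800L, burn_in = 300L) {
  mcmc_settings(iterations = iterations, burn_in = burn_in, seed = seed)
}

test_profile <- function(group = "older", height = 1.535, weight = 51.6,
                         id = "o01") {
  tibble::tibble(subject_id = id, group = group, height = height,
                 weight = weight, dominant_side = "right")
}

# generate a quick trial with shortened quiet phases (tests only)
quick_trial <- function(..., pre_time = 0.35, post_time = 0.05) {
  generate_trial(..., pre_time = pre_time, post_time = post_time)
}

# Independent natural-cubic-spline oracle: solves the tridiagonal system for
# the knot second derivatives (M_1 = M_n = 0) and evaluates the piecewise
# cubic directly. Kept deliberately separate from stats::spline.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # interior equations: h[i-1]/6 M[i-1] + (h[i-1]+h[i])/3 M[i] + h[i]/6 M[i+1] = rhs
  m <- rep(0, n)
  if (n > 2) {
    ni <- n - 2L
    A <- matrix(0, ni, ni)
    rhs <- numeric(ni)
    for (r in seq_len(ni)) {
      i <- r + 1L
      if (r > 1) A[r, r - 1] <- h[i - 1] / 6
      A[r, r] <- (h[i - 1] + h[i]) / 3
      if (r < ni) A[r, r + 1] <- h[i] / 6
      rhs[r] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
    }
    m[2:(n - 1)] <- solve(A, rhs)
  }
  vapply(xout, function(t) {
    i <- findInterval(t, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    hi <- h[i]
    a <- (x[i + 1] - t) / hi
    b <- (t - x[i]) / hi
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * hi^2 / 6
  }, numeric(1))
}

# build a minimal swing segment around an explicit heel path (for unit tests
# of the consistency statistics, bypassing event detection)
fake_swing <- function(heel, landing_time = max(heel$time),
                       heel_off_time = min(heel$time)) {
  structure(
    list(subject_id = "s01", group = "older", condition = "normal",
         trial_index = 1L,
         heel_off_time = heel_off_time, landing_time = landing_time,
         heel = heel, cog = heel, force = NULL, moments = NULL,
         trial = list(heel = heel)),
    class = "latstep_swing"
  )
}

# straight-line path on the normalized grid, offset laterally by `dy`
line_path <- function(n_points = 101L, dy = 0) {
  out <- tibble::tibble(
    u = seq(0, 1, length.out = n_points),
    x = seq(0, 0.3, length.out = n_points),
    y = dy,
    z = seq(0.02, 0.05, length.out = n_points)
  )
  class(out) <- c("latstep_path", class(out))
  out
}

# Monte-Carlo SE of an empirical quantile of MCMC draws, using the oracle's
# known marginal density at the quantile and the mean-ESS of the draws.
quantile_mcse <- function(draws_mat, p, oracle) {
  q <- quantile(as.vector(draws_mat), p, names = FALSE)
  dens <- dt((q - oracle$location) / oracle$scale, oracle$df) / oracle$scale
  sqrt(p * (1 - p) / ess_mean(draws_mat)) / dens
}
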