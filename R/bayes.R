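# Bayesian two-group Gaussian comparison.
#
# Model: y_i ~ Normal(mu, sigma), noninformative prior p(mu, sigma) ~ 1/sigma,
# i.e. flat in (mu, log sigma) after the change of variables. The posterior is
# explored per group with a self-implemented Hamiltonian Monte Carlo sampler
# on (mu, log sigma) (leapfrog integration, dual-averaging step-size
# adaptation during burn-in only, per-coordinate scale preconditioning from
# the sample moments), with a random-walk Metropolis fallback. Convergence is
# judged by split-chain Gelman-Rubin Rhat < 1.05. The group difference is the
# draw-wise young - old difference of the mean draws; its central 95% credible
# interval excluding zero is the significance rule. The closed-form conjugate
# marginal (a scaled, shifted Student-t) serves as an independent oracle.

#' MCMC settings
#'
#' Defaults match the published analysis: 2000 iterations, 500 burn-in,
#' thin 1, 4 chains, so `(2000 - 500) / 1 * 4 = 6000` retained draws.
#'
#' @param iterations Iterations per chain (including burn-in).
#' @param burn_in Discarded initial iterations per chain.
#' @param thin Thinning interval.
#' @param chains Number of chains.
#' @param sampler `"hmc"` (default) or `"rw_metropolis"`.
#' @param leapfrog_steps Maximum leapfrog steps per HMC proposal; the actual
#'   count is jittered uniformly on `1..leapfrog_steps` each iteration.
#' @param step_size Initial step size in preconditioned units; adapted during
#'   burn-in toward ~0.8 acceptance, then frozen.
#' @param seed Integer seed; chains derive their own seeds from it.
#' @return A `latstep_mcmc_settings` list.
#' @export
#' @examples
#' retained_draws(mcmc_settings())
mcmc_settings <- function(iterations = 2000L, burn_in = 500L, thin = 1L,
                          chains = 4L, sampler = c("hmc", "rw_metropolis"),
                          leapfrog_steps = 20L, step_size = 0.2, seed = 1L) {
  sampler <- match.arg(sampler)
  check_number(iterations, "iterations", positive = TRUE)
  check_number(burn_in, "burn_in", nonneg = TRUE)
  check_number(thin, "thin", positive = TRUE)
  check_number(chains, "chains", positive = TRUE)
  check_number(leapfrog_steps, "leapfrog_steps", positive = TRUE)
  check_number(step_size, "step_size", positive = TRUE)
  if (burn_in >= iterations) abort("`burn_in` must be smaller than `iterations`.")
  if ((iterations - burn_in) %% thin != 0) {
    abort("`iterations - burn_in` must be a multiple of `thin`.")
  }
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), chains = as.integer(chains),
         sampler = sampler, leapfrog_steps = as.integer(leapfrog_steps),
         step_size = step_size, seed = as.integer(seed)),
    class = "latstep_mcmc_settings"
  )
}

#' Retained posterior draws implied by MCMC settings
#'
#' `(iterations - burn_in) / thin * chains`; 6000 at the default settings.
#'
#' @param settings A [mcmc_settings()].
#' @return Integer draw count.
#' @export
retained_draws <- function(settings) {
  with(settings, as.integer((iterations - burn_in) %/% thin * chains))
}

#' Log posterior density of the Gaussian model
#'
#' Gaussian log-likelihood of the data at `(mu, sigma = exp(log_sigma))` plus
#' the noninformative prior `p(mu, sigma) ~ 1/sigma`, expressed in
#' `(mu, log_sigma)` where the Jacobian makes the prior flat; the prior
#' therefore contributes no term and the value is the log-likelihood itself
#' (normalising constants included).
#'
#' @param values Numeric data vector (>= 2 values).
#' @param mu Mean parameter.
#' @param log_sigma Log of the SD parameter.
#' @return Log posterior density (unnormalised over parameters).
#' @export
#' @examples
#' log_posterior(c(0, 0), mu = 0, log_sigma = 0)  # -log(2*pi)
log_posterior <- function(values, mu, log_sigma) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  n <- length(values)
  ss <- sum((values - mu)^2)
  -n * log_sigma - 0.5 * exp(-2 * log_sigma) * ss - 0.5 * n * log(2 * pi)
}

# One HMC chain on q = (mu, ls). Sufficient statistics only; leapfrog with
# per-coordinate scales s = (s_mu, s_ls) (diagonal preconditioning), global
# step size adapted by Nesterov dual averaging during burn-in.
hmc_chain <- function(n, sy, syy, settings, s_mu, s_ls, mu0, ls0, chain_seed) {
  iters <- settings$iterations; burn <- settings$burn_in
  thin <- settings$thin; L <- settings$leapfrog_steps
  keep <- (iters - burn) %/% thin
  mu_out <- numeric(keep); ls_out <- numeric(keep)
  lp_fun <- function(mu, ls) {
    ss <- syy - 2 * mu * sy + n * mu * mu
    -n * ls - 0.5 * exp(-2 * ls) * ss
  }
  withr::with_seed(chain_seed, {
    mu <- mu0; ls <- ls0
    cur_lp <- lp_fun(mu, ls)
    eps <- settings$step_size
    # dual averaging state
    mu_da <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75; target <- 0.8
    n_acc <- 0L; kept <- 0L
    for (i in seq_len(iters)) {
      p1 <- rnorm(1); p2 <- rnorm(1)
      # jittered trajectory length breaks periodic looping of fixed-length
      # trajectories (improves mixing without touching the invariant target)
      L_i <- 1L + as.integer(runif(1) * L)
      mu_p <- mu; ls_p <- ls
      e2 <- exp(-2 * ls_p)
      g1 <- e2 * (sy - n * mu_p)
      g2 <- -n + e2 * (syy - 2 * mu_p * sy + n * mu_p * mu_p)
      q1 <- p1 + 0.5 * eps * s_mu * g1
      q2 <- p2 + 0.5 * eps * s_ls * g2
      for (l in seq_len(L_i)) {
        mu_p <- mu_p + eps * s_mu * q1
        ls_p <- ls_p + eps * s_ls * q2
        e2 <- exp(-2 * ls_p)
        g1 <- e2 * (sy - n * mu_p)
        g2 <- -n + e2 * (syy - 2 * mu_p * sy + n * mu_p * mu_p)
        w <- if (l < L_i) 1 else 0.5
        q1 <- q1 + w * eps * s_mu * g1
        q2 <- q2 + w * eps * s_ls * g2
      }
      prop_lp <- lp_fun(mu_p, ls_p)
      log_alpha <- (prop_lp - 0.5 * (q1 * q1 + q2 * q2)) -
        (cur_lp - 0.5 * (p1 * p1 + p2 * p2))
      alpha <- if (is.finite(log_alpha)) exp(min(0, log_alpha)) else 0
      if (runif(1) < alpha) {
        mu <- mu_p; ls <- ls_p; cur_lp <- prop_lp
        n_acc <- n_acc + 1L
      }
      if (i <= burn) {
        h_bar <- (1 - 1 / (i + t0)) * h_bar + (target - alpha) / (i + t0)
        log_eps <- mu_da - sqrt(i) / gamma * h_bar
        w <- i^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- if (i < burn) exp(log_eps) else exp(log_eps_bar)
      } else if ((i - burn) %% thin == 0) {
        kept <- kept + 1L
        mu_out[kept] <- mu; ls_out[kept] <- ls
      }
    }
    list(mu = mu_out, sigma = exp(ls_out), accept = n_acc / iters,
         step_size = eps)
  })
}

rw_chain <- function(n, sy, syy, settings, s_mu, s_ls, mu0, ls0, chain_seed) {
  iters <- settings$iterations; burn <- settings$burn_in; thin <- settings$thin
  keep <- (iters - burn) %/% thin
  mu_out <- numeric(keep); ls_out <- numeric(keep)
  lp_fun <- function(mu, ls) {
    ss <- syy - 2 * mu * sy + n * mu * mu
    -n * ls - 0.5 * exp(-2 * ls) * ss
  }
  withr::with_seed(chain_seed, {
    mu <- mu0; ls <- ls0
    cur_lp <- lp_fun(mu, ls)
    sc <- 2.4 / sqrt(2)
    n_acc <- 0L; kept <- 0L
    for (i in seq_len(iters)) {
      mu_p <- mu + sc * s_mu * rnorm(1)
      ls_p <- ls + sc * s_ls * rnorm(1)
      prop_lp <- lp_fun(mu_p, ls_p)
      if (log(runif(1)) < prop_lp - cur_lp) {
        mu <- mu_p; ls <- ls_p; cur_lp <- prop_lp
        n_acc <- n_acc + 1L
      }
      if (i > burn && (i - burn) %% thin == 0) {
        kept <- kept + 1L
        mu_out[kept] <- mu; ls_out[kept] <- ls
      }
    }
    list(mu = mu_out, sigma = exp(ls_out), accept = n_acc / iters,
         step_size = NA_real_)
  })
}

#' Sample the posterior of one group's Gaussian parameters
#'
#' Runs the configured number of chains of HMC (or random-walk Metropolis) on
#' `(mu, log sigma)` under the flat `1/sigma` prior, discards burn-in, and
#' reports split-chain Rhat for both parameters. Reproducible given the
#' settings seed. Zero-variance data are rejected: the flat-prior posterior
#' is improper when every observation coincides.
#'
#' @param values Numeric data vector (>= 2 distinct values).
#' @param settings A [mcmc_settings()].
#' @return A `latstep_posterior`: tibble `draws` (`chain`, `draw`, `mu`,
#'   `sigma`), named `rhat`, per-chain acceptance rates, settings and data
#'   summaries.
#' @export
#' @examples
#' post <- sample_posterior(exact_moment_sample(20, 0.78, 0.10, 1),
#'                          mcmc_settings(iterations = 400, burn_in = 100))
#' glance(post)
sample_posterior <- function(values, settings = mcmc_settings()) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L || anyNA(values)) {
    abort("need at least two non-missing values", class = "latstep_bad_sample")
  }
  n <- length(values)
  m <- mean(values); s <- sd(values)
  if (s == 0) {
    abort("zero-variance sample: the flat-prior Gaussian posterior is improper",
          class = "latstep_zero_variance")
  }
  # Sample the standardized problem z = (y - m)/s, whose sufficient
  # statistics are exactly (sum z = 0, sum z^2 = n - 1), then map the draws
  # back affinely: mu = m + s mu_z, sigma = s sigma_z. The flat prior on
  # (mu, log sigma) is affine-invariant, so the target is identical, and
  # location/scale equivariance of the draws is exact by construction.
  sy <- 0; syy <- n - 1
  s_mu <- 1 / sqrt(n)          # posterior scale of mu_z
  s_ls <- 1 / sqrt(2 * n)      # posterior scale of log sigma_z
  chain_fun <- if (settings$sampler == "hmc") hmc_chain else rw_chain
  chains <- lapply(seq_len(settings$chains), function(k) {
    init_seed <- derive_seed(settings$seed, "init", k)
    init <- withr::with_seed(init_seed, c(rnorm(1), rnorm(1)))
    ch <- chain_fun(n, sy, syy, settings, s_mu, s_ls,
                    mu0 = 2 * s_mu * init[1],
                    ls0 = 2 * s_ls * init[2],
                    chain_seed = derive_seed(settings$seed, "chain", k))
    ch$mu <- m + s * ch$mu
    ch$sigma <- s * ch$sigma
    ch
  })
  accept <- vapply(chains, `[[`, numeric(1), "accept")
  if (mean(accept) < 0.1) {
    abort(sprintf(
      "sampler failed: mean acceptance %.3f (per chain: %s); try sampler = 'rw_metropolis' or a smaller step size",
      mean(accept), paste(sprintf("%.2f", accept), collapse = ", ")),
      class = "latstep_divergent")
  }
  keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  draws <- tibble::tibble(
    chain = rep(seq_len(settings$chains), each = keep),
    draw = rep(seq_len(keep), times = settings$chains),
    mu = unlist(lapply(chains, `[[`, "mu")),
    sigma = unlist(lapply(chains, `[[`, "sigma"))
  )
  mu_mat <- matrix(draws$mu, nrow = keep)
  sg_mat <- matrix(draws$sigma, nrow = keep)
  structure(
    list(draws = draws,
         rhat = c(mu = rhat(mu_mat), sigma = rhat(sg_mat)),
         accept = accept,
         step_size = vapply(chains, `[[`, numeric(1), "step_size"),
         settings = settings,
         n = n, sample_mean = m, sample_sd = s),
    class = "latstep_posterior"
  )
}

#' @export
print.latstep_posterior <- function(x, ...) {
  cat(sprintf(
    "<latstep_posterior> n = %d, %d draws; mu %.4f [sd %.4f], sigma %.4f; Rhat mu %.3f sigma %.3f\n",
    x$n, nrow(x$draws), mean(x$draws$mu), sd(x$draws$mu),
    mean(x$draws$sigma), x$rhat[["mu"]], x$rhat[["sigma"]]))
  invisible(x)
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half (modern practice), then the classic
#' between/within variance ratio is formed over the half-chains:
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate convergence;
#' the conventional acceptance threshold here is 1.05. Set `split = FALSE`
#' for the classic whole-chain estimator.
#'
#' @param chains A draws-by-chains numeric matrix (>= 2 chains, >= 4 draws).
#' @param split Split each chain in half first (default `TRUE`).
#' @return The Rhat estimate (scalar).
#' @export
rhat <- function(chains, split = TRUE) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L || nrow(chains) < 4L) {
    abort("need >= 2 chains of >= 4 draws", class = "latstep_bad_chains")
  }
  if (split) {
    h <- nrow(chains) %/% 2L
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[nrow(chains) - h + seq_len(h), , drop = FALSE])
  }
  n <- nrow(chains); m <- ncol(chains)
  means <- colMeans(chains)
  w <- mean(apply(chains, 2, var))
  b <- n * var(means)
  if (w == 0) return(1)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

#' Effective sample size of a draws matrix (mean estimation)
#'
#' Multi-chain initial-positive-sequence autocorrelation estimator; used to
#' form Monte-Carlo standard errors for posterior means and quantiles.
#'
#' @param chains A draws-by-chains numeric matrix.
#' @return Estimated effective sample size.
#' @export
ess_mean <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  ctr <- sweep(chains, 2, colMeans(chains))
  max_lag <- min(n - 1L, 200L)
  rho <- vapply(seq_len(max_lag), function(k) {
    num <- sum(ctr[seq_len(n - k), , drop = FALSE] *
                 ctr[k + seq_len(n - k), , drop = FALSE])
    num / ((n - k) * m)
  }, numeric(1)) / (sum(ctr^2) / (n * m))
  tau <- 1
  for (k in seq_len(max_lag)) {
    if (rho[k] < 0.01) break
    tau <- tau + 2 * rho[k]
  }
  max(n * m / tau, 1)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' @param chains A draws-by-chains numeric matrix.
#' @return `sd(draws) / sqrt(ess_mean(chains))`.
#' @export
mcse_mean <- function(chains) {
  sd(as.vector(as.matrix(chains))) / sqrt(ess_mean(chains))
}

#' Compare two groups via the posterior of their mean difference
#'
#' Samples each group's posterior independently, pairs the retained mean
#' draws in order, and forms the distribution of differences
#' `mu_young - mu_old`. Significance is judged by the central credible
#' interval excluding zero; if any of the four parameters' split-Rhat is at
#' or above 1.05 the result is flagged non-converged and the significance
#' decision withheld (`NA`).
#'
#' @param old,young Numeric per-subject value vectors for the two groups.
#' @param settings A [mcmc_settings()]; group chains derive distinct seeds.
#' @param ci_level Credible level (default 0.95).
#' @return A `latstep_comparison`: difference draws, `ci_low`, `ci_high`,
#'   `rhat_max`, `significant`, `converged`, and both group posteriors.
#' @export
#' @examples
#' cmp <- compare_groups(exact_moment_sample(20, 0.78, 0.10, 1),
#'                       exact_moment_sample(20, 0.69, 0.08, 2),
#'                       mcmc_settings(iterations = 400, burn_in = 100))
#' tidy(cmp)
compare_groups <- function(old, young, settings = mcmc_settings(),
                           ci_level = 0.95) {
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  st_old <- settings; st_old$seed <- derive_seed(settings$seed, "old")
  st_young <- settings; st_young$seed <- derive_seed(settings$seed, "young")
  post_old <- sample_posterior(old, st_old)
  post_young <- sample_posterior(young, st_young)
  diff <- post_young$draws$mu - post_old$draws$mu
  a <- (1 - ci_level) / 2
  ci <- unname(quantile(diff, c(a, 1 - a), names = FALSE))
  rhat_max <- max(post_old$rhat, post_young$rhat)
  converged <- rhat_max < 1.05
  structure(
    list(difference = diff, ci_low = ci[1], ci_high = ci[2],
         ci_level = ci_level, rhat_max = rhat_max, converged = converged,
         significant = if (converged) !(ci[1] <= 0 && 0 <= ci[2]) else NA,
         old = post_old, young = post_young),
    class = "latstep_comparison"
  )
}

#' @export
print.latstep_comparison <- function(x, ...) {
  cat(sprintf(
    "<latstep_comparison> young - old: %.4f [%.0f%% CI %.4f, %.4f], Rhat_max %.3f%s\n",
    mean(x$difference), 100 * x$ci_level, x$ci_low, x$ci_high, x$rhat_max,
    if (isTRUE(x$significant)) " *" else if (is.na(x$significant)) " (not converged)" else ""))
  invisible(x)
}

#' Closed-form conjugate oracle for the flat-prior Gaussian mean
#'
#' Under `p(mu, sigma) ~ 1/sigma`, the marginal posterior of `mu` is a
#' location-scale Student-t: location `sample_mean`, scale
#' `sample_sd / sqrt(n)`, `n - 1` degrees of freedom. Used as the
#' independent check of the MCMC sampler.
#'
#' @param n Sample size (>= 2).
#' @param sample_mean,sample_sd Sample moments (`sample_sd > 0`).
#' @return A `latstep_t` list with `location`, `scale`, `df`.
#' @export
#' @examples
#' oracle_ci(conjugate_oracle(20, 0, 1))
conjugate_oracle <- function(n, sample_mean, sample_sd) {
  check_number(n, "n", positive = TRUE)
  if (n < 2) abort("n must be >= 2")
  check_number(sample_sd, "sample_sd", positive = TRUE)
  structure(list(location = sample_mean, scale = sample_sd / sqrt(n),
                 df = n - 1),
            class = "latstep_t")
}

#' Quantiles of a location-scale t oracle
#' @param oracle A `latstep_t` from [conjugate_oracle()].
#' @param p Probabilities.
#' @return Quantiles of the marginal posterior of `mu`.
#' @export
oracle_quantile <- function(oracle, p) {
  oracle$location + oracle$scale * qt(p, oracle$df)
}

#' Central credible interval of a t oracle
#' @inheritParams oracle_quantile
#' @param ci_level Credible level.
#' @return Length-2 vector `c(low, high)`.
#' @export
oracle_ci <- function(oracle, ci_level = 0.95) {
  a <- (1 - ci_level) / 2
  oracle_quantile(oracle, c(a, 1 - a))
}

#' Monte-Carlo oracle for the credible interval of a group difference
#'
#' Simulates the exact conjugate marginals of both group means (independent
#' location-scale t variates) and returns empirical quantiles of
#' `mu_young - mu_old`, with the quantile Monte-Carlo SE.
#'
#' @param old,young `latstep_t` oracles for the two groups.
#' @param ci_level Credible level.
#' @param n_draws Monte-Carlo draws (default 1e6).
#' @param seed Integer seed.
#' @return A list `ci` (length 2), `se` (MC standard errors of the two
#'   endpoints), `n_draws`.
#' @export
oracle_diff_ci <- function(old, young, ci_level = 0.95, n_draws = 1e6,
                           seed = 1L) {
  a <- (1 - ci_level) / 2
  withr::with_seed(derive_seed(seed, "oracle-diff"), {
    d <- (young$location + young$scale * rt(n_draws, young$df)) -
      (old$location + old$scale * rt(n_draws, old$df))
    ci <- unname(quantile(d, c(a, 1 - a), names = FALSE))
    dens <- vapply(ci, function(q) {
      h <- sd(d) / 50
      mean(abs(d - q) < h) / (2 * h)
    }, numeric(1))
    list(ci = ci,
         se = sqrt(c(a * (1 - a), a * (1 - a)) / n_draws) / dens,
         n_draws = n_draws)
  })
}

#' Compare every (parameter, condition) cell of a group-sample table
#'
#' Maps [compare_groups()] over all cells of a [build_group_samples()] table
#' and assembles the results table: group means/SDs, the credible interval of
#' the young - old difference, maximal Rhat and the significance flag. Cell
#' seeds derive deterministically from the settings seed and the cell labels.
#'
#' @param samples A tibble from [build_group_samples()].
#' @param settings A [mcmc_settings()].
#' @param ci_level Credible level.
#' @return A `latstep_results` tibble: `parameter`, `condition`,
#'   `older_mean`, `older_sd`, `young_mean`, `young_sd`, `ci_low`, `ci_high`,
#'   `rhat`, `significant`. Cells whose sample variance is zero in either
#'   group cannot be fitted under the flat prior and carry NA interval,
#'   Rhat and significance columns.
#' @export
compare_cells <- function(samples, settings = mcmc_settings(),
                          ci_level = 0.95) {
  stopifnot(is.data.frame(samples),
            all(c("parameter", "condition", "group", "values") %in% names(samples)))
  wide <- samples |>
    dplyr::select("parameter", "condition", "group", "values") |>
    tidyr::pivot_wider(names_from = "group", values_from = "values")
  if (!all(c("older", "young") %in% names(wide))) {
    abort("group samples must contain both 'older' and 'young' groups")
  }
  out <- purrr::pmap(wide, function(parameter, condition, older, young) {
    st <- settings
    st$seed <- derive_seed(settings$seed, "compare", parameter, condition)
    row <- tibble::tibble(
      parameter = parameter, condition = condition,
      older_mean = mean(older), older_sd = sd(older),
      young_mean = mean(young), young_sd = sd(young),
      ci_low = NA_real_, ci_high = NA_real_,
      rhat = NA_real_, significant = NA
    )
    # zero-variance cells (all subjects identical, e.g. an SD printed as
    # 0.00) have an improper flat-prior posterior: left unfitted
    tryCatch({
      cmp <- compare_groups(older, young, st, ci_level = ci_level)
      row$ci_low <- cmp$ci_low; row$ci_high <- cmp$ci_high
      row$rhat <- cmp$rhat_max; row$significant <- cmp$significant
      row
    }, latstep_zero_variance = function(e) row)
  }) |>
    purrr::list_rbind()
  class(out) <- c("latstep_results", class(out))
  out
}
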