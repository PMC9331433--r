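# broom-style accessors and ggplot2 autoplot methods.

#' Tidy a group posterior
#'
#' One row per model parameter with posterior mean, SD, central credible
#' bounds, Rhat and effective sample size.
#'
#' @param x A `latstep_posterior`.
#' @param ci_level Credible level for the bounds.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy latstep_posterior
#' @export
tidy.latstep_posterior <- function(x, ci_level = 0.95, ...) {
  a <- (1 - ci_level) / 2
  keep <- nrow(x$draws) / x$settings$chains
  purrr::map(c("mu", "sigma"), function(term) {
    d <- x$draws[[term]]
    tibble::tibble(
      term = term, estimate = mean(d), std.error = sd(d),
      conf.low = quantile(d, a, names = FALSE),
      conf.high = quantile(d, 1 - a, names = FALSE),
      rhat = x$rhat[[term]],
      ess = ess_mean(matrix(d, nrow = keep))
    )
  }) |>
    purrr::list_rbind()
}

#' Glance at a group posterior
#'
#' @param x A `latstep_posterior`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `draws`, `chains`, `rhat_max`,
#'   `accept_mean`, `sample_mean`, `sample_sd`.
#' @method glance latstep_posterior
#' @export
glance.latstep_posterior <- function(x, ...) {
  tibble::tibble(
    n = x$n, draws = nrow(x$draws), chains = x$settings$chains,
    rhat_max = max(x$rhat), accept_mean = mean(x$accept),
    sample_mean = x$sample_mean, sample_sd = x$sample_sd
  )
}

#' Tidy a two-group comparison
#'
#' @param x A `latstep_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: posterior mean difference (young - old), its
#'   SD, credible bounds, `rhat_max`, `significant`.
#' @method tidy latstep_comparison
#' @export
tidy.latstep_comparison <- function(x, ...) {
  tibble::tibble(
    term = "mu_young - mu_old",
    estimate = mean(x$difference), std.error = sd(x$difference),
    conf.low = x$ci_low, conf.high = x$ci_high,
    rhat_max = x$rhat_max, significant = x$significant
  )
}

#' Glance at a two-group comparison
#' @param x A `latstep_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: draw count, CI level, convergence flags.
#' @method glance latstep_comparison
#' @export
glance.latstep_comparison <- function(x, ...) {
  tibble::tibble(
    draws = length(x$difference), ci_level = x$ci_level,
    rhat_max = x$rhat_max, converged = x$converged,
    significant = x$significant
  )
}

#' Plot resampled swing paths and their average
#'
#' @param object A list of `latstep_path` tibbles (or one path).
#' @param ... Unused.
#' @return A ggplot: lateral-vertical (X-Z) view of each path and the
#'   pointwise average trajectory.
#' @export
plot_trajectories <- function(object, ...) {
  paths <- if (is.data.frame(object)) list(object) else object
  df <- purrr::imap(paths, ~ dplyr::mutate(tibble::as_tibble(.x),
                                           trial = as.character(.y))) |>
    purrr::list_rbind()
  avg <- average_trajectory(paths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$trial)) +
    ggplot2::geom_path(alpha = 0.4, colour = "grey40") +
    ggplot2::geom_path(data = avg, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "lateral position X (m)", y = "vertical position Z (m)",
                  title = "Swing trajectories (grey) and average (red)") +
    ggplot2::coord_equal()
}

#' @rdname plot_trajectories
#' @method autoplot latstep_path
#' @export
autoplot.latstep_path <- function(object, ...) plot_trajectories(object, ...)

#' Plot a group posterior
#'
#' @param object A `latstep_posterior`.
#' @param ... Unused.
#' @return A ggplot of per-chain densities of the mean draws.
#' @method autoplot latstep_posterior
#' @export
autoplot.latstep_posterior <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$mu, colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(mu), colour = "chain",
                  title = sprintf("Posterior of the group mean (Rhat = %.3f)",
                                  object$rhat[["mu"]]))
}

#' Plot the posterior distribution of a group difference
#'
#' @param object A `latstep_comparison`.
#' @param ... Unused.
#' @return A ggplot: density of the young - old mean difference with the
#'   credible interval and zero marked.
#' @method autoplot latstep_comparison
#' @export
autoplot.latstep_comparison <- function(object, ...) {
  df <- tibble::tibble(difference = object$difference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "mean difference (young - old)",
                  title = sprintf("%.0f%% CI [%.3f, %.3f]%s",
                                  100 * object$ci_level, object$ci_low,
                                  object$ci_high,
                                  if (isTRUE(object$significant)) " *" else ""))
}

#' Forest-style plot of a results table
#'
#' @param object A `latstep_results` tibble from [compare_cells()].
#' @param ... Unused.
#' @return A ggplot of credible intervals of the young - old differences per
#'   parameter and condition; intervals excluding zero are highlighted.
#' @method autoplot latstep_results
#' @export
autoplot.latstep_results <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      cell = paste(.data$parameter, .data$condition))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$cell)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high,
                   colour = .data$significant), height = 0.3) +
    ggplot2::labs(x = "95% CI of the mean difference (young - old)",
                  y = NULL, colour = "CI excludes 0")
}
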