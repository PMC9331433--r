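# Trajectory-consistency scoring.
#
# Swing paths are normalized in time to u in [0, 1], cubic-spline resampled
# on a common grid (101 points by default: the conventional 0-100% grid),
# averaged pointwise, and scored by the error distance: the aggregated 3-D
# gap between each trial's path and the average path. Landing-position
# variability is the sample SD of the landed heel coordinates across trials.

#' Time-normalize and spline-resample a swing path
#'
#' Maps the swing window linearly onto normalized time `u` in `[0, 1]`,
#' fits an interpolating cubic spline per axis, and evaluates it at
#' `n_points` equally spaced `u` values. Amplitudes are untouched — only time
#' is normalized. Endpoints reproduce the raw boundary samples exactly.
#'
#' @param segment A `latstep_swing`, or a data frame with columns
#'   `time`, `x`, `y`, `z` covering one swing.
#' @param n_points Number of resampled points (default 101).
#' @param method Spline boundary condition: `"natural"` (zero second
#'   derivative, default) or `"fmm"` (knot-adjacent cubic extrapolation).
#'
#' @return A `latstep_path` tibble with columns `u`, `x`, `y`, `z`.
#' @export
normalize_and_resample <- function(segment, n_points = 101L,
                                   method = c("natural", "fmm")) {
  method <- match.arg(method)
  df <- if (inherits(segment, "latstep_swing")) segment$heel else segment
  stopifnot(is.data.frame(df), all(c("time", "x", "y", "z") %in% names(df)))
  if (nrow(df) < 4L) {
    abort("swing has fewer than 4 samples; cannot fit a cubic spline",
          class = "latstep_too_few_samples")
  }
  if (anyNA(df[c("time", "x", "y", "z")])) {
    abort("swing contains gaps", class = "latstep_marker_gap")
  }
  tr <- range(df$time)
  u_in <- (df$time - tr[1]) / diff(tr)
  u_out <- seq(0, 1, length.out = n_points)
  vals <- lapply(c("x", "y", "z"), function(a) {
    stats::spline(u_in, df[[a]], xout = u_out, method = method)$y
  })
  out <- tibble::tibble(u = u_out, x = vals[[1]], y = vals[[2]], z = vals[[3]])
  class(out) <- c("latstep_path", class(out))
  out
}

check_shared_grid <- function(paths) {
  if (!is.list(paths) || length(paths) < 1L) abort("`paths` must be a list of paths")
  u0 <- paths[[1]]$u
  ok <- vapply(paths, function(p) {
    is.data.frame(p) && all(c("u", "x", "y", "z") %in% names(p)) &&
      length(p$u) == length(u0) && max(abs(p$u - u0)) < 1e-12
  }, logical(1))
  if (!all(ok)) abort("all paths must share the same normalized-time grid",
                      class = "latstep_grid_mismatch")
  u0
}

#' Average trajectory over resampled paths
#'
#' Pointwise per-axis arithmetic mean of paths sharing one normalized grid.
#'
#' @param paths A list of `latstep_path` tibbles on a common grid.
#' @return A `latstep_path` tibble.
#' @export
average_trajectory <- function(paths) {
  u0 <- check_shared_grid(paths)
  out <- tibble::tibble(
    u = u0,
    x = rowMeans(sapply(paths, `[[`, "x")),
    y = rowMeans(sapply(paths, `[[`, "y")),
    z = rowMeans(sapply(paths, `[[`, "z"))
  )
  class(out) <- c("latstep_path", class(out))
  out
}

#' Error distance: trajectory-consistency statistic
#'
#' For each path, the 3-D Euclidean gap to the average trajectory is computed
#' at every grid point. Under the default `"mean_point"` aggregation the gaps
#' are averaged over grid points within each path and then averaged over
#' paths, yielding a mean per-point gap in metres. The literal alternative
#' `"sum_point"` sums the gaps over all grid points and all paths. Higher
#' values mean less consistent swing trajectories.
#'
#' @param paths A list of at least two `latstep_path` tibbles on one grid.
#' @param aggregation `"mean_point"` (default) or `"sum_point"`.
#' @return Error distance in metres.
#' @export
error_distance <- function(paths, aggregation = c("mean_point", "sum_point")) {
  aggregation <- match.arg(aggregation)
  check_shared_grid(paths)
  if (length(paths) < 2L) {
    abort("error distance is undefined for a single path",
          class = "latstep_too_few_paths")
  }
  avg <- average_trajectory(paths)
  gaps <- vapply(paths, function(p) {
    g <- sqrt((p$x - avg$x)^2 + (p$y - avg$y)^2 + (p$z - avg$z)^2)
    if (aggregation == "mean_point") mean(g) else sum(g)
  }, numeric(1))
  if (aggregation == "mean_point") mean(gaps) else sum(gaps)
}

#' Landing coordinates of a swing segment
#'
#' Heel-marker X/Y at the landing instant: the nearest marker-rate sample at
#' or before the force-defined landing time.
#'
#' @param segment A `latstep_swing`.
#' @return A named numeric vector `c(x = , y = )` in metres.
#' @export
landing_position <- function(segment) {
  stopifnot(inherits(segment, "latstep_swing"))
  heel <- segment$trial$heel
  idx <- max(which(heel$time <= segment$landing_time + 1e-9))
  c(x = heel$x[idx], y = heel$y[idx])
}

#' Landing-position standard deviations across trials
#'
#' Sample SD (denominator `n - 1`) of the landed heel-marker X (lateral) and
#' Y (anterior) coordinates over repeated trials of one subject/condition.
#' High values indicate inconsistent landed positions.
#'
#' @param segments A list of at least two `latstep_swing` objects.
#' @return A one-row tibble `sd_x`, `sd_y` (m), `n_trials`.
#' @export
landing_sd <- function(segments) {
  if (!is.list(segments) || length(segments) < 2L) {
    abort("landing SD needs at least two trials", class = "latstep_too_few_paths")
  }
  xy <- t(vapply(segments, landing_position, numeric(2)))
  tibble::tibble(sd_x = sd(xy[, 1]), sd_y = sd(xy[, 2]),
                 n_trials = length(segments))
}

#' Consistency summary for one subject/condition block
#'
#' Resamples every swing, then computes the error distance over all trials
#' and the landing-position SDs.
#'
#' @param segments A list of `latstep_swing` objects (>= 2).
#' @param n_points Resampling grid size.
#' @param aggregation Error-distance aggregation, see [error_distance()].
#' @return A one-row tibble `error_distance`, `sd_x`, `sd_y`, `n_trials`.
#' @export
consistency_summary <- function(segments, n_points = 101L,
                                aggregation = c("mean_point", "sum_point")) {
  aggregation <- match.arg(aggregation)
  paths <- lapply(segments, normalize_and_resample, n_points = n_points)
  lsd <- landing_sd(segments)
  tibble::tibble(
    error_distance = error_distance(paths, aggregation),
    sd_x = lsd$sd_x, sd_y = lsd$sd_y, n_trials = lsd$n_trials
  )
}
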