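# Swing-phase event detection.
#
# Heel-off: first marker sample whose 3-D displacement from a static baseline
# reference exceeds 2 mm (strict >). Landing: first force sample at or above
# 10 N (inclusive >=) that stays above threshold for a debounce window.
# Detection runs on the native sampling grids; no resampling.

#' Detect heel-off from a heel-marker series
#'
#' The baseline reference position is the per-axis median over the initial
#' `baseline_window` seconds; heel-off is the time of the first sample whose
#' Euclidean displacement from that reference strictly exceeds `threshold`
#' (2 mm by default). By default displacement is 3-D; `axes` restricts it
#' (e.g. `"z"` for vertical-only).
#'
#' @param heel A data frame with columns `time`, `x`, `y`, `z` (m).
#' @param baseline_window Length (s) of the static interval used for the
#'   baseline reference; the series must start with at least this much data.
#' @param threshold Displacement threshold in metres (default 0.002).
#' @param axes Axes included in the displacement norm.
#'
#' @return Heel-off time in seconds.
#' @export
detect_heel_off <- function(heel, baseline_window = 0.3, threshold = 0.002,
                            axes = c("x", "y", "z")) {
  stopifnot(is.data.frame(heel), all(c("time", axes) %in% names(heel)))
  check_number(threshold, "threshold", positive = TRUE)
  t <- heel$time
  if (t[length(t)] - t[1] < baseline_window) {
    abort("series must begin with at least `baseline_window` of data",
          class = "latstep_no_baseline")
  }
  base_idx <- t <= t[1] + baseline_window
  ref <- vapply(axes, function(a) median(heel[[a]][base_idx]), numeric(1))
  d2 <- Reduce(`+`, lapply(seq_along(axes), function(i) {
    (heel[[axes[i]]] - ref[i])^2
  }))
  hit <- which(d2 > threshold^2)
  if (length(hit) == 0L) {
    abort("no heel-off detected: displacement never exceeds threshold",
          class = "latstep_no_heel_off")
  }
  t[hit[1]]
}

#' Detect landing from a vertical ground-reaction-force series
#'
#' Landing is the time of the first sample at or above `threshold` (10 N by
#' default) such that the force stays at or above threshold throughout the
#' following `debounce` seconds (isolated spikes are rejected).
#'
#' @param force A data frame with columns `time` (s) and `fz` (N).
#' @param threshold Force threshold in newtons (inclusive).
#' @param debounce Duration (s) the force must remain above threshold.
#'
#' @return Landing time in seconds.
#' @export
detect_landing <- function(force, threshold = 10, debounce = 0.01) {
  stopifnot(is.data.frame(force), all(c("time", "fz") %in% names(force)))
  check_number(threshold, "threshold", positive = TRUE)
  check_number(debounce, "debounce", nonneg = TRUE)
  t <- force$time
  fz <- force$fz
  above <- fz >= threshold
  cand <- which(above)
  for (i in cand) {
    w <- t >= t[i] & t <= t[i] + debounce
    if (all(above[w])) return(t[i])
  }
  abort("no landing detected: force never sustains the threshold",
        class = "latstep_no_landing")
}

#' Extract the swing segment of a trial
#'
#' Detects heel-off and landing, then clips every stream of the trial to the
#' closed window `[heel_off, landing]` (both boundary samples included, each
#' stream on its native rate). Marker gaps (NA coordinates) inside the swing
#' window are refused rather than interpolated.
#'
#' @param trial A `latstep_trial` (from [generate_trial()] or [load_trial()]).
#' @param baseline_window,heel_threshold,force_threshold,debounce Event
#'   detection settings, see [detect_heel_off()] and [detect_landing()].
#' @param axes Axes used for the heel-off displacement norm.
#'
#' @return A `latstep_swing` object: clipped `heel`, `cog`, `force`,
#'   `moments` tibbles plus `heel_off_time`, `landing_time` and trial
#'   metadata.
#' @export
extract_swing <- function(trial, baseline_window = 0.3,
                          heel_threshold = 0.002, force_threshold = 10,
                          debounce = 0.01, axes = c("x", "y", "z")) {
  stopifnot(inherits(trial, "latstep_trial"))
  heel_off <- detect_heel_off(trial$heel, baseline_window, heel_threshold, axes)
  landing <- detect_landing(trial$force, force_threshold, debounce)
  if (landing <= heel_off) {
    abort(sprintf("event order violation: landing (%.3f s) precedes heel-off (%.3f s)",
                  landing, heel_off),
          class = "latstep_event_order")
  }
  eps <- 1e-9
  clip <- function(df) df[df$time >= heel_off - eps & df$time <= landing + eps, ]
  heel_w <- clip(trial$heel)
  if (anyNA(heel_w[c("x", "y", "z")])) {
    abort("marker gap inside the swing window; gapped swings are not analysed",
          class = "latstep_marker_gap")
  }
  structure(
    list(
      subject_id = trial$subject_id, group = trial$group,
      condition = trial$condition, trial_index = trial$trial_index,
      heel_off_time = heel_off, landing_time = landing,
      heel = heel_w, cog = clip(trial$cog),
      force = clip(trial$force), moments = clip(trial$moments),
      trial = trial
    ),
    class = "latstep_swing"
  )
}

#' @export
print.latstep_swing <- function(x, ...) {
  cat(sprintf("<latstep_swing> %s %s trial %d: [%.3f, %.3f] s (%d marker samples)\n",
              x$subject_id, x$condition, x$trial_index,
              x$heel_off_time, x$landing_time, nrow(x$heel)))
  invisible(x)
}

#' Step time of a swing segment
#'
#' Landing time minus heel-off time, in seconds.
#'
#' @param segment A `latstep_swing` from [extract_swing()].
#' @return Step time (s), strictly positive.
#' @export
step_time <- function(segment) {
  stopifnot(inherits(segment, "latstep_swing"))
  dt <- segment$landing_time - segment$heel_off_time
  if (!is.finite(dt) || dt <= 0) {
    abort("invalid segment: non-positive step time", class = "latstep_event_order")
  }
  dt
}
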