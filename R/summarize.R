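# Per-trial scalar summaries and group-sample assembly.
#
# Scalar outcomes (step time, COG displacement maxima, joint-moment maxima)
# are taken from the tenth trial of each condition block; the consistency
# statistics (error distance, landing SDs) use all trials of the block.

#' Maximal COG displacement during the swing
#'
#' Per axis, the maximum over the swing window of the absolute displacement
#' of the COG from its position at the reference instant (heel-off by
#' default; `reference = "start"` uses the first sample of the series).
#'
#' @param cog A data frame `time, x, y, z` covering the swing window.
#' @param heel_off_time,landing_time Swing boundaries (s).
#' @param reference `"heel_off"` (default) or `"start"`.
#' @param signed If `TRUE`, return the signed extremum of largest magnitude
#'   instead of the absolute maximum.
#' @return Named vector `c(x = , y = , z = )` in metres (all >= 0 unless
#'   `signed`).
#' @export
cog_max_displacement <- function(cog, heel_off_time, landing_time,
                                 reference = c("heel_off", "start"),
                                 signed = FALSE) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(cog), all(c("time", "x", "y", "z") %in% names(cog)))
  eps <- 1e-9
  w <- cog$time >= heel_off_time - eps & cog$time <= landing_time + eps
  if (!any(w)) abort("COG series does not cover the swing window")
  ref_idx <- if (reference == "heel_off") {
    max(which(cog$time <= heel_off_time + eps))
  } else 1L
  vapply(c("x", "y", "z"), function(a) {
    d <- cog[[a]][w] - cog[[a]][ref_idx]
    if (signed) d[which.max(abs(d))] else max(abs(d))
  }, numeric(1))
}

#' Maximal joint moments during the swing
#'
#' Per-channel maximum of the body-mass-normalized moment curves (hip
#' extension, knee extension, ankle plantar-flexion; extension and
#' plantar-flexion positive) over the swing window.
#'
#' @param moments A data frame `time, hip_ext, knee_ext, ankle_pf` (Nm/kg).
#' @param heel_off_time,landing_time Swing boundaries (s).
#' @return Named vector `c(hip_ext = , knee_ext = , ankle_pf = )` in Nm/kg.
#' @export
moment_maxima <- function(moments, heel_off_time, landing_time) {
  stopifnot(is.data.frame(moments),
            all(c("time", "hip_ext", "knee_ext", "ankle_pf") %in% names(moments)))
  eps <- 1e-9
  w <- moments$time >= heel_off_time - eps & moments$time <= landing_time + eps
  if (!any(w)) abort("moment series does not cover the swing window")
  vapply(c("hip_ext", "knee_ext", "ankle_pf"),
         function(a) max(moments[[a]][w]), numeric(1))
}

#' Summarise one swing segment into its scalar outcomes
#'
#' @param segment A `latstep_swing`.
#' @inheritParams cog_max_displacement
#' @return One-row tibble: identifiers plus `step_time`, `cog_x/y/z`,
#'   `hip_moment`, `knee_moment`, `ankle_moment`, `landing_x`, `landing_y`.
#' @export
summarize_trial <- function(segment, reference = c("heel_off", "start")) {
  stopifnot(inherits(segment, "latstep_swing"))
  cogm <- cog_max_displacement(segment$trial$cog, segment$heel_off_time,
                               segment$landing_time, reference = reference)
  mom <- moment_maxima(segment$trial$moments, segment$heel_off_time,
                       segment$landing_time)
  land <- landing_position(segment)
  tibble::tibble(
    subject_id = segment$subject_id, group = segment$group,
    condition = segment$condition, trial_index = segment$trial_index,
    step_time = step_time(segment),
    cog_x = cogm[["x"]], cog_y = cogm[["y"]], cog_z = cogm[["z"]],
    hip_moment = mom[["hip_ext"]], knee_moment = mom[["knee_ext"]],
    ankle_moment = mom[["ankle_pf"]],
    landing_x = land[["x"]], landing_y = land[["y"]]
  )
}

#' Tenth-trial selection rule for scalar outcomes
#'
#' Scalar outcomes adopt the value of the last (tenth) trial of the condition
#' block; consistency statistics (error distance, landing SDs) bypass this
#' rule and use all trials. Requires a complete block.
#'
#' @param summaries A tibble of exactly `n_trials` rows from
#'   [summarize_trial()], one per trial of one subject/condition block.
#' @param parameter Scalar column name (e.g. `"step_time"`).
#' @param n_trials Expected block size (default 10).
#' @return The parameter value of the trial with the highest `trial_index`.
#' @export
select_scalar_trial <- function(summaries, parameter, n_trials = 10L) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) != n_trials) {
    abort(sprintf("expected exactly %d trial summaries, got %d",
                  n_trials, nrow(summaries)),
          class = "latstep_incomplete_block")
  }
  if (!parameter %in% names(summaries)) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  summaries[[parameter]][which.max(summaries$trial_index)]
}

#' Analyse a cohort of trials into per-subject scalar outcomes
#'
#' Runs event detection, trajectory consistency scoring and scalar
#' summarisation over a cohort tibble (see [generate_cohort()] or
#' [load_cohort()]): scalars from the tenth trial, error distance and landing
#' SDs from all trials of each subject/condition block.
#'
#' @param cohort A cohort tibble with list-column `trial`.
#' @param n_points Resampling grid size for consistency scoring.
#' @param aggregation Error-distance aggregation.
#' @param ... Passed to [extract_swing()].
#' @return A long tibble `subject_id`, `group`, `condition`, `parameter`,
#'   `value` covering all ten outcome parameters.
#' @export
summarize_cohort <- function(cohort, n_points = 101L,
                             aggregation = c("mean_point", "sum_point"), ...) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(cohort), "trial" %in% names(cohort))
  cohort |>
    dplyr::group_by(.data$subject_id, .data$group, .data$condition) |>
    dplyr::group_modify(function(block, key) {
      segs <- lapply(block$trial, extract_swing, ...)
      sums <- purrr::map(segs, summarize_trial) |> purrr::list_rbind()
      n_tr <- nrow(sums)
      scalars <- vapply(
        c("step_time", "cog_x", "cog_y", "cog_z",
          "hip_moment", "knee_moment", "ankle_moment"),
        function(p) select_scalar_trial(sums, p, n_trials = n_tr), numeric(1))
      cons <- consistency_summary(segs, n_points = n_points,
                                  aggregation = aggregation)
      tibble::tibble(
        parameter = c(names(scalars), "error_distance", "sd_x", "sd_y"),
        value = c(unname(scalars), cons$error_distance, cons$sd_x, cons$sd_y)
      )
    }) |>
    dplyr::ungroup()
}

#' Assemble per-subject values into group samples
#'
#' Pivots the long per-subject outcome table into one row per
#' (parameter, condition, group) cell, each holding the per-subject values
#' the Bayesian comparison consumes. Incomplete cells (a subject missing a
#' condition block) are rejected with the offending subjects named.
#'
#' @param scalars A long tibble `subject_id`, `group`, `condition`,
#'   `parameter`, `value` (see [summarize_cohort()] or
#'   [simulate_scalar_cohort()]).
#' @param n_per_group Expected subjects per group cell.
#' @return A tibble `parameter`, `condition`, `group`, `n`, and list-column
#'   `values`.
#' @export
build_group_samples <- function(scalars, n_per_group = 20L) {
  stopifnot(is.data.frame(scalars),
            all(c("subject_id", "group", "condition", "parameter", "value")
                %in% names(scalars)))
  if (anyNA(scalars$value) || !all(is.finite(scalars$value))) {
    abort("non-finite outcome values in the scalar table")
  }
  expected <- tidyr::expand_grid(
    subject_id = unique(scalars$subject_id),
    condition = unique(scalars$condition),
    parameter = unique(scalars$parameter)
  )
  missing <- dplyr::anti_join(
    expected, scalars, by = c("subject_id", "condition", "parameter"))
  if (nrow(missing) > 0L) {
    abort(sprintf("incomplete condition blocks for subject(s): %s",
                  paste(unique(missing$subject_id), collapse = ", ")),
          class = "latstep_incomplete_block")
  }
  out <- scalars |>
    dplyr::group_by(.data$parameter, .data$condition, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     values = list(.data$value), .groups = "drop")
  bad <- out$n != n_per_group
  if (any(bad)) {
    abort(sprintf("group cells with n != %d: %s", n_per_group,
                  paste(sprintf("(%s, %s, %s): %d", out$parameter[bad],
                                out$condition[bad], out$group[bad], out$n[bad]),
                        collapse = "; ")),
          class = "latstep_incomplete_block")
  }
  out
}
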