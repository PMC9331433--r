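#' Study design for a lateral obstacle-crossing experiment
#'
#' Encodes the experimental design of a two-group lateral obstacle-crossing
#' study: each subject crosses an obstacle set at a fraction of their body
#' height, placed lateral to the stance foot, repeatedly under four speed /
#' initial-posture conditions. The defaults reproduce the canonical design:
#' 20 subjects per group, 10 trials in each of 4 conditions (40 per subject),
#' obstacle at 15% of body height placed 0.10 m lateral to the right foot,
#' leaning start at 70% of the lateral limit of stability, markers sampled at
#' 100 Hz and the force plate at 1000 Hz.
#'
#' @param n_per_group Subjects per group.
#' @param conditions Ordered condition labels.
#' @param trials_per_condition Trials per (subject, condition).
#' @param obstacle_height_fraction Obstacle height as a fraction of body height.
#' @param obstacle_lateral_offset Distance (m) from the right foot to the near
#'   edge of the obstacle, along +X (lateral, rightward).
#' @param obstacle_depth Lateral extent (m) of the obstacle box.
#' @param leaning_fraction_of_los Fraction of the lateral limit of stability at
#'   which leaning-condition trials start.
#' @param los_excursion Maximal lateral centre-of-pressure excursion (m) used
#'   to define the limit of stability. Subject-specific in a real protocol; a
#'   single configurable value here.
#' @param marker_rate,force_rate Sampling rates in Hz; `force_rate` must be an
#'   integer multiple of `marker_rate`.
#'
#' @return A `latstep_design` list.
#' @export
#' @examples
#' study_design()
study_design <- function(n_per_group = 20L,
                         conditions = c("normal", "fast", "leaning", "leaning_fast"),
                         trials_per_condition = 10L,
                         obstacle_height_fraction = 0.15,
                         obstacle_lateral_offset = 0.10,
                         obstacle_depth = 0.03,
                         leaning_fraction_of_los = 0.70,
                         los_excursion = 0.10,
                         marker_rate = 100,
                         force_rate = 1000) {
  check_number(n_per_group, "n_per_group", positive = TRUE)
  check_number(trials_per_condition, "trials_per_condition", positive = TRUE)
  check_number(obstacle_height_fraction, "obstacle_height_fraction", positive = TRUE)
  check_number(obstacle_lateral_offset, "obstacle_lateral_offset", nonneg = TRUE)
  check_number(obstacle_depth, "obstacle_depth", positive = TRUE)
  check_number(leaning_fraction_of_los, "leaning_fraction_of_los")
  if (leaning_fraction_of_los <= 0 || leaning_fraction_of_los >= 1) {
    abort("`leaning_fraction_of_los` must lie strictly between 0 and 1.")
  }
  check_number(los_excursion, "los_excursion", positive = TRUE)
  check_number(marker_rate, "marker_rate", positive = TRUE)
  check_number(force_rate, "force_rate", positive = TRUE)
  if (abs(force_rate / marker_rate - round(force_rate / marker_rate)) > 1e-9) {
    abort("`force_rate` must be an integer multiple of `marker_rate`.")
  }
  if (!is.character(conditions) || anyDuplicated(conditions) > 0 || length(conditions) < 1) {
    abort("`conditions` must be distinct labels.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      conditions = conditions,
      trials_per_condition = as.integer(trials_per_condition),
      obstacle_height_fraction = obstacle_height_fraction,
      obstacle_lateral_offset = obstacle_lateral_offset,
      obstacle_depth = obstacle_depth,
      leaning_fraction_of_los = leaning_fraction_of_los,
      los_excursion = los_excursion,
      marker_rate = marker_rate,
      force_rate = force_rate
    ),
    class = "latstep_design"
  )
}

#' @export
print.latstep_design <- function(x, ...) {
  cat("<latstep_design>\n")
  cat(sprintf("  %d subjects/group; %s\n", x$n_per_group,
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  %d trials/condition; obstacle %.0f%% height at %.2f m lateral\n",
              x$trials_per_condition, 100 * x$obstacle_height_fraction,
              x$obstacle_lateral_offset))
  cat(sprintf("  leaning start %.0f%% of LOS (%.2f m); markers %g Hz, force %g Hz\n",
              100 * x$leaning_fraction_of_los, x$los_excursion,
              x$marker_rate, x$force_rate))
  invisible(x)
}

#' Generate a cohort of subject profiles
#'
#' Draws per-subject anthropometrics for the two groups. Group-level height and
#' weight distributions default to the study population: older adults
#' 153.5 +/- 4.2 cm and 51.6 +/- 6.8 kg, young adults 164.4 +/- 7.3 cm and
#' 56.2 +/- 7.6 kg. All subjects are right-footed.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer seed; profiles are reproducible given the seed.
#' @param group_stats Optional tibble with columns `group`, `height_mean`,
#'   `height_sd`, `weight_mean`, `weight_sd` (heights in m, weights in kg).
#'
#' @return A tibble with columns `subject_id`, `group` (`"older"`/`"young"`),
#'   `height` (m), `weight` (kg), `dominant_side`.
#' @export
#' @examples
#' subject_profiles(n_per_group = 3, seed = 1)
subject_profiles <- function(n_per_group = 20L, seed = 1L, group_stats = NULL) {
  if (is.null(group_stats)) {
    group_stats <- tibble::tibble(
      group = c("older", "young"),
      height_mean = c(1.535, 1.644), height_sd = c(0.042, 0.073),
      weight_mean = c(51.6, 56.2), weight_sd = c(6.8, 7.6)
    )
  }
  withr::with_seed(derive_seed(seed, "profiles"), {
    purrr::pmap(group_stats, function(group, height_mean, height_sd,
                                      weight_mean, weight_sd) {
      tibble::tibble(
        subject_id = sprintf("%s%02d", substr(group, 1, 1), seq_len(n_per_group)),
        group = group,
        height = pmax(1.2, rnorm(n_per_group, height_mean, height_sd)),
        weight = pmax(30, rnorm(n_per_group, weight_mean, weight_sd)),
        dominant_side = "right"
      )
    }) |>
      purrr::list_rbind()
  })
}

#' Noise model for the synthetic generator
#'
#' Controls trial-to-trial variability of the generated crossing motions:
#' spatial jitter of the swing arc control points, scatter of the landing
#' position, and timing jitter of the step duration. A calibration table
#' (see [default_calibration()]) supplies the group-level scalar means and SDs
#' from which per-subject outcome targets are drawn.
#'
#' @param trajectory_sd Spatial SD (m) of per-trial arc control-point jitter.
#' @param landing_sd_x,landing_sd_y Trial-to-trial SD (m) of the landed heel
#'   position, lateral and anterior.
#' @param timing_sd Trial-to-trial SD (s) of the step duration.
#' @param calibration Tibble of group-level scalar means/SDs per
#'   (parameter, condition, group); defaults to [default_calibration()].
#'
#' @return A `latstep_noise` list.
#' @export
noise_model <- function(trajectory_sd = 0.01,
                        landing_sd_x = 0.02,
                        landing_sd_y = 0.015,
                        timing_sd = 0.05,
                        calibration = default_calibration()) {
  for (nm in c("trajectory_sd", "landing_sd_x", "landing_sd_y", "timing_sd")) {
    check_number(get(nm), nm, nonneg = TRUE)
  }
  structure(
    list(trajectory_sd = trajectory_sd,
         landing_sd_x = landing_sd_x, landing_sd_y = landing_sd_y,
         timing_sd = timing_sd, calibration = calibration),
    class = "latstep_noise"
  )
}

#' Zero-noise model
#'
#' Convenience wrapper: all trial-to-trial SDs zero, so repeated trials of a
#' subject/condition are identical and arcs follow their programmed shape
#' exactly.
#'
#' @inheritParams noise_model
#' @return A `latstep_noise` list.
#' @export
zero_noise <- function(calibration = default_calibration()) {
  noise_model(0, 0, 0, 0, calibration = calibration)
}

#' Default group-level outcome calibration table
#'
#' The published group summary statistics the synthetic cohort is calibrated
#' to: for each outcome parameter, condition and group, the mean and SD of the
#' per-subject values (n = 20 per group). Outcomes are the maximal COG
#' displacement per axis (m), maximal hip extension / knee extension / ankle
#' plantar-flexion moments (Nm/kg), landing-position SDs (m), error distance
#' (m) and step time (s).
#'
#' Note the moment rows of the source table duplicate the COG rows verbatim
#' (an apparent typesetting fault in the source); they are retained as printed
#' so that the calibration covers every tabulated cell.
#'
#' @return A tibble with columns `parameter`, `condition`, `group`, `mean`, `sd`.
#' @export
#' @examples
#' dplyr::filter(default_calibration(), parameter == "step_time")
default_calibration <- function() {
  cell <- function(parameter, om, os, ym, ys) {
    tibble::tibble(
      parameter = parameter,
      condition = rep(conditions_all(), 2L),
      group = rep(c("older", "young"), each = 4L),
      mean = c(om, ym), sd = c(os, ys)
    )
  }
  dplyr::bind_rows(
    cell("cog_x", c(0.27, 0.34, 0.36, 0.40), c(0.14, 0.30, 0.37, 0.42),
         c(0.25, 0.23, 0.22, 0.21), c(0.03, 0.04, 0.06, 0.04)),
    cell("cog_y", c(0.06, 0.08, 0.07, 0.07), c(0.09, 0.08, 0.08, 0.09),
         c(0.03, 0.04, 0.04, 0.04), c(0.01, 0.02, 0.02, 0.02)),
    cell("cog_z", c(0.19, 0.30, 0.31, 0.32), c(0.33, 0.51, 0.55, 0.46),
         c(0.08, 0.08, 0.08, 0.08), c(0.01, 0.01, 0.02, 0.01)),
    cell("hip_moment", c(0.27, 0.34, 0.36, 0.40), c(0.14, 0.30, 0.37, 0.42),
         c(0.25, 0.23, 0.22, 0.21), c(0.03, 0.04, 0.06, 0.04)),
    cell("knee_moment", c(0.06, 0.08, 0.07, 0.07), c(0.09, 0.08, 0.08, 0.09),
         c(0.03, 0.04, 0.04, 0.04), c(0.01, 0.02, 0.02, 0.02)),
    cell("ankle_moment", c(0.19, 0.30, 0.31, 0.32), c(0.33, 0.51, 0.55, 0.46),
         c(0.08, 0.08, 0.08, 0.08), c(0.01, 0.01, 0.02, 0.01)),
    cell("sd_x", c(0.03, 0.02, 0.03, 0.02), c(0.03, 0.03, 0.03, 0.02),
         c(0.02, 0.02, 0.02, 0.02), c(0.01, 0.01, 0.00, 0.02)),
    cell("sd_y", c(0.02, 0.02, 0.02, 0.02), c(0.02, 0.02, 0.02, 0.01),
         c(0.02, 0.01, 0.01, 0.02), c(0.01, 0.01, 0.00, 0.01)),
    cell("error_distance", c(0.018, 0.016, 0.021, 0.016), c(0.008, 0.007, 0.008, 0.008),
         c(0.017, 0.016, 0.017, 0.014), c(0.005, 0.005, 0.005, 0.005)),
    cell("step_time", c(0.83, 0.66, 0.78, 0.63), c(0.09, 0.08, 0.10, 0.08),
         c(0.81, 0.62, 0.69, 0.54), c(0.09, 0.05, 0.08, 0.07))
  )
}

calibration_cell <- function(calibration, parameter, condition, group) {
  row <- calibration[calibration$parameter == parameter &
                       calibration$condition == condition &
                       calibration$group == group, ]
  if (nrow(row) != 1L) {
    abort(sprintf("calibration cell (%s, %s, %s) missing or duplicated",
                  parameter, condition, group))
  }
  row
}
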