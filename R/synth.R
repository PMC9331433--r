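# Synthetic trial generator.
#
# A crossing trial is a quiet-standing interval, a smooth swing arc of the
# heel marker over the obstacle, and a landing. The arc is parameterised per
# axis on normalized swing time s in [0, 1]:
#   x(s) = Lx * Q(s) + jx * B(s)      (lateral travel to the landing point)
#   y(s) = Ly * Q(s) + jy * B(s)      (small anterior drift)
#   z(s) = z0 + (apex - z0) * B(s)    (arc over the obstacle)
# with Q the quintic smoothstep (zero velocity/acceleration at both ends) and
# B(s) = sin(pi s)^2 a unimodal bump. Both are C2, so the marker is exactly
# static before heel-off and after landing. COG and joint-moment streams are
# smooth curves whose extrema equal programmed per-subject scalar targets;
# inverse dynamics is out of scope. The vertical force is zero until foot
# contact, then ramps linearly to body weight over 50 ms.

heel_base_z <- 0.02   # resting heel-marker height (m)
ramp_time <- 0.05     # force ramp duration at landing (s)
gravity <- 9.80665

# smallest normalized time at which the 3-D displacement from the start
# position exceeds `threshold` (continuous-time ground truth)
swing_threshold_crossing <- function(lx, ly, jx, jy, dz, threshold = 0.002) {
  f <- function(s) {
    q <- smoothstep5(s); b <- bump(s)
    sqrt((lx * q + jx * b)^2 + (ly * q + jy * b)^2 + (dz * b)^2) - threshold
  }
  grid <- seq(0, 1, by = 1e-3)
  vals <- f(grid)
  k <- which(vals > 0)[1]
  if (is.na(k) || k == 1L) abort("degenerate swing: displacement never exceeds threshold")
  stats::uniroot(f, c(grid[k - 1L], grid[k]), tol = 1e-12)$root
}

default_scalar_targets <- function(calibration, condition, group) {
  pars <- c("cog_x", "cog_y", "cog_z", "hip_moment", "knee_moment",
            "ankle_moment", "step_time")
  vals <- vapply(pars, function(p) {
    calibration_cell(calibration, p, condition, group)$mean
  }, numeric(1))
  as.list(vals)
}

#' Generate one synthetic crossing trial
#'
#' Simulates a single lateral obstacle-crossing attempt for one subject:
#' 3-D heel-marker and whole-body COG trajectories at the marker rate, a
#' vertical ground-reaction force at the force rate, and body-mass-normalized
#' joint-moment curves (hip extension, knee extension, ankle plantar-flexion).
#' The heel is quasi-static for `pre_time` seconds, then follows a smooth arc
#' clearing an obstacle of height `obstacle_height_fraction * height` placed
#' `obstacle_lateral_offset` metres lateral, and lands beyond it. In leaning
#' conditions the COG starts displaced to `leaning_fraction_of_los *
#' los_excursion` laterally. The generator records its continuous-time ground
#' truth (2 mm heel-off crossing, 10 N force crossing, landing position,
#' programmed extrema) in the `truth` element, for validating event detection.
#'
#' A trial whose noisy arc would intersect the obstacle box is redrawn with a
#' derived seed (up to `max_redraws` attempts), mirroring the exclusion of
#' tripped trials in the experimental protocol.
#'
#' @param profile A one-row data frame (or list) with at least `subject_id`,
#'   `group`, `height`, `weight`; see [subject_profiles()].
#' @param condition One of the design's condition labels.
#' @param design A [study_design()].
#' @param noise A [noise_model()]; use [zero_noise()] for deterministic arcs.
#' @param seed Integer seed; the trial is reproducible given the seed.
#' @param targets Optional named list of programmed per-trial scalars
#'   (`step_time`, `cog_x/y/z`, `hip_moment`, `knee_moment`, `ankle_moment`,
#'   `landing_x`, `landing_y`). Unset entries fall back to the calibration
#'   means for (condition, group).
#' @param trial_index Trial number within the condition block.
#' @param pre_time,post_time Quiet time (s) before heel-off / after landing.
#' @param clearance Programmed apex clearance (m) above the obstacle.
#' @param min_clearance Minimal admissible gap (m) between arc and obstacle.
#' @param max_redraws Redraw budget for obstacle-intersecting noisy arcs.
#'
#' @return A `latstep_trial` object: tibbles `heel`, `cog` (`time, x, y, z`),
#'   `force` (`time, fz`), `moments` (`time, hip_ext, knee_ext, ankle_pf`),
#'   subject metadata, and the generator `truth`.
#' @export
#' @examples
#' pr <- subject_profiles(2, seed = 1)[1, ]
#' tr <- generate_trial(pr, "normal", seed = 7)
#' tr$truth$step_time
generate_trial <- function(profile, condition,
                           design = study_design(),
                           noise = noise_model(),
                           seed = 1L,
                           targets = NULL,
                           trial_index = 1L,
                           pre_time = 0.5, post_time = 0.4,
                           clearance = 0.05, min_clearance = 0.005,
                           max_redraws = 20L) {
  if (is.data.frame(profile)) profile <- as.list(profile[1, ])
  if (!condition %in% design$conditions) {
    abort(sprintf("unknown condition '%s' (design has: %s)",
                  condition, paste(design$conditions, collapse = ", ")),
          class = "latstep_bad_condition")
  }
  group <- profile$group
  height <- profile$height
  weight <- profile$weight
  check_number(height, "height", positive = TRUE)
  check_number(weight, "weight", positive = TRUE)

  base <- default_scalar_targets(noise$calibration, condition, group)
  base[names(targets)] <- targets
  h_obs <- design$obstacle_height_fraction * height
  obs_x <- c(design$obstacle_lateral_offset,
             design$obstacle_lateral_offset + design$obstacle_depth)
  lx_default <- obs_x[2] + 0.17   # land well beyond the far obstacle edge
  bw <- weight * gravity
  f_off <- ramp_time * 10 / bw    # contact -> 10 N crossing

  for (attempt in seq_len(max_redraws)) {
    par <- withr::with_seed(derive_seed(seed, "trial-draw", attempt), {
      list(
        st = (base$step_time %||% 0.8) + rnorm(1) * noise$timing_sd,
        lx = (base$landing_x %||% lx_default) + rnorm(1) * noise$landing_sd_x,
        ly = (base$landing_y %||% 0.02) + rnorm(1) * noise$landing_sd_y,
        apex = h_obs + clearance + rnorm(1) * noise$trajectory_sd,
        jx = rnorm(1) * noise$trajectory_sd,
        jy = rnorm(1) * noise$trajectory_sd
      )
    })
    par$st <- max(par$st, 0.2)
    par$lx <- max(par$lx, obs_x[2] + 0.05)
    par$apex <- max(par$apex, h_obs + min_clearance + heel_base_z)

    # obstacle clearance of the noisy arc
    s_grid <- seq(0, 1, by = 1e-3)
    xg <- par$lx * smoothstep5(s_grid) + par$jx * bump(s_grid)
    zg <- heel_base_z + (par$apex - heel_base_z) * bump(s_grid)
    over <- xg >= obs_x[1] & xg <= obs_x[2]
    if (any(over) && min(zg[over]) - h_obs >= min_clearance) break
    if (!any(over)) break   # arc never above the obstacle footprint: clear
    if (attempt == max_redraws) {
      abort(sprintf("no obstacle-clearing arc found in %d redraws for %s/%s",
                    max_redraws, profile$subject_id, condition))
    }
  }

  dz <- par$apex - heel_base_z
  s2mm <- swing_threshold_crossing(par$lx, par$ly, par$jx, par$jy, dz)
  t_swing <- (par$st - f_off) / (1 - s2mm)   # contact-to-onset duration
  if (!is.finite(t_swing) || t_swing <= 0) {
    abort("programmed step time too short for the arc shape")
  }
  t_on <- pre_time
  t_contact <- t_on + t_swing
  total <- t_on + t_swing + post_time

  tm <- seq.int(0, ceiling(total * design$marker_rate)) / design$marker_rate
  s <- pmin(pmax((tm - t_on) / t_swing, 0), 1)
  q <- smoothstep5(s); b <- bump(s)
  heel <- tibble::tibble(
    time = tm,
    x = par$lx * q + par$jx * b,
    y = par$ly * q + par$jy * b,
    z = heel_base_z + dz * b
  )

  cog0 <- c(if (is_leaning(condition))
    design$leaning_fraction_of_los * design$los_excursion else 0,
    0, 0.55 * height)
  cog <- tibble::tibble(
    time = tm,
    x = cog0[1] + base$cog_x * q,
    y = cog0[2] + base$cog_y * q,
    z = cog0[3] + base$cog_z * b
  )
  moments <- tibble::tibble(
    time = tm,
    hip_ext = base$hip_moment * b,
    knee_ext = base$knee_moment * b,
    ankle_pf = base$ankle_moment * b
  )

  tf <- seq.int(0, ceiling(total * design$force_rate)) / design$force_rate
  force <- tibble::tibble(
    time = tf,
    fz = pmin(pmax((tf - t_contact) / ramp_time, 0), 1) * bw
  )

  structure(
    list(
      subject_id = profile$subject_id %||% "s01",
      group = group, condition = condition,
      trial_index = as.integer(trial_index),
      height = height, weight = weight,
      heel = heel, cog = cog, force = force, moments = moments,
      design = design,
      truth = list(
        onset = t_on,
        heel_off = t_on + s2mm * t_swing,
        contact = t_contact,
        landing = t_contact + f_off,
        step_time = par$st,
        landing_xy = c(x = par$lx, y = par$ly),
        cog_max = c(x = abs(base$cog_x), y = abs(base$cog_y), z = abs(base$cog_z)),
        moment_max = c(hip_ext = base$hip_moment, knee_ext = base$knee_moment,
                       ankle_pf = base$ankle_moment),
        obstacle = list(height = h_obs, x_range = obs_x, apex = par$apex),
        cog_start = cog0,
        redraws = attempt - 1L
      )
    ),
    class = "latstep_trial"
  )
}

#' @export
print.latstep_trial <- function(x, ...) {
  cat(sprintf("<latstep_trial> %s %s trial %d: step %.3f s, land (%.3f, %.3f) m\n",
              x$subject_id, x$condition, x$trial_index,
              x$truth$step_time, x$truth$landing_xy[1], x$truth$landing_xy[2]))
  invisible(x)
}

#' Generate a full synthetic cohort of trials
#'
#' Runs the study design over a profile table: every subject performs
#' `trials_per_condition` trials in every condition. Per-subject outcome
#' targets (step time, COG and moment extrema) are drawn once per
#' (subject, condition) from the calibration table's group cells, so
#' between-subject variance follows the calibrated group SDs; the noise model
#' adds trial-to-trial scatter on top. All trial seeds derive deterministically
#' from the master seed.
#'
#' @param design A [study_design()].
#' @param profiles A profile tibble; must contain exactly
#'   `2 * design$n_per_group` rows (see [subject_profiles()]).
#' @param noise A [noise_model()].
#' @param seed Master integer seed.
#' @param ... Passed on to [generate_trial()] (e.g. `pre_time`).
#'
#' @return A tibble with one row per trial: `subject_id`, `group`,
#'   `condition`, `trial_index`, and list-column `trial` of `latstep_trial`.
#' @export
generate_cohort <- function(design = study_design(),
                            profiles = subject_profiles(design$n_per_group),
                            noise = noise_model(),
                            seed = 1L, ...) {
  if (nrow(profiles) != 2L * design$n_per_group) {
    abort(sprintf("profile list size mismatch: expected %d profiles, got %d",
                  2L * design$n_per_group, nrow(profiles)),
          class = "latstep_bad_profiles")
  }
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(profiles)),
    condition = design$conditions
  )
  rows <- purrr::pmap(grid, function(i, condition) {
    pr <- as.list(profiles[i, ])
    tgt <- withr::with_seed(
      derive_seed(seed, "subject", pr$subject_id, condition), {
        cal <- noise$calibration
        draw <- function(p, lo = 0.005) {
          cc <- calibration_cell(cal, p, condition, pr$group)
          max(lo, cc$mean + cc$sd * rnorm(1))
        }
        list(step_time = draw("step_time", lo = 0.25),
             cog_x = draw("cog_x"), cog_y = draw("cog_y"), cog_z = draw("cog_z"),
             hip_moment = draw("hip_moment", lo = 0),
             knee_moment = draw("knee_moment", lo = 0),
             ankle_moment = draw("ankle_moment", lo = 0))
      })
    purrr::map(seq_len(design$trials_per_condition), function(k) {
      generate_trial(pr, condition, design, noise,
                     seed = derive_seed(seed, "trial", pr$subject_id, condition, k),
                     targets = tgt, trial_index = k, ...)
    })
  })
  cohort <- tidyr::expand_grid(
    i = seq_len(nrow(profiles)),
    condition = design$conditions
  )
  cohort$trials <- rows
  cohort |>
    tidyr::unnest_longer("trials", values_to = "trial") |>
    dplyr::mutate(
      subject_id = purrr::map_chr(.data$trial, "subject_id"),
      group = purrr::map_chr(.data$trial, "group"),
      trial_index = purrr::map_int(.data$trial, "trial_index")
    ) |>
    dplyr::select("subject_id", "group", "condition", "trial_index", "trial")
}

#' Sample with exact first and second sample moments
#'
#' Draws `n` values whose sample mean equals `target_mean` and whose sample SD
#' (denominator `n - 1`) equals `target_sd` exactly (to floating-point
#' round-off): a standard normal draw is centred and rescaled. Used to rebuild
#' per-subject outcome cells whose printed group mean/SD must be reproduced
#' exactly by the synthetic cohort.
#'
#' @param n Number of values (>= 2 when `target_sd > 0`).
#' @param target_mean,target_sd Target sample moments; `target_sd >= 0`.
#' @param seed Integer seed.
#'
#' @return A numeric vector of length `n`.
#' @export
#' @examples
#' x <- exact_moment_sample(20, 0.78, 0.10, seed = 1)
#' c(mean(x), sd(x))
exact_moment_sample <- function(n, target_mean, target_sd, seed = 1L) {
  check_number(n, "n", positive = TRUE)
  check_number(target_mean, "target_mean")
  check_number(target_sd, "target_sd", nonneg = TRUE)
  n <- as.integer(n)
  if (target_sd == 0) return(rep(target_mean, n))
  if (n < 2L) {
    abort("n must be >= 2 when target_sd > 0", class = "latstep_bad_n")
  }
  withr::with_seed(derive_seed(seed, "exact-moment", n), {
    repeat {
      z <- rnorm(n)
      z <- z - mean(z)
      s <- sd(z)
      if (s > 0) break
    }
    target_mean + z * (target_sd / s)
  })
}

#' Simulate per-subject scalar outcomes for the whole study
#'
#' Generates the per-subject scalar outcome table directly (bypassing time
#' series): one value per (subject, condition, parameter), drawn per group
#' cell from the calibration table. With `exact = TRUE` each cell is drawn via
#' [exact_moment_sample()], so its sample mean and SD reproduce the calibrated
#' group statistics exactly — the mode used to re-derive the published
#' between-group comparisons.
#'
#' @param design A [study_design()].
#' @param calibration Calibration tibble, see [default_calibration()].
#' @param seed Master seed.
#' @param exact Use exact-sample-moment draws (default) or plain normal draws.
#'
#' @return A tibble `subject_id`, `group`, `condition`, `parameter`, `value`.
#' @export
simulate_scalar_cohort <- function(design = study_design(),
                                   calibration = default_calibration(),
                                   seed = 1L, exact = TRUE) {
  n <- design$n_per_group
  cells <- calibration[calibration$condition %in% design$conditions, ]
  purrr::pmap(cells, function(parameter, condition, group, mean, sd) {
    s <- derive_seed(seed, "cell", parameter, condition, group)
    vals <- if (exact) {
      exact_moment_sample(n, mean, sd, seed = s)
    } else {
      withr::with_seed(s, rnorm(n, mean, sd))
    }
    tibble::tibble(
      subject_id = sprintf("%s%02d", substr(group, 1, 1), seq_len(n)),
      group = group, condition = condition, parameter = parameter,
      value = vals
    )
  }) |>
    purrr::list_rbind()
}
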