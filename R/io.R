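# File formats: TRC marker files (standard ASCII mocap format), CSV time
# series, a JSON trial manifest, and the TSV results table. Internally time
# is always seconds and coordinates metres, whatever the file units. Readers
# reject inconsistent metadata rather than coercing it; marker gaps are kept
# as explicit NA and never interpolated here.

#' Build a TRC document from a marker time series
#'
#' @param markers A data frame `time, x, y, z` (s, m) or a named list of such
#'   data frames (one per marker, shared time base).
#' @param data_rate Sampling rate in Hz.
#' @param units Coordinate units of the document, `"m"` or `"mm"`.
#' @return A `latstep_trc` list: `data_rate`, `camera_rate`, `units`,
#'   `marker_names`, `frames` (tibble `frame`, `time`, `<marker>_x/_y/_z`,
#'   always metres in memory).
#' @export
trc_document <- function(markers, data_rate = 100, units = "m") {
  if (is.data.frame(markers)) markers <- list(RHEE = markers)
  stopifnot(length(markers) >= 1L, !is.null(names(markers)))
  frames <- tibble::tibble(frame = seq_len(nrow(markers[[1]])),
                           time = markers[[1]]$time)
  for (nm in names(markers)) {
    m <- markers[[nm]]
    stopifnot(all(c("time", "x", "y", "z") %in% names(m)),
              nrow(m) == nrow(frames))
    frames[[paste0(nm, "_x")]] <- m$x
    frames[[paste0(nm, "_y")]] <- m$y
    frames[[paste0(nm, "_z")]] <- m$z
  }
  structure(list(data_rate = data_rate, camera_rate = data_rate,
                 units = units, marker_names = names(markers),
                 frames = frames),
            class = "latstep_trc")
}

#' Write a TRC marker file
#'
#' Standard tab-separated TRC layout: a four-line header (file type,
#' header fields, header values, marker labels) plus an axis-label line and
#' the frame rows. Coordinates are written in the document's units at 1e-6 m
#' resolution; NA samples become empty fields (gaps).
#'
#' @param doc A `latstep_trc` from [trc_document()] or [read_trc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(doc, path) {
  stopifnot(inherits(doc, "latstep_trc"))
  scale <- switch(doc$units, m = 1, mm = 1000,
                  abort(sprintf("unsupported TRC units '%s'", doc$units)))
  nf <- nrow(doc$frames)
  nm <- length(doc$marker_names)
  hdr <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(format(doc$data_rate), format(doc$camera_rate), nf, nm, doc$units,
          format(doc$data_rate), 1L, nf, sep = "\t"),
    paste(c("Frame#", "Time", as.vector(rbind(doc$marker_names, "", ""))),
          collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                           rep(seq_len(nm), each = 3))), collapse = "\t"),
    ""
  )
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v * scale))
  coord_cols <- setdiff(names(doc$frames), c("frame", "time"))
  body <- do.call(paste, c(
    list(doc$frames$frame, sprintf("%.6f", doc$frames$time)),
    lapply(doc$frames[coord_cols], fmt),
    sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a TRC marker file
#'
#' Validates the header (DataRate, NumFrames, NumMarkers, Units), converts
#' coordinates to metres (`Units` may be `m` or `mm`), represents missing
#' samples as NA, and rejects malformed files with the offending line number:
#' inconsistent column counts, a NumFrames/row-count mismatch, or
#' non-increasing frame times.
#'
#' @param path TRC file path.
#' @return A `latstep_trc`; coordinates in metres, `units` set to `"m"`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) abort("malformed TRC: fewer than 6 lines")
  if (!startsWith(lines[1], "PathFileType")) {
    abort("malformed TRC header at line 1: missing PathFileType")
  }
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% keys) || length(vals) < length(keys)) {
    abort("malformed TRC header at line 2-3: missing required fields")
  }
  hv <- setNames(vals[seq_along(keys)], keys)
  data_rate <- as.numeric(hv[["DataRate"]])
  n_frames <- as.integer(hv[["NumFrames"]])
  n_markers <- as.integer(hv[["NumMarkers"]])
  units <- hv[["Units"]]
  if (!units %in% c("m", "mm")) {
    abort(sprintf("line 3: unsupported Units '%s' (expected m or mm)", units))
  }
  scale <- if (units == "mm") 1e-3 else 1
  labels <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- labels[labels != ""][-(1:2)]
  if (length(marker_names) != n_markers) {
    abort(sprintf("line 4: %d marker labels but header NumMarkers=%d",
                  length(marker_names), n_markers))
  }
  idx <- seq_along(lines)[-(1:5)]
  keep <- trimws(lines[idx]) != ""
  body <- lines[idx][keep]
  body_ln <- idx[keep]
  if (length(body) != n_frames) {
    abort(sprintf("header NumFrames=%d but %d data rows found",
                  n_frames, length(body)),
          class = "latstep_trc_mismatch")
  }
  ncol_expect <- 2L + 3L * n_markers
  rows <- strsplit(body, "\t", fixed = TRUE)
  frames <- matrix(NA_real_, n_frames, ncol_expect)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) > ncol_expect) {
      abort(sprintf("line %d: %d columns, expected %d",
                    body_ln[i], length(r), ncol_expect))
    }
    r <- c(r, rep("", ncol_expect - length(r)))
    frames[i, ] <- suppressWarnings(as.numeric(ifelse(r == "", NA, r)))
  }
  if (anyNA(frames[, 1:2])) abort("missing frame index or time in TRC body")
  if (any(diff(frames[, 2]) <= 0)) {
    abort("frame times are not strictly increasing")
  }
  out <- tibble::tibble(frame = as.integer(frames[, 1]), time = frames[, 2])
  for (j in seq_len(n_markers)) {
    out[[paste0(marker_names[j], "_x")]] <- frames[, 3 * j] * scale
    out[[paste0(marker_names[j], "_y")]] <- frames[, 3 * j + 1] * scale
    out[[paste0(marker_names[j], "_z")]] <- frames[, 3 * j + 2] * scale
  }
  structure(list(data_rate = data_rate, camera_rate = data_rate,
                 units = "m", marker_names = marker_names, frames = out),
            class = "latstep_trc")
}

trc_marker <- function(doc, name) {
  cols <- paste0(name, c("_x", "_y", "_z"))
  if (!all(cols %in% names(doc$frames))) {
    abort(sprintf("marker '%s' not present in TRC document", name))
  }
  tibble::tibble(time = doc$frames$time,
                 x = doc$frames[[cols[1]]],
                 y = doc$frames[[cols[2]]],
                 z = doc$frames[[cols[3]]])
}

#' Write one trial to disk
#'
#' Writes the heel marker as TRC and the force, COG and moment streams as
#' CSV (one file per stream, columns `time` + channels), and returns the
#' manifest entry describing them.
#'
#' @param trial A `latstep_trial`.
#' @param dir Output directory (created if needed).
#' @return The manifest entry (a list), invisibly usable with [load_trial()].
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "latstep_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sprintf("%s_%s_t%02d", trial$subject_id, trial$condition,
                trial$trial_index)
  files <- list(markers = paste0(id, "_markers.trc"),
                force = paste0(id, "_force.csv"),
                cog = paste0(id, "_cog.csv"),
                moments = paste0(id, "_moments.csv"))
  write_trc(trc_document(list(RHEE = trial$heel),
                         data_rate = trial$design$marker_rate),
            file.path(dir, files$markers))
  readr::write_csv(trial$force, file.path(dir, files$force))
  readr::write_csv(trial$cog, file.path(dir, files$cog))
  readr::write_csv(trial$moments, file.path(dir, files$moments))
  list(subject_id = trial$subject_id, group = trial$group,
       condition = trial$condition, trial_index = trial$trial_index,
       height = trial$height, weight = trial$weight,
       marker_rate = trial$design$marker_rate,
       force_rate = trial$design$force_rate,
       files = files)
}

#' Write a cohort and its JSON manifest
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), "trial" %in% names(cohort))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort$trial, write_trial, dir = dir)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(trials = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

infer_rate <- function(t) 1 / median(diff(t))

#' Load one trial from a manifest entry
#'
#' Reads the marker TRC and the force/COG/moment CSVs referenced by a
#' manifest entry and rebuilds the trial. Missing stream files and sampling
#' rates that disagree with the manifest (beyond 0.1%) are rejected with
#' named errors. All streams stay on their native rates.
#'
#' @param entry A manifest entry (list), as produced by [write_trial()].
#' @param dir Directory the entry's file names are relative to.
#' @param design A [study_design()] supplying the expected rates.
#' @return A `latstep_trial` (with no generator `truth`).
#' @export
load_trial <- function(entry, dir, design = study_design()) {
  paths <- vapply(entry$files, function(f) file.path(dir, f), character(1))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("missing stream file(s): %s",
                  paste(names(paths)[missing], basename(paths[missing]),
                        sep = " = ", collapse = ", ")),
          class = "latstep_missing_stream")
  }
  doc <- read_trc(paths[["markers"]])
  check_rate <- function(actual, expected, what) {
    if (abs(actual / expected - 1) > 1e-3) {
      abort(sprintf("%s rate mismatch: file has %g Hz, manifest/design expects %g Hz",
                    what, actual, expected),
            class = "latstep_rate_mismatch")
    }
  }
  check_rate(doc$data_rate, entry$marker_rate, "marker")
  check_rate(entry$marker_rate, design$marker_rate, "marker (design)")
  force <- readr::read_csv(paths[["force"]], show_col_types = FALSE)
  check_rate(infer_rate(force$time), entry$force_rate, "force")
  check_rate(entry$force_rate, design$force_rate, "force (design)")
  cog <- readr::read_csv(paths[["cog"]], show_col_types = FALSE)
  moments <- readr::read_csv(paths[["moments"]], show_col_types = FALSE)
  structure(
    list(subject_id = entry$subject_id, group = entry$group,
         condition = entry$condition,
         trial_index = as.integer(entry$trial_index),
         height = entry$height, weight = entry$weight,
         heel = trc_marker(doc, doc$marker_names[1]),
         cog = cog, force = force, moments = moments,
         design = design, truth = NULL),
    class = "latstep_trial"
  )
}

#' Load a whole cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by [write_cohort()].
#' @param design A [study_design()]; the trial count per (subject, condition)
#'   must match `design$trials_per_condition`.
#' @return A cohort tibble like [generate_cohort()]'s.
#' @export
load_cohort <- function(manifest_path, design = study_design()) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  trials <- lapply(manifest$trials, load_trial, dir = dir, design = design)
  cohort <- tibble::tibble(
    subject_id = vapply(trials, `[[`, character(1), "subject_id"),
    group = vapply(trials, `[[`, character(1), "group"),
    condition = vapply(trials, `[[`, character(1), "condition"),
    trial_index = vapply(trials, `[[`, integer(1), "trial_index"),
    trial = trials
  )
  counts <- dplyr::count(cohort, .data$subject_id, .data$condition)
  bad <- counts$n != design$trials_per_condition
  if (any(bad)) {
    abort(sprintf("trial count mismatch: design expects %d trials per condition but found %s",
                  design$trials_per_condition,
                  paste(sprintf("%s/%s: %d", counts$subject_id[bad],
                                counts$condition[bad], counts$n[bad]),
                        collapse = "; ")),
          class = "latstep_trial_count")
  }
  cohort
}

#' Write the results table as TSV
#'
#' Fixed column order: parameter, condition, older mean/SD, young mean/SD,
#' CI 2.5%, CI 97.5%, Rhat, and a trailing `*` for significant cells.
#' Scalars are printed to 2 decimals; error-distance rows to 3.
#'
#' @param results A `latstep_results` tibble from [compare_cells()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  digits <- ifelse(results$parameter == "error_distance", 3L, 2L)
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), v)
  out <- tibble::tibble(
    parameter = results$parameter,
    condition = results$condition,
    older_mean = fmt(results$older_mean),
    older_sd = fmt(results$older_sd),
    young_mean = fmt(results$young_mean),
    young_sd = fmt(results$young_sd),
    ci_low = fmt(results$ci_low),
    ci_high = fmt(results$ci_high),
    rhat = sprintf("%.2f", results$rhat),
    significant = ifelse(!is.na(results$significant) & results$significant,
                         "*", "")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' JSON configuration with optional nested blocks `design`, `noise`, `mcmc`
#' plus top-level `seed`, `mode` (`"exact_scalar"` or `"full"`) and
#' `out_dir`; unknown keys are rejected. See [run_synthetic_study()].
#'
#' @param path JSON config path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("design", "noise", "mcmc", "seed", "mode", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  cfg
}
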