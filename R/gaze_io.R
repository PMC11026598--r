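# Reading and cleaning gaze tables: binocular merge, image-boundary sample
# exclusion, and the >10%-missing image-level QC rule.

gaze_csv_columns <- function() {
  c("participant_id", "scene_id", "t_s", "lx_px", "ly_px", "rx_px", "ry_px",
    "pupil_mm", "valid")
}

#' Read gaze recordings from CSV
#'
#' Expects columns `participant_id, scene_id, t_s, lx_px, ly_px, rx_px,
#' ry_px, pupil_mm, valid` and returns one `gaze_recording` per (participant,
#' scene) block. Timestamps must be strictly increasing within each
#' recording; violations are reported with the offending file row.
#'
#' @param path CSV file path.
#' @param rate_hz nominal sampling rate stored on each recording.
#' @return Named list of `gaze_recording` data frames
#'   (`<participant>_<scene>`).
#' @export
read_gaze_table <- function(path, rate_hz = 60) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(gaze_csv_columns(), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df$.row <- seq_len(nrow(df)) + 1L  # file line (after header)
  key <- paste(df$participant_id, df$scene_id, sep = "_")
  out <- list()
  for (k in unique(key)) {
    d <- df[key == k, ]
    bad <- which(diff(d$t_s) <= 0)
    if (length(bad))
      stop("non-monotone t_s in ", path, " at row ", d$.row[bad[1] + 1L],
           " (recording ", k, ")")
    rec <- d[, setdiff(gaze_csv_columns(), c("participant_id", "scene_id"))]
    rownames(rec) <- NULL
    duration <- nrow(rec) / rate_hz
    out[[k]] <- structure(rec, class = c("gaze_recording", "data.frame"),
                          participant_id = d$participant_id[1],
                          scene_id = d$scene_id[1], rate_hz = rate_hz,
                          duration_s = duration)
  }
  out
}

#' Merge binocular samples into a cyclopean point series
#'
#' Per valid sample, `x = (lx + rx) / 2`, `y = (ly + ry) / 2`; invalid
#' samples are dropped. No smoothing and no fixation parsing (raw-form
#' analysis). Set `eye` to use a single eye instead of the average.
#'
#' @param recording a `gaze_recording`.
#' @param eye `"cyclopean"` (default), `"left"` or `"right"`.
#' @return Data frame `t_s, x_px, y_px, pupil_mm` of the valid samples.
#' @export
cyclopean_merge <- function(recording, eye = c("cyclopean", "left", "right")) {
  eye <- match.arg(eye)
  d <- recording[recording$valid == 1 & !is.na(recording$lx_px), ]
  if (nrow(d) == 0)
    return(data.frame(t_s = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), pupil_mm = numeric(0)))
  x <- switch(eye, cyclopean = (d$lx_px + d$rx_px) / 2,
              left = d$lx_px, right = d$rx_px)
  y <- switch(eye, cyclopean = (d$ly_px + d$ry_px) / 2,
              left = d$ly_px, right = d$ry_px)
  data.frame(t_s = d$t_s, x_px = x, y_px = y, pupil_mm = d$pupil_mm)
}

#' Remove out-of-image samples and compute the retained fraction
#'
#' Keeps points with `0 <= x < width` and `0 <= y < height` (0-based pixel
#' coordinates, origin top-left). The retained fraction is computed against
#' the expected sample count `duration x rate`, so tracker dropouts and
#' boundary exclusions both count as missing.
#'
#' @param points cyclopean point series (from [cyclopean_merge()]).
#' @param geometry a [screen_geometry()].
#' @param expected_n expected number of samples for the trial.
#' @return A `clean_gaze` list: `points`, `retained_fraction`, `excluded`
#'   (`NA` until [qc_exclude_image()] is applied).
#' @export
clean_samples <- function(points, geometry, expected_n) {
  stopifnot(inherits(geometry, "screen_geometry"), expected_n >= 1)
  keep <- points$x_px >= 0 & points$x_px < geometry$width_px &
    points$y_px >= 0 & points$y_px < geometry$height_px
  pts <- points[keep, , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts,
                 retained_fraction = nrow(pts) / expected_n,
                 excluded = NA),
            class = "clean_gaze")
}

#' Image-level QC: exclude trials missing more than 10% of samples
#'
#' A trial is excluded when the missing fraction strictly exceeds the
#' threshold ("more than 10%" read as a strict inequality), so exactly 10%
#' missing is retained.
#'
#' @param clean a `clean_gaze` from [clean_samples()].
#' @param threshold maximum tolerated missing fraction, in \[0, 1\].
#' @return Logical: `TRUE` if the trial is excluded.
#' @export
qc_exclude_image <- function(clean, threshold = 0.10) {
  stopifnot(inherits(clean, "clean_gaze"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  (1 - clean$retained_fraction) > threshold
}

#' Clean and QC one recording end-to-end
#'
#' [cyclopean_merge()] + [clean_samples()] + [qc_exclude_image()] with the
#' expected sample count taken from the recording's nominal duration and
#' rate.
#'
#' @param recording a `gaze_recording`.
#' @param geometry a [screen_geometry()].
#' @param threshold QC missingness threshold.
#' @param eye passed to [cyclopean_merge()].
#' @return A `clean_gaze` with `excluded` set.
#' @export
process_recording <- function(recording, geometry, threshold = 0.10,
                              eye = "cyclopean") {
  expected <- floor(attr(recording, "duration_s") * attr(recording, "rate_hz"))
  cg <- clean_samples(cyclopean_merge(recording, eye), geometry, expected)
  cg$excluded <- qc_exclude_image(cg, threshold)
  cg
}

#' Clean a whole cohort and build per-trial density maps
#'
#' Applies [process_recording()] to every participant x scene and builds a
#' [density_map()] for every retained trial ( `NULL` where QC excluded the
#' trial or no samples survived cleaning).
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param sigma_px density-map smoothing sigma; the default scales the
#'   55-px fovea kernel of the 1600-px reference display to the cohort's
#'   geometry (about 1 degree).
#' @param threshold QC missingness threshold.
#' @return List with `maps` and `clean` (both `[[participant]][[scene]]`),
#'   `groups` (named vector), and `exclusions` (per-participant counts).
#' @export
cohort_density_maps <- function(cohort, sigma_px = NULL, threshold = 0.10) {
  geom <- cohort$spec$geometry
  if (is.null(sigma_px)) sigma_px <- px_per_degree(geom)  # ~1 deg fovea
  maps <- list(); clean <- list()
  excl <- setNames(integer(nrow(cohort$participants)),
                   cohort$participants$participant_id)
  for (pid in names(cohort$recordings)) {
    maps[[pid]] <- list(); clean[[pid]] <- list()
    for (sid in names(cohort$recordings[[pid]])) {
      cg <- process_recording(cohort$recordings[[pid]][[sid]], geom, threshold)
      clean[[pid]][[sid]] <- cg
      if (cg$excluded || nrow(cg$points) == 0) {
        maps[[pid]][sid] <- list(NULL)
        excl[pid] <- excl[pid] + 1L
      } else {
        maps[[pid]][[sid]] <- density_map(cg$points, geom, sigma_px)
      }
    }
  }
  groups <- setNames(cohort$participants$group,
                     cohort$participants$participant_id)
  list(maps = maps, clean = clean, groups = groups, exclusions = excl)
}
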