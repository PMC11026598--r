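# Group-conditioned synthetic gaze: a three-component attractor mixture
# (image center / objects / background) with per-fixation log-normal dwell
# times, per-sample jitter, Poisson blink dropouts, slow pupil drift and
# binocular output (cyclopean point +/- fixed horizontal disparity).

#' Viewer profile for the synthetic gaze generator
#'
#' Each fixation target is drawn from a three-component mixture: with
#' probability `w_center` a truncated Gaussian around the image center (sigma
#' 1 degree), with `w_object` an object centroid (chosen proportionally to
#' `baseline + affinity x attributes`) plus 2-degree Gaussian jitter truncated
#' to the object's mask (an object-seeking fixation lands on the object), and
#' with `w_background` a uniform point over the non-object region (whole image
#' when the scene has no objects). `exploration` divides the log-normal fixation
#' durations, so larger values yield more distinct fixations per trial and
#' more dispersed gaze maps.
#'
#' @param group_label free-text label ("CU", "AD", "LBD", or custom).
#' @param w_center,w_object,w_background nonnegative mixture weights summing
#'   to 1.
#' @param attribute_affinity named nonnegative multipliers over `baseline`
#'   plus the 4 properties and 12 semantic attributes, controlling which
#'   objects attract gaze.
#' @param exploration positive scalar; scales the number of distinct fixations.
#' @param fixation_duration_mean_s,fixation_duration_sd_s log-normal dwell
#'   time parameters (seconds) at `exploration = 1`.
#' @param jitter_sd_deg per-sample oculomotor jitter (degrees).
#' @param blink_rate_hz Poisson rate of blink events; each blink invalidates a
#'   100-300 ms run of samples.
#' @param pupil_mean_mm,pupil_drift_mm pupil diameter baseline and linear
#'   drift over the trial (millimetres).
#' @return A `viewer_profile` list.
#' @export
viewer_profile <- function(group_label = "custom",
                           w_center = 0.2, w_object = 0.6, w_background = 0.2,
                           attribute_affinity = default_affinity(),
                           exploration = 1,
                           fixation_duration_mean_s = 0.25,
                           fixation_duration_sd_s = 0.10,
                           jitter_sd_deg = 0.15,
                           blink_rate_hz = 0.2,
                           pupil_mean_mm = 3.5,
                           pupil_drift_mm = 0) {
  w <- c(w_center, w_object, w_background)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must be nonnegative and sum to 1")
  if (exploration <= 0) stop("exploration must be positive")
  if (fixation_duration_mean_s <= 0 || fixation_duration_sd_s <= 0)
    stop("fixation durations must be positive")
  aff <- default_affinity()
  aff[names(attribute_affinity)] <- attribute_affinity
  if (any(aff < 0)) stop("attribute affinities must be nonnegative")
  structure(list(group_label = group_label, w_center = w_center,
                 w_object = w_object, w_background = w_background,
                 attribute_affinity = aff, exploration = exploration,
                 fixation_duration_mean_s = fixation_duration_mean_s,
                 fixation_duration_sd_s = fixation_duration_sd_s,
                 jitter_sd_deg = jitter_sd_deg, blink_rate_hz = blink_rate_hz,
                 pupil_mean_mm = pupil_mean_mm,
                 pupil_drift_mm = pupil_drift_mm),
            class = "viewer_profile")
}

#' Default attribute affinities of the object attractor
#'
#' Socially and semantically salient attributes (faces, text, watchable
#' objects) pull gaze more strongly than plain objects.
#' @return Named nonnegative vector over `baseline` + 16 attributes.
#' @export
default_affinity <- function() {
  aff <- setNames(rep(1, 17), c("baseline", property_names(), semantic_names()))
  aff[property_names()] <- 0
  aff[c("face", "text", "watchability")] <- 2
  aff
}

#' Default group presets for the synthetic cohort
#'
#' Chosen to qualitatively reproduce the clinical ordering: CU-like viewers
#' are object-driven with high exploration; AD-like intermediate; LBD-like
#' center-biased with low exploration, slower gaze and mildly reduced pupil
#' size. Fully overridable.
#'
#' @return Named list of [viewer_profile()]s for `CU`, `AD`, `LBD`.
#' @export
default_profiles <- function() {
  list(
    CU = viewer_profile("CU", w_center = 0.15, w_object = 0.75,
                        w_background = 0.10, exploration = 1.5,
                        pupil_mean_mm = 3.6),
    AD = viewer_profile("AD", w_center = 0.25, w_object = 0.65,
                        w_background = 0.10, exploration = 1.0,
                        pupil_mean_mm = 3.5),
    LBD = viewer_profile("LBD", w_center = 0.40, w_object = 0.50,
                         w_background = 0.10, exploration = 0.6,
                         pupil_mean_mm = 3.3))
}

# truncated Gaussian draw around a point, clamped into the image
trunc_gauss_xy <- function(cx, cy, sigma_px, W, H, max_sd = 3) {
  for (i in 1:50) {
    dx <- rnorm(1, 0, sigma_px); dy <- rnorm(1, 0, sigma_px)
    if (dx^2 + dy^2 <= (max_sd * sigma_px)^2) break
  }
  c(x = min(W - 1e-6, max(0, cx + dx)), y = min(H - 1e-6, max(0, cy + dy)))
}

object_attractor_weights <- function(scene, affinity) {
  vapply(scene$objects, function(ob) {
    vals <- c(unlist(ob$properties), as.numeric(ob$semantics))
    names(vals) <- c(property_names(), semantic_names())
    max(1e-6, affinity[["baseline"]] + sum(affinity[names(vals)] * vals))
  }, numeric(1))
}

#' Simulate one free-viewing gaze recording
#'
#' Emits `floor(duration_s * rate_hz)` sample slots. Fixation targets follow
#' the viewer's attractor mixture; samples add Gaussian jitter around the
#' active fixation; blink events invalidate 100-300 ms runs (coordinates NA,
#' `valid = 0`, mirroring a tracker that records nothing when either eye is
#' lost); the pupil series is baseline + linear drift + noise. Left/right eye
#' coordinates are the cyclopean point +/- 0.2 degree horizontal disparity,
#' with jointly dropped validity.
#'
#' @param scene an `annotated_scene`.
#' @param viewer a [viewer_profile()].
#' @param geometry a [screen_geometry()] whose pixel dims match the scene.
#' @param duration_s,rate_hz trial duration (s) and sampling rate (Hz).
#' @param seed integer seed.
#' @param participant_id,scene_id identifiers stored on the recording.
#' @return A `gaze_recording` data frame (`t_s, lx_px, ly_px, rx_px, ry_px,
#'   pupil_mm, valid`) with attributes `rate_hz`, `duration_s` and
#'   `fixations` (the generating fixation log, used for generator-contract
#'   checks).
#' @export
simulate_gaze <- function(scene, viewer, geometry, duration_s = 3,
                          rate_hz = 60, seed = 1L,
                          participant_id = NA_character_,
                          scene_id = scene$scene_id) {
  stopifnot(inherits(scene, "annotated_scene"),
            inherits(viewer, "viewer_profile"),
            inherits(geometry, "screen_geometry"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  W <- scene$width; H <- scene$height
  ppd <- px_per_degree(geometry)
  with_seed(as.integer(seed), {
    # fixation timeline: log-normal dwell times shortened by exploration
    m <- viewer$fixation_duration_mean_s / viewer$exploration
    s <- viewer$fixation_duration_sd_s / viewer$exploration
    sdlog <- sqrt(log(1 + s^2 / m^2))
    meanlog <- log(m) - sdlog^2 / 2
    t0 <- 0; fix <- list()
    bg_idx <- which(!object_union_mask(scene))
    if (length(bg_idx) == 0) bg_idx <- seq_len(W * H)
    obj_w <- if (length(scene$objects))
      object_attractor_weights(scene, viewer$attribute_affinity) else numeric(0)
    while (t0 < duration_s) {
      dur <- rlnorm(1, meanlog, sdlog)
      type <- sample(c("center", "object", "background"), 1,
                     prob = c(viewer$w_center, viewer$w_object,
                              viewer$w_background))
      if (type == "object" && length(obj_w) == 0) type <- "background"
      xy <- switch(type,
        center = trunc_gauss_xy((W - 1) / 2, (H - 1) / 2, 1 * ppd, W, H),
        object = {
          k <- sample.int(length(obj_w), 1, prob = obj_w)
          ob <- scene$objects[[k]]
          ct <- ob$centroid_xy_px
          # centroid + 2 deg Gaussian jitter, truncated to the object mask:
          # an object-seeking fixation lands on the object itself
          xy <- NULL
          for (i in 1:20) {
            cand <- trunc_gauss_xy(ct[["x"]], ct[["y"]], 2 * ppd, W, H)
            if (ob$mask[floor(cand[["y"]]) + 1L, floor(cand[["x"]]) + 1L]) {
              xy <- cand; break
            }
          }
          if (is.null(xy)) {
            px <- which(ob$mask)
            px <- px[sample.int(length(px), 1)]
            xy <- c(x = min(W - 1e-6, max(0, ((px - 1) %/% H) + runif(1) - 0.5)),
                    y = min(H - 1e-6, max(0, ((px - 1) %% H) + runif(1) - 0.5)))
          }
          xy
        },
        background = {
          px <- bg_idx[sample.int(length(bg_idx), 1)]
          c(x = ((px - 1) %/% H) + runif(1) - 0.5,
            y = ((px - 1) %% H) + runif(1) - 0.5)
        })
      fix[[length(fix) + 1L]] <- data.frame(
        type = type, x = xy[["x"]], y = xy[["y"]],
        t_start = t0, t_end = min(duration_s, t0 + dur))
      t0 <- t0 + dur
    }
    fix <- do.call(rbind, fix)
    n <- floor(duration_s * rate_hz)
    t_s <- (seq_len(n) - 1) / rate_hz
    fi <- findInterval(t_s, fix$t_start)
    jit <- viewer$jitter_sd_deg * ppd
    x <- pmin(W - 1e-6, pmax(0, fix$x[fi] + rnorm(n, 0, jit)))
    y <- pmin(H - 1e-6, pmax(0, fix$y[fi] + rnorm(n, 0, jit)))
    valid <- rep(1L, n)
    for (b in seq_len(rpois(1, viewer$blink_rate_hz * duration_s))) {
      bs <- runif(1, 0, duration_s); bl <- runif(1, 0.1, 0.3)
      valid[t_s >= bs & t_s < bs + bl] <- 0L
    }
    pupil <- viewer$pupil_mean_mm +
      viewer$pupil_drift_mm * t_s / duration_s + rnorm(n, 0, 0.05)
    disp <- 0.2 * ppd
    rec <- data.frame(t_s = t_s,
                      lx_px = x - disp, ly_px = y,
                      rx_px = x + disp, ry_px = y,
                      pupil_mm = pupil, valid = valid)
    rec[rec$valid == 0L, c("lx_px", "ly_px", "rx_px", "ry_px")] <- NA_real_
    structure(rec, class = c("gaze_recording", "data.frame"),
              participant_id = participant_id, scene_id = scene_id,
              rate_hz = rate_hz, duration_s = duration_s, fixations = fix)
  })
}
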