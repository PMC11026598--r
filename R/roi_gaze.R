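# ROI-level gaze statistics on the 15 scene ROIs (12 semantic-attribute
# unions, semantic objects, other objects, background) and assembly of the
# 65-dimensional participant feature vector.

#' Names of the 15 scene ROIs
#' @return Character vector: the 12 semantic attributes plus
#'   `semantic_objects`, `other_objects`, `background`.
#' @export
roi_names <- function() {
  c(semantic_names(), "semantic_objects", "other_objects", "background")
}

#' Build the 15 ROI masks of a scene
#'
#' Attribute masks are unions of the masks of objects carrying that flag (and
#' may overlap each other); `semantic_objects` is the union of objects with
#' at least one semantic flag, `other_objects` the union of objects with
#' none, and `background` the complement of all objects. The last three
#' partition the image.
#'
#' @param scene an `annotated_scene`.
#' @return Named list of 15 logical H x W masks (`roi_set`).
#' @export
roi_masks <- function(scene) {
  H <- scene$height; W <- scene$width
  empty <- matrix(FALSE, H, W)
  out <- setNames(rep(list(empty), 15), roi_names())
  for (ob in scene$objects) {
    has_sem <- sum(ob$semantics) > 0
    key <- if (has_sem) "semantic_objects" else "other_objects"
    out[[key]] <- out[[key]] | ob$mask
    for (a in semantic_names())
      if (ob$semantics[[a]] == 1) out[[a]] <- out[[a]] | ob$mask
  }
  out[["background"]] <- !(out[["semantic_objects"]] | out[["other_objects"]])
  structure(out, class = "roi_set")
}

#' Fraction of gaze samples on each ROI
#'
#' The proportion of valid gaze samples whose pixel falls inside each ROI
#' mask. The `semantic_objects + other_objects + background` proportions sum
#' to 1 by the partition property.
#'
#' @param points cleaned cyclopean points (`x_px`, `y_px`, 0-based, in
#'   image).
#' @param rois a [roi_masks()] result.
#' @param method `"samples"` (fraction of raw samples in the mask, default)
#'   or `"density"` (mass of a smoothed density map over the mask;
#'   equivalent up to smoothing).
#' @param map a [density_map()], required for `method = "density"`.
#' @return Named numeric vector of 15 proportions.
#' @export
roi_gaze_proportions <- function(points, rois,
                                 method = c("samples", "density"),
                                 map = NULL) {
  method <- match.arg(method)
  if (method == "density") {
    if (is.null(map)) stop("method = 'density' requires a density map")
    return(vapply(rois, function(m) sum(map[m]), numeric(1)))
  }
  if (is.null(points) || nrow(points) == 0)
    stop("no valid gaze points; scene must be skipped")
  ij <- cbind(floor(points$y_px) + 1L, floor(points$x_px) + 1L)
  vapply(rois, function(m) mean(m[ij]), numeric(1))
}

# split sample indices into temporal runs, breaking on dropped samples
time_runs <- function(t_s, rate_hz) {
  if (length(t_s) == 0) return(integer(0))
  cumsum(c(1L, as.integer(diff(t_s) > 1.5 / rate_hz)))
}

#' Mean gaze-visit duration on each ROI
#'
#' A visit is a maximal run of consecutive samples inside the ROI; runs are
#' also broken by gaps in the sample clock (dropped/invalid samples), so a
#' blink splits a visit in two. Duration = run length / rate. ROIs never
#' visited report 0 with a `visited` attribute flag (they are excluded from
#' participant-level duration averages).
#'
#' @param points cleaned cyclopean points with `t_s`.
#' @param rois a [roi_masks()] result.
#' @param rate_hz sampling rate.
#' @return Named vector of 15 mean visit durations (s), with a logical
#'   `visited` attribute.
#' @export
roi_visit_durations <- function(points, rois, rate_hz = 60) {
  if (is.null(points) || nrow(points) == 0)
    stop("no valid gaze points; scene must be skipped")
  ij <- cbind(floor(points$y_px) + 1L, floor(points$x_px) + 1L)
  seg <- time_runs(points$t_s, rate_hz)
  out <- setNames(numeric(15), roi_names())
  visited <- setNames(logical(15), roi_names())
  for (rn in roi_names()) {
    inroi <- rois[[rn]][ij]
    if (!any(inroi)) next
    r <- rle(paste0(seg, "_", inroi))
    lens <- r$lengths[grepl("_TRUE$", r$values)]
    out[rn] <- mean(lens) / rate_hz
    visited[rn] <- TRUE
  }
  attr(out, "visited") <- visited
  out
}

#' Canonical names of the 65 eye-movement features
#' @return Character vector of length 65.
#' @export
eye_feature_names <- function() {
  c("w_center", "w_background", "w_low_level", "w_high_level",
    "entropy_mean",
    paste0("prop_", roi_names(), "_mean"), paste0("prop_", roi_names(), "_sd"),
    paste0("dur_", roi_names(), "_mean"), paste0("dur_", roi_names(), "_sd"))
}

#' Assemble one participant's 65-dimensional eye-movement feature vector
#'
#' 4 attention-model type weights + mean map entropy + per-ROI gaze
#' proportion mean and sd across scenes (15 x 2) + per-ROI mean visit
#' duration mean and sd across scenes (15 x 2). Standard deviations use the
#' n-1 denominator. Scenes where an ROI was never visited are excluded from
#' that ROI's duration mean/sd (a 0-duration visit is meaningless); ROIs
#' visited in fewer than 2 scenes are imputed as 0 so the vector is NaN-free.
#'
#' @param type_weights named 4-vector (center, background, low_level,
#'   high_level).
#' @param entropies per-scene map entropies (usable scenes only).
#' @param proportions scenes x 15 matrix of [roi_gaze_proportions()] values.
#' @param durations scenes x 15 matrix of [roi_visit_durations()] values.
#' @param visited scenes x 15 logical matrix (the `visited` attributes).
#' @return Named numeric vector of length 65.
#' @export
participant_feature_vector <- function(type_weights, entropies, proportions,
                                       durations, visited) {
  stopifnot(length(type_weights) == 4, ncol(proportions) == 15,
            ncol(durations) == 15, all(dim(durations) == dim(visited)))
  if (nrow(proportions) < 2)
    stop("fewer than 2 usable scenes: sd undefined, participant excluded")
  dur_stat <- function(fun) vapply(seq_len(15), function(j) {
    v <- durations[visited[, j], j]
    if (length(v) < 2) 0 else fun(v)
  }, numeric(1))
  out <- c(unname(type_weights)[1:4], mean(entropies),
           colMeans(proportions), apply(proportions, 2, sd),
           dur_stat(mean), dur_stat(sd))
  names(out) <- eye_feature_names()
  stopifnot(length(out) == 65, !anyNA(out))
  out
}

#' Eye-movement feature table for a whole cohort
#'
#' Runs the full per-participant pipeline: QC + density maps, per-scene
#' entropy, participant-level attention weights, per-scene ROI proportions
#' and visit durations, assembled into the 65-feature vector per participant
#' and joined with the clinical covariates.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dm optional precomputed [cohort_density_maps()] result.
#' @param stacks optional precomputed feature stacks by scene id.
#' @param n_per_class,C,seed attention-model settings.
#' @param min_scenes minimum usable scenes per participant.
#' @return Data frame: participant metadata + 65 feature columns; excluded
#'   participants are dropped with a warning.
#' @export
cohort_features <- function(cohort, dm = NULL, stacks = NULL,
                            n_per_class = 10, C = 1, seed = 1L,
                            min_scenes = 2) {
  geom <- cohort$spec$geometry
  if (is.null(dm)) dm <- cohort_density_maps(cohort)
  if (is.null(stacks))
    stacks <- lapply(cohort$scenes, build_feature_stack, geometry = geom)
  att <- suppressWarnings(
    group_attention_analysis(dm$maps, dm$groups, stacks,
                             level = "participant", n_per_class = n_per_class,
                             min_scenes = min_scenes, C = C, seed = seed))
  rois <- lapply(cohort$scenes, roi_masks)
  rate <- cohort$spec$rate_hz
  rows <- list()
  for (pid in names(cohort$recordings)) {
    if (is.null(att[[pid]])) next
    ent <- c(); props <- list(); durs <- list(); vis <- list()
    for (sid in names(cohort$recordings[[pid]])) {
      m <- dm$maps[[pid]][[sid]]
      if (is.null(m)) next
      pts <- dm$clean[[pid]][[sid]]$points
      ent <- c(ent, map_entropy(m))
      props[[sid]] <- roi_gaze_proportions(pts, rois[[sid]])
      dv <- roi_visit_durations(pts, rois[[sid]], rate)
      durs[[sid]] <- as.numeric(dv)
      vis[[sid]] <- attr(dv, "visited")
    }
    if (length(ent) < 2) { warning("participant ", pid, " excluded"); next }
    fv <- participant_feature_vector(att[[pid]]$types, ent,
                                     do.call(rbind, props),
                                     do.call(rbind, durs),
                                     do.call(rbind, vis))
    rows[[pid]] <- c(list(participant_id = pid), as.list(fv))
  }
  feats <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(feats) <- NULL
  merge(cohort$participants, feats, by = "participant_id", sort = FALSE)
}
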