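# Cohort assembly: scenes + group-conditioned gaze recordings + participant
# metadata (synthetic MMSE/CDR-SB/gait/brain-ROI values), in memory or
# written to disk (PNG + JSON + CSV + manifest).

#' Names of the 10 synthetic brain ROI measures
#' @return Character vector (volume/thickness summaries consumed as a table).
#' @export
brain_roi_names <- function() {
  c("hippocampus", "entorhinal", "amygdala", "precuneus",
    "posterior_cingulate", "superior_frontal", "superior_parietal",
    "inferior_temporal", "fusiform", "lateral_occipital")
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group named integer vector (participants per group); names
#'   must match `profiles`.
#' @param n_images number of scenes, viewed by every participant.
#' @param profiles named list of [viewer_profile()]s (default
#'   [default_profiles()]).
#' @param geometry a [screen_geometry()]; scenes are generated at its pixel
#'   dimensions.
#' @param duration_s,rate_hz per-trial viewing duration and sampling rate.
#' @param seed master seed; all scene/recording/metadata seeds derive from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(CU = 5, AD = 5, LBD = 5),
                        n_images = 10, profiles = default_profiles(),
                        geometry = screen_geometry(), duration_s = 3,
                        rate_hz = 60, seed = 1L) {
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  if (n_images < 1) stop("n_images must be >= 1")
  if (!all(names(n_per_group) %in% names(profiles)))
    stop("every group needs a viewer profile")
  structure(list(n_per_group = n_per_group, n_images = as.integer(n_images),
                 profiles = profiles, geometry = geometry,
                 duration_s = duration_s, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# group-conditioned clinical metadata; distributions documented in the
# methods vignette (plausible desk values, not estimates)
sample_metadata <- function(group, n) {
  pars <- switch(group,
    CU = list(mmse = c(28.8, 1.0), cdr = c(0, 0.2), gait = c(1.20, 0.15),
              anti = 0, stage = NA),
    AD = list(mmse = c(22.5, 3.0), cdr = c(4.5, 2.0), gait = c(1.05, 0.15),
              anti = 0.05, stage = 0.6),
    LBD = list(mmse = c(23.5, 3.0), cdr = c(5.0, 2.5), gait = c(0.85, 0.20),
               anti = 0.35, stage = 0.65),
    list(mmse = c(27, 2), cdr = c(1, 1), gait = c(1.1, 0.2), anti = 0.1,
         stage = 0.5))
  df <- data.frame(
    age = round(rnorm(n, 75, 6)),
    sex = rbinom(n, 1, 0.5),
    education = round(pmax(6, rnorm(n, 12, 3))),
    MMSE = round(pmin(30, pmax(0, rnorm(n, pars$mmse[1], pars$mmse[2])))),
    CDR_SB = round(pmin(18, pmax(0, rnorm(n, pars$cdr[1], pars$cdr[2]))) * 2) / 2,
    gait_speed = round(pmax(0.2, rnorm(n, pars$gait[1], pars$gait[2])), 2),
    antipsychotic = rbinom(n, 1, pars$anti),
    stage = if (is.na(pars$stage)) NA_character_ else
      ifelse(rbinom(n, 1, pars$stage) == 1, "MCI", "dementia"))
  # brain ROIs: z-scored regional measures, mildly reduced in patient groups
  shift <- switch(group, CU = 0, AD = -0.8, LBD = -0.5, 0)
  rois <- matrix(rnorm(n * 10, shift, 1), n, 10,
                 dimnames = list(NULL, brain_roi_names()))
  cbind(df, as.data.frame(round(rois, 3)))
}

#' Simulate a cohort in memory
#'
#' Generates `n_images` annotated scenes (object counts drawn Poisson(7)),
#' one gaze recording per participant x scene under the group's viewer
#' profile, and group-conditioned participant metadata. Deterministic given
#' the spec (all sub-seeds derive from the master seed).
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort` list: `scenes` (named list), `participants` (data
#'   frame), `recordings` (`recordings[[participant_id]][[scene_id]]`),
#'   `spec`, `seeds`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  geom <- spec$geometry
  with_seed(spec$seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_images)
    meta_seed <- sample.int(.Machine$integer.max - 1L, 1)
    gaze_seed_base <- sample.int(.Machine$integer.max - 1L, 1)
  })
  scene_ids <- sprintf("scene_%03d", seq_len(spec$n_images))
  scenes <- setNames(lapply(seq_len(spec$n_images), function(i) {
    cfg <- scene_config(width_px = geom$width_px, height_px = geom$height_px,
                        n_objects = NA, seed = scene_seeds[i])
    generate_scene(cfg, scene_id = scene_ids[i])
  }), scene_ids)
  groups <- names(spec$n_per_group)
  participants <- do.call(rbind, lapply(groups, function(g) {
    n <- spec$n_per_group[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n))
    meta <- with_seed(meta_seed + match(g, groups),
                      sample_metadata(g, n))
    cbind(data.frame(participant_id = ids, group = g,
                     stringsAsFactors = FALSE), meta)
  }))
  rownames(participants) <- NULL
  recordings <- list()
  k <- 0L
  for (pi in seq_len(nrow(participants))) {
    pid <- participants$participant_id[pi]
    prof <- spec$profiles[[participants$group[pi]]]
    recordings[[pid]] <- setNames(lapply(seq_along(scenes), function(si) {
      simulate_gaze(scenes[[si]], prof, geom, duration_s = spec$duration_s,
                    rate_hz = spec$rate_hz,
                    seed = (gaze_seed_base + 7919L * pi + si) %%
                      (.Machine$integer.max - 1L),
                    participant_id = pid, scene_id = scene_ids[si])
    }), scene_ids)
  }
  structure(list(scenes = scenes, participants = participants,
                 recordings = recordings, spec = spec,
                 seeds = list(master = spec$seed, scenes = scene_seeds,
                              metadata = meta_seed, gaze = gaze_seed_base)),
            class = "cohort")
}

scene_to_json <- function(scene) {
  objs <- lapply(scene$objects, function(ob) {
    list(object_id = ob$object_id,
         mask_rle = mask_to_rle(ob$mask),
         centroid_xy_px = unname(ob$centroid_xy_px),
         properties = ob$properties,
         semantics = as.list(ob$semantics))
  })
  list(scene_id = scene$scene_id, width = scene$width, height = scene$height,
       objects = objs)
}

#' Read a scene annotation JSON written by [generate_cohort()]
#' @param path JSON file path.
#' @return An `annotated_scene` (without the pixel image).
#' @export
read_scene_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  objects <- lapply(j$objects, function(ob) {
    rle_obj <- list(starts = unlist(ob$mask_rle$starts),
                    lengths = unlist(ob$mask_rle$lengths))
    list(object_id = ob$object_id,
         mask = rle_to_mask(rle_obj, j$height, j$width),
         centroid_xy_px = c(x = ob$centroid_xy_px[[1]],
                            y = ob$centroid_xy_px[[2]]),
         properties = lapply(ob$properties, as.numeric),
         semantics = unlist(ob$semantics))
  })
  structure(list(scene_id = j$scene_id, width = j$width, height = j$height,
                 image = NULL, objects = objects,
                 n_objects = length(objects)),
            class = "annotated_scene")
}

recording_to_table <- function(rec) {
  data.frame(participant_id = attr(rec, "participant_id"),
             scene_id = attr(rec, "scene_id"),
             rec, check.names = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Writes `scenes/<id>.png` + `scenes/<id>.json`, one gaze CSV per
#' participant x scene under `gaze/`, `participants.csv`, and a
#' `manifest.json` recording the spec and every derived seed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the in-memory cohort with a `paths` attribute.
#' @export
generate_cohort <- function(spec, out_dir) {
  cohort <- simulate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir)
  sc_dir <- file.path(out_dir, "scenes"); gz_dir <- file.path(out_dir, "gaze")
  dir.create(sc_dir, showWarnings = FALSE); dir.create(gz_dir, showWarnings = FALSE)
  for (sc in cohort$scenes) {
    png::writePNG(sc$image, file.path(sc_dir, paste0(sc$scene_id, ".png")))
    jsonlite::write_json(scene_to_json(sc),
                         file.path(sc_dir, paste0(sc$scene_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (pid in names(cohort$recordings))
    for (sid in names(cohort$recordings[[pid]]))
      write.csv(recording_to_table(cohort$recordings[[pid]][[sid]]),
                file.path(gz_dir, sprintf("%s_%s.csv", pid, sid)),
                row.names = FALSE)
  write.csv(cohort$participants, file.path(out_dir, "participants.csv"),
            row.names = FALSE)
  manifest <- list(seed = spec$seed, n_per_group = as.list(spec$n_per_group),
                   n_images = spec$n_images, duration_s = spec$duration_s,
                   rate_hz = spec$rate_hz,
                   geometry = unclass(spec$geometry), seeds = cohort$seeds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(cohort, "paths") <- list(root = out_dir, scenes = sc_dir, gaze = gz_dir)
  invisible(cohort)
}
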