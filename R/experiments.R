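# Packaged simulation experiments: attention-weight recovery under dominant
# attractor profiles, type-contribution orderings under the clinical presets,
# the entropy-vs-exploration grid, and a feature-level cohort simulator for
# classifier validation. These drive the validation suite and the analysis
# scripts.

#' Dominant-attractor viewer profiles for the recovery experiment
#'
#' Three viewers, each dominated by one attractor of the fixation mixture:
#' center (0.9/0.05/0.05), object (0/0.95/0.05) and background
#' (0/0.05/0.95), all at exploration 2 so each trial yields many fixations.
#' The non-center scenarios carry no center component at all: the image
#' center is a single narrow landmark, and mixing even a few center
#' fixations into another profile leaves a center signature that is not part
#' of the attractor under test.
#'
#' @return Named list of three [viewer_profile()]s.
#' @export
dominant_profiles <- function() {
  list(center = viewer_profile("center", 0.9, 0.05, 0.05, exploration = 2),
       object = viewer_profile("object", 0, 0.95, 0.05, exploration = 2),
       background = viewer_profile("background", 0, 0.05, 0.95,
                                   exploration = 2))
}

# simulate one group of viewers on shared scenes and return density maps
simulate_group_maps <- function(scenes, profile, geometry, n_participants,
                                seed, duration_s = 3, rate_hz = 60) {
  maps <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    maps[[pid]] <- list()
    for (si in seq_along(scenes)) {
      sid <- names(scenes)[si]
      rec <- simulate_gaze(scenes[[sid]], profile, geometry,
                           duration_s = duration_s, rate_hz = rate_hz,
                           seed = str_seed("sim", pid, sid, base = seed),
                           participant_id = pid)
      cg <- process_recording(rec, geometry)
      maps[[pid]][[sid]] <- if (cg$excluded || nrow(cg$points) == 0) NULL else
        density_map(cg$points, geometry, px_per_degree(geometry))
    }
  }
  maps
}

#' Attention-weight recovery experiment
#'
#' For each replicate and each dominant-attractor scenario, simulates a group
#' of viewers on the shared scenes, fits the group-level attention model and
#' records whether the largest type contribution matches the generating
#' attractor (center scenario -> `center`, object -> `high_level`,
#' background -> `background`).
#'
#' @param scenes named list of annotated scenes (shared across replicates).
#' @param stacks matching [build_feature_stack()] list.
#' @param geometry a [screen_geometry()].
#' @param n_reps number of replicates.
#' @param n_participants viewers per scenario.
#' @param n_per_class looked/not-looked samples per scene.
#' @param seed base seed.
#' @return Data frame `replicate, scenario, winner, match` with a
#'   `match_rate` attribute.
#' @export
attention_recovery <- function(scenes, stacks, geometry, n_reps = 40,
                               n_participants = 5, n_per_class = 20,
                               seed = 1L) {
  doms <- dominant_profiles()
  target <- c(center = "center", object = "high_level",
              background = "background")
  rows <- list()
  for (r in seq_len(n_reps)) for (dn in names(doms)) {
    maps <- simulate_group_maps(scenes, doms[[dn]], geometry, n_participants,
                                seed = str_seed("recov", r, dn, base = seed))
    groups <- setNames(rep(dn, length(maps)), names(maps))
    ga <- suppressWarnings(
      group_attention_analysis(maps, groups, stacks, level = "group",
                               n_per_class = n_per_class,
                               seed = str_seed("fit", r, dn, base = seed)))
    winner <- names(which.max(ga[[dn]]$types))
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r, scenario = dn, winner = winner,
      match = winner == target[[dn]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "match_rate") <- mean(out$match)
  out
}

#' Type-contribution ordering under the clinical presets
#'
#' Simulates CU/AD/LBD cohorts (default presets) on the shared scenes over
#' `n_reps` replicates and averages the group-level type contributions, the
#' scale at which the preset ordering (high-level decreasing and center
#' increasing from CU to LBD) is assessed.
#'
#' @inheritParams attention_recovery
#' @param profiles named list of group presets.
#' @return 3 x 4 matrix of mean type contributions (groups x types), with
#'   the per-replicate array as attribute `replicates`.
#' @export
preset_type_contributions <- function(scenes, stacks, geometry, n_reps = 6,
                                      n_participants = 5, n_per_class = 20,
                                      seed = 1L,
                                      profiles = default_profiles()) {
  arr <- array(NA_real_, c(length(profiles), 4, n_reps),
               dimnames = list(names(profiles),
                               c("center", "background", "low_level",
                                 "high_level"), NULL))
  for (r in seq_len(n_reps)) {
    maps <- list(); groups <- c()
    for (g in names(profiles)) {
      gm <- simulate_group_maps(scenes, profiles[[g]], geometry,
                                n_participants,
                                seed = str_seed("ord", r, g, base = seed))
      names(gm) <- paste(g, names(gm), sep = "_")
      maps <- c(maps, gm)
      groups[names(gm)] <- g
    }
    ga <- suppressWarnings(
      group_attention_analysis(maps, groups, stacks, level = "group",
                               n_per_class = n_per_class,
                               seed = str_seed("ordfit", r, base = seed)))
    for (g in names(profiles)) arr[g, , r] <- ga[[g]]$types
  }
  out <- apply(arr, c(1, 2), mean)
  attr(out, "replicates") <- arr
  out
}

#' Map entropy across an exploration-parameter grid
#'
#' For each seed and each exploration value, simulates recordings on the
#' scenes (object-driven viewers differing only in exploration), builds
#' density maps and averages their Shannon entropy; reports the per-seed
#' Spearman correlation between exploration and mean entropy.
#'
#' @param scenes named list of annotated scenes.
#' @param geometry a [screen_geometry()].
#' @param grid exploration values (default a 5-point grid).
#' @param n_seeds independent repetitions.
#' @param seed base seed.
#' @return List with `table` (seed x grid mean entropies), `spearman`
#'   (per-seed rho) and `mean_entropy` (grid means over seeds).
#' @export
entropy_exploration_grid <- function(scenes, geometry,
                                     grid = c(0.5, 0.85, 1.25, 1.8, 2.6),
                                     n_seeds = 6, seed = 1L) {
  tab <- matrix(NA_real_, n_seeds, length(grid),
                dimnames = list(NULL, paste0("expl_", grid)))
  for (s in seq_len(n_seeds)) for (gi in seq_along(grid)) {
    vp <- viewer_profile("grid", 0.2, 0.6, 0.2, exploration = grid[gi])
    ents <- c()
    for (sid in names(scenes)) {
      rec <- simulate_gaze(scenes[[sid]], vp, geometry,
                           seed = str_seed("ent", s, gi, sid, base = seed))
      cg <- process_recording(rec, geometry)
      if (cg$excluded || nrow(cg$points) == 0) next
      ents <- c(ents, map_entropy(density_map(cg$points, geometry,
                                              px_per_degree(geometry))))
    }
    tab[s, gi] <- mean(ents)
  }
  rho <- apply(tab, 1, function(v) cor(grid, v, method = "spearman"))
  list(table = tab, spearman = rho, mean_entropy = colMeans(tab))
}

#' Feature-level cohort simulator for classifier validation
#'
#' Draws standard-normal 65-feature vectors and shifts a distinct 10-feature
#' block per group by `shift` standard deviations, emulating well-separated
#' (or, with `shift = 0`, uninformative) eye-movement features.
#'
#' @param n_per_group participants per group.
#' @param shift group-mean shift in sd units.
#' @param groups group labels.
#' @param p number of features.
#' @param seed integer seed.
#' @return List with feature matrix `X` (named columns) and labels `y`.
#' @export
simulate_feature_cohort <- function(n_per_group, shift = 2,
                                    groups = c("AD", "CU", "LBD"), p = 65,
                                    seed = 1L) {
  with_seed(as.integer(seed), {
    k <- length(groups)
    X <- matrix(rnorm(k * n_per_group * p), k * n_per_group, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(groups, each = n_per_group)
    for (gi in seq_len(k)) {
      cols <- ((gi - 1) * 10 + 1):(gi * 10)
      X[y == groups[gi], cols] <- X[y == groups[gi], cols] + shift
    }
    list(X = X, y = y)
  })
}
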