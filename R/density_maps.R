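# Gaze-density maps and their summary statistics: Shannon entropy, Pearson
# map similarity, similarity-to-controls, and the empty-center (2 deg) check.

# Banded Gaussian smoothing matrix, truncated at 3 sigma. Columns are
# normalized to sum 1, so every source pixel distributes unit mass even at the
# borders (border renormalization) and smoothing conserves total mass.
gauss_band <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    w <- dnorm(lo:hi, mean = j, sd = sigma)
    A[lo:hi, j] <- w / sum(w)
  }
  A
}

# Separable Gaussian blur of an H x W matrix (sigma in px). "mass" conserves
# the total (each source pixel spreads unit mass; right for histograms);
# "dc" preserves constants (each output pixel averages unit weight; right
# for images).
gauss_blur <- function(m, sigma, normalize = c("mass", "dc")) {
  normalize <- match.arg(normalize)
  if (sigma <= 0) return(m)
  Ar <- gauss_band(nrow(m), sigma); Ac <- gauss_band(ncol(m), sigma)
  if (normalize == "mass") Ar %*% m %*% t(Ac) else t(Ar) %*% m %*% Ac
}

new_density_map <- function(values, scene_id = NA_character_,
                            source = NA_character_) {
  structure(values, class = c("gaze_density_map", "matrix"),
            scene_id = scene_id, source = source)
}

#' Gaze-density map from raw gaze samples
#'
#' Bins cleaned gaze points into a pixel histogram, smooths it with an
#' isotropic fovea-sized Gaussian kernel (default sigma = 55 px on the
#' 1600 x 1200 display, about 1 degree) truncated at 3 sigma with border
#' renormalization, and divides by the total so the map sums to 1.
#'
#' @param points data frame with `x_px`, `y_px` (0-based pixel coordinates,
#'   inside the image).
#' @param geometry a [screen_geometry()] giving the map dimensions.
#' @param sigma_px Gaussian smoothing parameter in pixels, read according to
#'   `kernel`.
#' @param kernel whether `sigma_px` is the Gaussian sigma (default) or the
#'   kernel FWHM (`"fwhm"`, divided by 2 sqrt(2 log 2)); both readings of a
#'   "55-pixel fovea kernel" are supported.
#' @param window optional `c(start_s, end_s)` time window; only points with
#'   `start <= t_s < end` enter the map (requires a `t_s` column).
#' @return An H x W `gaze_density_map` matrix summing to 1.
#' @export
density_map <- function(points, geometry, sigma_px = 55,
                        kernel = c("sigma", "fwhm"), window = NULL) {
  stopifnot(inherits(geometry, "screen_geometry"))
  kernel <- match.arg(kernel)
  if (sigma_px <= 0) stop("sigma_px must be positive")
  if (kernel == "fwhm") sigma_px <- sigma_px / (2 * sqrt(2 * log(2)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, "t_s" %in% names(points))
    points <- points[points$t_s >= window[1] & points$t_s < window[2], ,
                     drop = FALSE]
  }
  if (is.null(points) || nrow(points) == 0)
    stop("density_map requires at least one gaze point (apply QC first)")
  W <- geometry$width_px; H <- geometry$height_px
  ix <- floor(points$x_px) + 1L
  iy <- floor(points$y_px) + 1L
  if (any(ix < 1L | ix > W | iy < 1L | iy > H))
    stop("gaze points outside the image; run clean_samples() first")
  m <- matrix(0, H, W)
  idx <- (ix - 1L) * H + iy
  tab <- tabulate(idx, nbins = H * W)
  m[] <- tab
  sm <- gauss_blur(m, sigma_px)
  sm <- sm / sum(sm)
  new_density_map(sm)
}

#' Shannon entropy of a gaze-density map, in bits
#'
#' `-sum(p_i * log2(p_i))` over map pixels, with `0 * log 0 := 0`. The map is
#' renormalized by its sum before the computation. Higher entropy means more
#' spatially dispersed exploration; a point mass has entropy 0, a uniform map
#' `log2(W * H)` bits.
#'
#' @param m a nonnegative matrix (typically a [density_map()]).
#' @param downsample integer block size; values above 1 aggregate the map
#'   into `downsample x downsample` pixel blocks before the computation (a
#'   speed option, off by default; entropy is then measured at the coarser
#'   resolution).
#' @return Entropy in bits.
#' @export
map_entropy <- function(m, downsample = 1L) {
  if (downsample > 1 && !is.null(dim(m))) {
    H <- nrow(m); W <- ncol(m)
    bi <- (seq_len(H) - 1) %/% downsample
    bj <- (seq_len(W) - 1) %/% downsample
    m <- rowsum(t(rowsum(m, bi)), bj)
  }
  v <- as.numeric(m)
  if (any(v < 0)) stop("density map has negative entries")
  s <- sum(v)
  if (s <= 0) stop("density map sums to zero")
  p <- v[v > 0] / s
  -sum(p * log2(p))
}

#' Pearson similarity of two gaze-density maps
#'
#' Both maps are flattened to vectors and compared with the Pearson
#' correlation coefficient.
#'
#' @param a,b matrices of identical dimensions.
#' @return Correlation in \[-1, 1\].
#' @export
map_similarity <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("maps must have identical dimensions")
  va <- as.numeric(a); vb <- as.numeric(b)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("map similarity undefined: at least one map is constant")
  cor(va, vb)
}

#' Per-participant gaze similarity to the control group
#'
#' For a patient, the per-scene similarity is the mean Pearson correlation of
#' their map with every control participant's map for that scene. For a
#' control, it is the mean over all unordered within-control pairs involving
#' that participant. Scenes excluded by QC for either member of a pair are
#' skipped.
#'
#' @param maps nested list: `maps[[participant_id]][[scene_id]]` is a density
#'   map (or `NULL` when the scene was excluded for that participant).
#' @param groups named character vector mapping participant id to group label.
#' @param control label of the control group (default `"CU"`).
#' @return Data frame with `participant_id`, `group`, `scene_id`, `r`, plus a
#'   `group_summary` attribute (mean r per group over participants and scenes).
#' @export
similarity_to_controls <- function(maps, groups, control = "CU") {
  ids <- names(maps)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  controls <- ids[groups[ids] == control]
  if (length(controls) < 2) stop("need at least 2 control participants")
  out <- list()
  for (id in ids) {
    others <- if (groups[[id]] == control) setdiff(controls, id) else controls
    for (sc in names(maps[[id]])) {
      a <- maps[[id]][[sc]]
      if (is.null(a)) next
      rs <- c()
      for (oid in others) {
        b <- maps[[oid]][[sc]]
        if (is.null(b)) next
        rs <- c(rs, map_similarity(a, b))
      }
      if (length(rs))
        out[[length(out) + 1L]] <- data.frame(
          participant_id = id, group = groups[[id]], scene_id = sc,
          r = mean(rs), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  per_part <- aggregate(r ~ participant_id + group, tab, mean)
  summ <- aggregate(r ~ group, per_part, mean)
  attr(tab, "group_summary") <- setNames(summ$r, summ$group)
  tab
}

#' Group-aggregate gaze-density map
#'
#' Mean of the participant maps, renormalized to sum 1 (used for group-level
#' figures).
#'
#' @param maps list of same-dimension density maps.
#' @return A `gaze_density_map`.
#' @export
aggregate_maps <- function(maps) {
  maps <- Filter(Negate(is.null), maps)
  if (length(maps) == 0) stop("no maps to aggregate")
  m <- Reduce(`+`, maps) / length(maps)
  new_density_map(m / sum(m))
}

# Pixel mask of the central disc of the given radius in degrees.
center_disc_mask <- function(geometry, radius_deg = 2) {
  W <- geometry$width_px; H <- geometry$height_px
  r_px <- radius_deg * px_per_degree(geometry)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  dx2 <- (seq_len(W) - 1 - cx)^2
  dy2 <- (seq_len(H) - 1 - cy)^2
  outer(dy2, dx2, "+") <= r_px^2
}

#' Center-bias check on scenes with an empty central disc
#'
#' Restricts to scenes where no object mask touches the central disc of
#' `radius_deg` degrees, computes each participant's gaze-density mass inside
#' that disc, and reports per-group means and ratios versus the control group.
#'
#' @param maps nested list as in [similarity_to_controls()].
#' @param groups named group-label vector by participant id.
#' @param scenes named list of annotated scenes (see [generate_scene()]).
#' @param geometry a [screen_geometry()].
#' @param radius_deg disc radius in degrees of visual angle.
#' @param control control group label.
#' @return List with `eligible_scenes`, a per-observation `table`,
#'   `group_mean` and `ratio_vs_control`. When no scene is eligible the result
#'   has `eligible_scenes = character(0)` and empty components.
#' @export
center_disc_stats <- function(maps, groups, scenes, geometry,
                              radius_deg = 2, control = "CU") {
  disc <- center_disc_mask(geometry, radius_deg)
  eligible <- names(scenes)[vapply(scenes, function(sc) {
    if (length(sc$objects) == 0) return(TRUE)
    !any(vapply(sc$objects, function(ob) any(ob$mask & disc), logical(1)))
  }, logical(1))]
  if (length(eligible) == 0)
    return(list(eligible_scenes = character(0),
                table = data.frame(), group_mean = numeric(0),
                ratio_vs_control = numeric(0)))
  rows <- list()
  for (id in names(maps)) for (sc in intersect(names(maps[[id]]), eligible)) {
    m <- maps[[id]][[sc]]
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = id, group = groups[[id]], scene_id = sc,
      center_share = sum(m[disc]), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  per_part <- aggregate(center_share ~ participant_id + group, tab, mean)
  gm <- aggregate(center_share ~ group, per_part, mean)
  group_mean <- setNames(gm$center_share, gm$group)
  if (!control %in% names(group_mean)) stop("control group absent from maps")
  list(eligible_scenes = eligible, table = tab, group_mean = group_mean,
       ratio_vs_control = group_mean / group_mean[[control]])
}
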