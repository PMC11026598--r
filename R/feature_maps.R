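# The 22 per-scene feature maps consumed by the attention model: 3 Itti-Koch
# conspicuity maps (color, intensity, orientation), 17 object-attribute maps
# (4 properties + 12 semantics + an object-presence baseline channel), the
# image-center Gaussian and the binary background map.

#' Names of the 17 high-level (object-based) feature channels
#'
#' The 4 mask-derived properties, the 12 semantic attributes, and an
#' `object_presence` baseline channel (value 1 for every object), which
#' completes the 17-channel object-based set.
#' @return Character vector of length 17.
#' @export
highlevel_names <- function() c(property_names(), semantic_names(), "object_presence")

#' Canonical order of the 22 feature maps
#' @return Character vector of length 22.
#' @export
feature_map_names <- function() {
  c("center", "background", "color", "intensity", "orientation",
    highlevel_names())
}

resize_mat <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  out <- EBImage::resize(m, w = H, h = W)
  matrix(as.numeric(out), H, W)
}

minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 1e-9) return(m * 0)  # constant up to fp noise
  (m - rng[1]) / (rng[2] - rng[1])
}

# Itti-Koch max-based normalization N(.): scale to [0,1], then multiply by
# (1 - mean height of the non-global local maxima)^2, promoting maps with a
# single dominant peak.
ik_normalize <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  m <- m / mx
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(m)
  ctr <- m[2:(H - 1), 2:(W - 1)]
  is_max <- ctr >= m[1:(H - 2), 2:(W - 1)] & ctr >= m[3:H, 2:(W - 1)] &
    ctr >= m[2:(H - 1), 1:(W - 2)] & ctr >= m[2:(H - 1), 3:W] &
    ctr >= m[1:(H - 2), 1:(W - 2)] & ctr >= m[1:(H - 2), 3:W] &
    ctr >= m[3:H, 1:(W - 2)] & ctr >= m[3:H, 3:W]
  peaks <- ctr[is_max]
  peaks <- peaks[peaks < max(m) - 1e-12]
  mbar <- if (length(peaks)) mean(peaks) else 0
  m * (1 - mbar)^2
}

# Iterative difference-of-Gaussians normalization: repeated self-excitation
# / broad inhibition with rectification, sharpening isolated peaks further
# than the one-shot max-based operator.
ik_normalize_iterative <- function(m, n_iter = 5) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  m <- m / mx
  sig_ex <- max(1, 0.02 * ncol(m)); sig_in <- max(2, 0.25 * ncol(m))
  for (i in seq_len(n_iter)) {
    ex <- 0.5 * gauss_blur(m, sig_ex, normalize = "dc")
    inh <- 1.5 * gauss_blur(m, sig_in, normalize = "dc")
    m <- pmax(m + ex - inh - 0.02, 0)
    if (max(m) > 0) m <- m / max(m)
  }
  m
}

gaussian_pyramid <- function(m, n_levels) {
  pyr <- vector("list", n_levels)
  pyr[[1]] <- m
  for (l in 2:n_levels) {
    b <- gauss_blur(pyr[[l - 1]], 1, normalize = "dc")
    pyr[[l]] <- b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE]
  }
  pyr
}

# center-surround scale pairs feasible for a pyramid of n_levels levels
# (level indices 0-based in the classic formulation; list indices 1-based)
cs_pairs <- function(n_levels) {
  cands <- intersect(c(2, 3, 4), seq_len(n_levels - 2))
  if (length(cands) == 0) cands <- 1
  prs <- list()
  for (cc in cands) for (dd in c(3, 4)) {
    ss <- min(cc + dd, n_levels - 1)
    if (ss > cc) prs[[paste(cc, ss)]] <- c(cc, ss)
  }
  unique(prs)
}

center_surround <- function(pyr_c, pyr_s, pairs) {
  lapply(pairs, function(pr) {
    cen <- pyr_c[[pr[1] + 1L]]
    sur <- resize_mat(pyr_s[[pr[2] + 1L]], nrow(cen), ncol(cen))
    list(level = pr[1], map = abs(cen - sur))
  })
}

# sum feature maps at the integration level after N(.) per map
across_scale_sum <- function(cs_maps, target_dim, norm_fn = ik_normalize) {
  acc <- matrix(0, target_dim[1], target_dim[2])
  for (cm in cs_maps)
    acc <- acc + resize_mat(norm_fn(cm$map), target_dim[1], target_dim[2])
  acc
}

gabor_kernel <- function(theta, size = 9L, sigma = 2.3, lambda = 4.6,
                         phase = 0) {
  half <- (size - 1) / 2
  gx <- matrix(rep(-half:half, each = size), size, size)
  gy <- matrix(rep(-half:half, size), size, size)
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda + phase)
  k - mean(k)  # zero DC response: constant images yield zero maps
}

#' Itti-Koch conspicuity maps (color, intensity, orientation)
#'
#' The classic architecture: intensity `I = (r + g + b) / 3`; red-green and
#' blue-yellow opponency channels; dyadic Gaussian pyramids;
#' center-surround differences at center scales `c in {2,3,4}` against
#' surrounds `s = c + delta`, `delta in {3,4}` (scale sets are reduced, with
#' a message, when the image is too small for a 9-level pyramid); orientation
#' channels from zero-DC Gabor filters at 0/45/90/135 degrees; the max-based
#' normalization operator N(.) per map; across-scale addition; and per-channel
#' conspicuity maps upsampled to full resolution and min-max scaled to
#' \[0, 1\].
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param normalization `"max"` (the 1998 operator, default) or
#'   `"iterative"` (repeated DoG self-excitation/inhibition).
#' @return Named list of H x W matrices: `color`, `intensity`, `orientation`.
#' @export
ittikoch_conspicuity <- function(image, normalization = c("max", "iterative")) {
  normalization <- match.arg(normalization)
  ik_norm <- if (normalization == "max") ik_normalize else ik_normalize_iterative
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("ittikoch_conspicuity requires an RGB image (H x W x 3)")
  H <- dim(image)[1]; W <- dim(image)[2]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  I <- (r + g + b) / 3
  n_levels <- max(4L, min(9L, floor(log2(min(H, W) / 4)) + 1L))
  if (n_levels < 9) message("pyramid reduced to ", n_levels, " levels")
  # hue channels, normalized by intensity where it is appreciable
  imax <- max(I)
  nz <- I > imax / 10
  rn <- r; gn <- g; bn <- b
  rn[nz] <- r[nz] / I[nz]; gn[nz] <- g[nz] / I[nz]; bn[nz] <- b[nz] / I[nz]
  rn[!nz] <- 0; gn[!nz] <- 0; bn[!nz] <- 0
  R <- pmax(rn - (gn + bn) / 2, 0)
  G <- pmax(gn - (rn + bn) / 2, 0)
  B <- pmax(bn - (rn + gn) / 2, 0)
  Y <- pmax((rn + gn) / 2 - abs(rn - gn) / 2 - bn, 0)
  pyrI <- gaussian_pyramid(I, n_levels)
  pyrRG <- gaussian_pyramid(R - G, n_levels)
  pyrBY <- gaussian_pyramid(B - Y, n_levels)
  pairs <- cs_pairs(n_levels)
  tl <- min(4L, n_levels - 1L) + 1L  # integration level (list index)
  tdim <- dim(pyrI[[tl]])
  # intensity
  csI <- center_surround(pyrI, pyrI, pairs)
  conspI <- ik_norm(across_scale_sum(csI, tdim, ik_norm))
  # color: double-opponency |rg_c + rg_s|, |by_c + by_s|
  csC <- c(
    lapply(pairs, function(pr) {
      cen <- pyrRG[[pr[1] + 1L]]
      sur <- resize_mat(pyrRG[[pr[2] + 1L]], nrow(cen), ncol(cen))
      list(level = pr[1], map = abs(cen + sur))
    }),
    lapply(pairs, function(pr) {
      cen <- pyrBY[[pr[1] + 1L]]
      sur <- resize_mat(pyrBY[[pr[2] + 1L]], nrow(cen), ncol(cen))
      list(level = pr[1], map = abs(cen + sur))
    }))
  conspC <- ik_norm(across_scale_sum(csC, tdim, ik_norm))
  # orientation: Gabor energy pyramids per angle
  conspO <- matrix(0, tdim[1], tdim[2])
  for (theta in c(0, 45, 90, 135) * pi / 180) {
    ke <- gabor_kernel(theta, phase = 0)
    ko <- gabor_kernel(theta, phase = pi / 2)
    pyrO <- lapply(pyrI, function(lv) {
      if (min(dim(lv)) < 11) return(lv * 0)
      e <- EBImage::filter2(lv, ke, boundary = "replicate")
      o <- EBImage::filter2(lv, ko, boundary = "replicate")
      sqrt(e^2 + o^2)
    })
    csO <- center_surround(pyrO, pyrO, pairs)
    conspO <- conspO + ik_norm(across_scale_sum(csO, tdim, ik_norm))
  }
  conspO <- ik_norm(conspO)
  lapply(list(color = conspC, intensity = conspI, orientation = conspO),
         function(m) minmax01(resize_mat(m, H, W)))
}

gaussian_peak_map <- function(W, H, cx, cy, sigma_px) {
  outer(exp(-((0:(H - 1)) - cy)^2 / (2 * sigma_px^2)),
        exp(-((0:(W - 1)) - cx)^2 / (2 * sigma_px^2)))
}

#' Object-attribute feature maps
#'
#' One map per high-level channel: the sum over objects of the object's
#' attribute value times a 2-D Gaussian (sigma = `sigma_deg` degrees) at the
#' object centroid. Semantic values are 0/1, property values continuous, and
#' the `object_presence` channel uses value 1 for every object. Nonzero maps
#' are min-max scaled to \[0, 1\].
#'
#' @param scene an `annotated_scene`.
#' @param geometry a [screen_geometry()].
#' @param sigma_deg kernel width in degrees of visual angle.
#' @return Named list of 17 H x W matrices.
#' @export
attribute_maps <- function(scene, geometry, sigma_deg = 2) {
  sig <- sigma_deg * px_per_degree(geometry)
  W <- scene$width; H <- scene$height
  vals <- function(ob, a) {
    if (a == "object_presence") 1
    else if (a %in% property_names()) ob$properties[[a]]
    else if (a %in% semantic_names()) as.numeric(ob$semantics[[a]])
    else stop("unknown attribute: ", a)
  }
  setNames(lapply(highlevel_names(), function(a) {
    m <- matrix(0, H, W)
    for (ob in scene$objects) {
      v <- vals(ob, a)
      if (v == 0) next
      ct <- ob$centroid_xy_px
      m <- m + v * gaussian_peak_map(W, H, ct[["x"]], ct[["y"]], sig)
    }
    if (max(m) > 0) minmax01(m) else m
  }), highlevel_names())
}

#' Image-center Gaussian map
#'
#' Isotropic Gaussian (peak 1) at the image center, sigma = `sigma_deg`
#' degrees.
#'
#' @param dims `c(H, W)` in pixels.
#' @param geometry a [screen_geometry()].
#' @param sigma_deg kernel sigma in degrees.
#' @return H x W matrix with maximum 1 at the center pixel.
#' @export
center_map <- function(dims, geometry, sigma_deg = 1) {
  H <- dims[1]; W <- dims[2]
  gaussian_peak_map(W, H, (W - 1) / 2, (H - 1) / 2,
                    sigma_deg * px_per_degree(geometry))
}

#' Binary background map
#'
#' 1 where no object mask covers the pixel, 0 elsewhere; all ones for a scene
#' with no objects.
#'
#' @param scene an `annotated_scene`.
#' @return H x W 0/1 matrix.
#' @export
background_map <- function(scene) {
  u <- object_union_mask(scene)
  for (ob in scene$objects)
    if (!all(dim(ob$mask) == dim(u))) stop("object mask dimension mismatch")
  1 - u * 1
}

#' Assemble the full 22-map feature stack for one scene
#'
#' Center map, background map, the 3 Itti-Koch conspicuity maps and the 17
#' object-attribute maps, in canonical order ([feature_map_names()]). All
#' maps are finite and lie in \[0, 1\].
#'
#' @param scene an `annotated_scene` (must include the pixel image).
#' @param geometry a [screen_geometry()].
#' @return A `feature_stack`: named list of 22 H x W matrices.
#' @export
build_feature_stack <- function(scene, geometry) {
  if (is.null(scene$image)) stop("scene has no pixel image")
  dims <- c(scene$height, scene$width)
  stack <- c(list(center = center_map(dims, geometry),
                  background = background_map(scene)),
             ittikoch_conspicuity(scene$image),
             attribute_maps(scene, geometry))
  stack <- stack[feature_map_names()]
  stopifnot(length(stack) == 22,
            all(vapply(stack, function(m) all(is.finite(m)), logical(1))))
  structure(stack, class = "feature_stack", scene_id = scene$scene_id)
}
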