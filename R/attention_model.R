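# The object-level computational visual-attention analysis: sample looked /
# not-looked pixels from gaze-density maps (top 10% vs bottom 30%), fit a
# linear max-margin classifier on standardized feature-stack values, and
# aggregate the 22 per-feature weights into 4 type-level attention
# contributions (center, background, low-level, high-level).

feature_type_of <- function(names) {
  ifelse(names == "center", "center",
         ifelse(names == "background", "background",
                ifelse(names %in% c("color", "intensity", "orientation"),
                       "low_level", "high_level")))
}

#' Deterministic 31-bit sub-seed from string components
#'
#' Hashes the `/`-joined components (plus a base seed) into `[0, 2^31)`;
#' used throughout to derive independent, order-invariant sub-seeds from a
#' single master seed.
#'
#' @param ... components coerced to character.
#' @param base integer base seed.
#' @return Integer seed.
#' @export
str_seed <- function(..., base = 0L) {
  s <- paste(..., sep = "/")
  h <- as.numeric(base)
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Sample looked / not-looked pixel locations from a gaze-density map
#'
#' Positive samples are drawn uniformly without replacement from the pixels
#' at or above the `pos_quantile` of map values (the top 10% by default),
#' negatives from those at or below the `neg_quantile` (bottom 30%);
#' percentile ties are included in the candidate sets before sampling. On a
#' degenerate (near-constant) map the percentile sets collapse and the scene
#' is skipped with a warning (`NULL` return).
#'
#' @param m a [density_map()].
#' @param pos_quantile,neg_quantile value quantiles bounding the candidate
#'   sets.
#' @param n_per_class draws per class (all candidates, with a warning, when
#'   fewer are available).
#' @param seed integer seed.
#' @return Data frame `x, y, label` (0-based pixel coordinates, label +1/-1),
#'   or `NULL` for a degenerate map.
#' @export
sample_locations <- function(m, pos_quantile = 0.90, neg_quantile = 0.30,
                             n_per_class = 10, seed = 1L) {
  stopifnot(n_per_class >= 1)
  v <- as.numeric(m); H <- nrow(m)
  qpos <- quantile(v, pos_quantile, names = FALSE)
  qneg <- quantile(v, neg_quantile, names = FALSE)
  pos <- which(v >= qpos); neg <- which(v <= qneg)
  if (qpos <= qneg || length(pos) == 0 || length(neg) == 0) {
    warning("degenerate density map: percentile sets overlap; scene skipped")
    return(NULL)
  }
  with_seed(as.integer(seed), {
    draw <- function(set, n) {
      if (length(set) < n) {
        warning("candidate set smaller than n_per_class; using all ",
                length(set), " pixels")
        set
      } else set[sample.int(length(set), n)]
    }
    pi_ <- draw(pos, n_per_class); ni_ <- draw(neg, n_per_class)
    data.frame(x = ((c(pi_, ni_) - 1L) %/% H),
               y = ((c(pi_, ni_) - 1L) %% H),
               label = rep(c(1L, -1L), c(length(pi_), length(ni_))))
  })
}

# feature values of a stack at 0-based pixel locations -> n x 22 matrix
extract_features <- function(stack, locs) {
  X <- vapply(stack, function(m) m[cbind(locs$y + 1L, locs$x + 1L)],
              numeric(nrow(locs)))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(stack)))
  X
}

#' Standardized training set for the attention model
#'
#' Standardizes each feature column to mean 0, sd 1; constant columns are
#' dropped with a warning (their weights are reported as 0).
#'
#' @param X numeric matrix (rows = sampled locations, named columns).
#' @param y labels, +1 / -1.
#' @return A `training_set` list: `X`, `y`, `center`, `scale`, `dropped`.
#' @export
make_training_set <- function(X, y) {
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  dropped <- colnames(X)[scl == 0]
  if (length(dropped))
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  structure(list(X = Xs, y = y, center = ctr[keep], scale = scl[keep],
                 dropped = dropped),
            class = "training_set")
}

#' Fit the linear attention model
#'
#' Linear-kernel soft-margin SVM (hinge loss, regularization `C`) on a
#' standardized training set; the primal coefficients are the per-feature
#' attention weights, oriented so that positive scores predict looked
#' locations.
#'
#' @param ts a [make_training_set()].
#' @param C regularization parameter.
#' @return An `attention_weights` list: `w` (named, length 22 with dropped
#'   features at 0), `intercept`, `accuracy` (training), `n`.
#' @export
fit_attention_model <- function(ts, C = 1) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$y)) < 2) stop("training labels contain a single class")
  fit <- e1071::svm(x = ts$X, y = factor(ts$y, levels = c(-1, 1)),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  score <- drop(ts$X %*% w) + b
  if (mean(score[ts$y == 1]) < mean(score[ts$y == -1])) { w <- -w; b <- -b }
  acc <- mean(sign(drop(ts$X %*% w) + b) == ts$y)
  full <- setNames(numeric(length(feature_map_names())), feature_map_names())
  full[names(w)] <- w
  structure(list(w = full, intercept = b, accuracy = acc, n = nrow(ts$X)),
            class = "attention_weights")
}

#' Type-level attention contributions
#'
#' Aggregates the 22 signed per-feature weights into the 4 feature types:
#' center and background are singleton types; low-level is the mean of the 3
#' conspicuity weights; high-level the mean of the 17 object-attribute
#' weights. `method = "sum"` and `"mean_abs"` are offered as alternative
#' aggregations.
#'
#' @param aw an `attention_weights` (or a named 22-vector of weights).
#' @param method aggregation of within-type coefficients.
#' @return Named numeric vector: `center, background, low_level, high_level`.
#' @export
type_contributions <- function(aw, method = c("mean", "sum", "mean_abs")) {
  method <- match.arg(method)
  w <- if (inherits(aw, "attention_weights")) aw$w else aw
  ty <- feature_type_of(names(w))
  agg <- switch(method, mean = function(v) mean(v), sum = function(v) sum(v),
                mean_abs = function(v) mean(abs(v)))
  vapply(c("center", "background", "low_level", "high_level"),
         function(t) agg(w[ty == t]), numeric(1))
}

collect_unit_samples <- function(maps_pid, stacks, n_per_class, seed_tag,
                                 base_seed) {
  Xs <- list(); ys <- list(); scenes_used <- character(0)
  for (sid in names(maps_pid)) {
    m <- maps_pid[[sid]]
    if (is.null(m) || is.null(stacks[[sid]])) next
    locs <- withCallingHandlers(
      sample_locations(m, n_per_class = n_per_class,
                       seed = str_seed(seed_tag, sid, base = base_seed)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(locs)) next
    Xs[[sid]] <- extract_features(stacks[[sid]], locs)
    ys[[sid]] <- locs$label
    scenes_used <- c(scenes_used, sid)
  }
  list(X = do.call(rbind, Xs), y = unlist(ys, use.names = FALSE),
       scenes = scenes_used)
}

#' Group- or participant-level attention-weight estimation
#'
#' Pools looked / not-looked samples over all QC-passed scenes of a
#' diagnostic group (level `"group"`) or of one participant (level
#' `"participant"`), then standardizes, fits the linear model and derives the
#' type contributions; the pipeline is identical at both levels.
#' Participants with fewer than `min_scenes` usable scenes are excluded with
#' a warning. Sub-seeds are derived per (unit, participant, scene), so
#' results do not depend on participant ordering.
#'
#' @param maps nested density-map list (`[[participant]][[scene]]`, `NULL`
#'   where QC excluded the trial), e.g. from [cohort_density_maps()].
#' @param groups named group-label vector by participant id.
#' @param stacks named list of [build_feature_stack()] results by scene id.
#' @param level `"group"` or `"participant"`.
#' @param n_per_class samples per class per scene.
#' @param min_scenes minimum usable scenes per participant
#'   (participant level).
#' @param C SVM regularization.
#' @param seed base seed.
#' @return Named list per unit: `weights` (`attention_weights`), `types`
#'   (type contributions), `n_scenes`.
#' @export
group_attention_analysis <- function(maps, groups, stacks,
                                     level = c("group", "participant"),
                                     n_per_class = 10, min_scenes = 10,
                                     C = 1, seed = 1L) {
  level <- match.arg(level)
  out <- list()
  if (level == "group") {
    for (g in unique(groups[names(maps)])) {
      pids <- sort(names(maps)[groups[names(maps)] == g])  # order-invariant
      Xs <- list(); ys <- list(); ns <- 0L
      for (pid in pids) {
        cs <- collect_unit_samples(maps[[pid]], stacks, n_per_class,
                                   paste(g, pid, sep = "/"), seed)
        if (is.null(cs$X)) next
        Xs[[pid]] <- cs$X; ys[[pid]] <- cs$y
        ns <- ns + length(cs$scenes)
      }
      ts <- make_training_set(do.call(rbind, Xs), unlist(ys, use.names = FALSE))
      aw <- fit_attention_model(ts, C = C)
      out[[g]] <- list(weights = aw, types = type_contributions(aw),
                       n_scenes = ns)
    }
  } else {
    for (pid in names(maps)) {
      cs <- collect_unit_samples(maps[[pid]], stacks, n_per_class, pid, seed)
      if (length(cs$scenes) < min_scenes) {
        warning("participant ", pid, " has ", length(cs$scenes),
                " usable scenes (< ", min_scenes, "); excluded")
        next
      }
      ts <- make_training_set(cs$X, cs$y)
      aw <- fit_attention_model(ts, C = C)
      out[[pid]] <- list(weights = aw, types = type_contributions(aw),
                         n_scenes = length(cs$scenes))
    }
  }
  out
}

#' Bootstrap confidence intervals for group type contributions
#'
#' Resamples scenes with replacement, re-samples locations and refits the
#' group model `B` times; percentile 95% intervals per feature type.
#'
#' @inheritParams group_attention_analysis
#' @param group group label to bootstrap.
#' @param B bootstrap replicates.
#' @return List with `estimate` and `ci` (2 x 4 matrix, rows = bounds).
#' @export
type_contribution_ci <- function(maps, groups, stacks, group, B = 200,
                                 n_per_class = 10, C = 1, seed = 1L) {
  pids <- names(maps)[groups[names(maps)] == group]
  sub <- maps[pids]
  est <- group_attention_analysis(sub, groups, stacks, level = "group",
                                  n_per_class = n_per_class, C = C,
                                  seed = seed)[[group]]$types
  sids <- names(stacks)
  boots <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, names(est)))
  for (b in seq_len(B)) {
    pick <- with_seed(str_seed(group, "boot", b, base = seed),
                      sample(sids, length(sids), replace = TRUE))
    bmaps <- lapply(sub, function(mp) {
      ms <- mp[pick]
      names(ms) <- sprintf("%s__%d", pick, seq_along(pick))
      ms
    })
    bstacks <- stacks[pick]
    names(bstacks) <- sprintf("%s__%d", pick, seq_along(pick))
    res <- tryCatch(
      group_attention_analysis(bmaps, groups, bstacks, level = "group",
                               n_per_class = n_per_class, C = C,
                               seed = seed + b),
      error = function(e) NULL)
    if (!is.null(res)) boots[b, ] <- res[[group]]$types
  }
  list(estimate = est,
       ci = apply(boots, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
}
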