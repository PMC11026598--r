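# Group-level statistics: scene-blocked repeated-measures ANOVA with
# Bonferroni post-hoc tests and Hedges' g, two-way mixed-design ANOVA,
# per-scene effect-size trends, covariate-adjusted Spearman correlations,
# BH correction, forward-stepwise BIC regression, ANOVA power analysis and
# the pupil-diameter fatigue check.

check_long_data <- function(data, value, group, participant, scene) {
  for (col in c(value, group, participant, scene))
    if (!col %in% names(data)) stop("missing column: ", col)
  if (length(unique(data[[group]])) < 2) stop("need at least 2 groups")
  invisible(data)
}

#' Bias-corrected standardized mean difference (Hedges' g)
#'
#' `g = J * (mean(x1) - mean(x2)) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 * df - 1)`, `df = n1 + n2 - 2`.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @return Hedges' g.
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))  # -0.8
#' @export
hedges_g <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("hedges_g needs >= 2 observations per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / df)
  if (sp == 0) return(0)
  (1 - 3 / (4 * df - 1)) * (mean(x1) - mean(x2)) / sp
}

#' Mixed repeated-measures ANOVA with the image as a blocking factor
#'
#' Tests the group effect on per-participant, per-scene measurements with the
#' scene (image) entered as a blocking factor: the model is
#' `value ~ scene + group` and the group effect is F-tested against the
#' residual. Bonferroni-adjusted pairwise post-hoc comparisons refit the same
#' blocked model per group pair; Hedges' g is computed on participant means
#' (each participant's value averaged over scenes).
#'
#' @param data long-format data frame.
#' @param value,group,participant,scene column names.
#' @return An `anova_result` list: `F`, `df_num`, `df_den`, `p`, `eta_p2` and
#'   a `posthoc` table (`pair`, `p_raw`, `p_bonferroni`, `hedges_g`).
#' @export
mixed_rm_anova <- function(data, value = "value", group = "group",
                           participant = "participant_id",
                           scene = "scene_id") {
  check_long_data(data, value, group, participant, scene)
  if (length(unique(data[[scene]])) < 2) stop("need at least 2 scenes")
  tab <- table(data[[group]], data[[scene]])
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop("empty group x scene cells: ",
         paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  d <- data.frame(value = data[[value]],
                  group = factor(data[[group]]),
                  participant = data[[participant]],
                  scene = factor(data[[scene]]))
  fit <- lm(value ~ scene + group, data = d)
  an <- anova(fit)
  Fg <- an["group", "F value"]; p <- an["group", "Pr(>F)"]
  eta <- an["group", "Sum Sq"] / (an["group", "Sum Sq"] + an["Residuals", "Sum Sq"])
  levs <- levels(d$group)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    dd <- droplevels(d[d$group %in% pr, ])
    a2 <- anova(lm(value ~ scene + group, data = dd))
    praw <- a2["group", "Pr(>F)"]
    pm <- aggregate(value ~ participant + group, dd, mean)
    g <- hedges_g(pm$value[pm$group == pr[1]], pm$value[pm$group == pr[2]])
    data.frame(pair = paste(pr, collapse = " vs "), p_raw = praw,
               p_bonferroni = min(1, m * praw), hedges_g = g,
               stringsAsFactors = FALSE)
  }))
  structure(list(F = Fg, df_num = an["group", "Df"],
                 df_den = an["Residuals", "Df"], p = p, eta_p2 = eta,
                 posthoc = ph),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("group effect: F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_p2))
  if (!is.null(x$posthoc)) { cat("post-hoc (Bonferroni):\n"); print(x$posthoc) }
  invisible(x)
}

#' Two-way mixed-design ANOVA (group x stratum)
#'
#' Aggregates measurements to one value per participant and stratum (mean over
#' scenes), then fits the classical mixed design with group as the
#' between-participant factor and the stratum (e.g. fewer/more objects, or
#' initial/latter session half) as the within-participant factor, via
#' `aov(value ~ group * stratum + Error(participant))`. Post-hoc tables:
#' Bonferroni-adjusted pairwise group comparisons within each stratum, and
#' paired stratum comparisons within each group.
#'
#' @inheritParams mixed_rm_anova
#' @param stratum stratum column name.
#' @return List with main-effect and interaction F/p plus post-hoc tables.
#' @export
two_way_interaction <- function(data, value = "value", group = "group",
                                participant = "participant_id",
                                stratum = "stratum", scene = NULL) {
  for (col in c(value, group, participant, stratum))
    if (!col %in% names(data)) stop("missing column: ", col)
  if (length(unique(data[[stratum]])) < 2)
    stop("stratum must have at least 2 levels")
  d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                  participant = factor(data[[participant]]),
                  stratum = factor(data[[stratum]]))
  d <- aggregate(value ~ participant + group + stratum, d, mean)
  fit <- aov(value ~ group * stratum + Error(participant), data = d)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(tb) trimws(rownames(tb))
  gi <- match("group", rn(between)); ii <- match("group:stratum", rn(within))
  si <- match("stratum", rn(within))
  res <- list(
    F_group = between[gi, "F value"], p_group = between[gi, "Pr(>F)"],
    F_stratum = within[si, "F value"], p_stratum = within[si, "Pr(>F)"],
    F_interaction = within[ii, "F value"],
    p_interaction = within[ii, "Pr(>F)"])
  # post-hoc: groups within stratum (Bonferroni over all pairs x strata)
  levs <- levels(d$group); strata <- levels(d$stratum)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m1 <- length(pairs) * length(strata)
  res$posthoc_group_within_stratum <- do.call(rbind, lapply(strata, function(st) {
    do.call(rbind, lapply(pairs, function(pr) {
      x1 <- d$value[d$stratum == st & d$group == pr[1]]
      x2 <- d$value[d$stratum == st & d$group == pr[2]]
      praw <- t.test(x1, x2)$p.value
      data.frame(stratum = st, pair = paste(pr, collapse = " vs "),
                 p_raw = praw, p_bonferroni = min(1, m1 * praw),
                 hedges_g = hedges_g(x1, x2), stringsAsFactors = FALSE)
    }))
  }))
  # post-hoc: strata within group (paired on participants)
  spairs <- utils::combn(strata, 2, simplify = FALSE)
  m2 <- length(spairs) * length(levs)
  res$posthoc_stratum_within_group <- do.call(rbind, lapply(levs, function(g) {
    do.call(rbind, lapply(spairs, function(pr) {
      w <- reshape(d[d$group == g, c("participant", "stratum", "value")],
                   idvar = "participant", timevar = "stratum",
                   direction = "wide")
      x1 <- w[[paste0("value.", pr[1])]]; x2 <- w[[paste0("value.", pr[2])]]
      ok <- complete.cases(x1, x2)
      praw <- t.test(x1[ok], x2[ok], paired = TRUE)$p.value
      data.frame(group = g, pair = paste(pr, collapse = " vs "),
                 p_raw = praw, p_bonferroni = min(1, m2 * praw),
                 hedges_g = hedges_g(x1[ok], x2[ok]), stringsAsFactors = FALSE)
    }))
  }))
  res
}

#' Per-scene between-group effect size and its trend with object count
#'
#' For every scene, a one-way ANOVA of the measurement by group yields partial
#' eta-squared `SS_between / (SS_between + SS_within)`; the trend is the
#' Pearson correlation of these effect sizes with the scene object counts.
#'
#' @inheritParams mixed_rm_anova
#' @param object_counts named numeric vector of object counts by scene id.
#' @return List with `per_scene` (scene, eta_p2, n_objects), `r` and `p`.
#' @export
per_image_effect_trend <- function(data, object_counts, value = "value",
                                   group = "group", scene = "scene_id") {
  rows <- list()
  for (sc in unique(data[[scene]])) {
    d <- data[data[[scene]] == sc, ]
    if (length(unique(d[[group]])) < 2) next
    an <- anova(lm(d[[value]] ~ factor(d[[group]])))
    eta <- an[1, "Sum Sq"] / (an[1, "Sum Sq"] + an[2, "Sum Sq"])
    rows[[length(rows) + 1L]] <- data.frame(
      scene_id = sc, eta_p2 = eta,
      n_objects = unname(object_counts[[as.character(sc)]]),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ct <- cor.test(tab$eta_p2, tab$n_objects)
  list(per_scene = tab, r = unname(ct$estimate), p = ct$p.value)
}

#' Covariate-adjusted Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariates, residualizes the ranked `x`
#' and `y` on the ranked covariates by least squares, and computes the
#' Pearson correlation of the residuals (the standard Spearman partial
#' correlation). The p-value uses the t approximation with `n - 2 - q`
#' degrees of freedom for `q` covariates. Ranking the covariates as well is
#' what removes a shared monotone confound completely; residualizing ranks
#' on raw covariates leaves their nonlinear monotone remainder in both
#' variables.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame of numeric covariates (encode sex as 0/1).
#' @return List with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates) {
  if (sd(x) == 0 || sd(y) == 0) stop("constant x or y")
  n <- length(x)
  stopifnot(length(y) == n, nrow(covariates) == n)
  Z <- cbind(1, apply(as.matrix(covariates), 2, rank))
  rx <- lm.fit(Z, rank(x))$residuals
  ry <- lm.fit(Z, rank(y))$residuals
  rho <- cor(rx, ry)
  df <- n - 2 - ncol(covariates)
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df), n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] after
#' validating the inputs).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Forward stepwise linear regression under BIC with forced covariates
#'
#' Starts from a covariate-only linear model and greedily adds the candidate
#' predictor giving the largest BIC decrease, stopping when no addition
#' decreases BIC. Candidates that make the design collinear (aliased
#' coefficients) are skipped with a warning. Forced covariates are always
#' retained.
#'
#' @param data data frame holding all variables.
#' @param response response column name.
#' @param candidates character vector of candidate predictor columns.
#' @param forced character vector of always-included covariate columns.
#' @return List with `model` (the final `lm`), `selected` (candidates added,
#'   in order), `coefficients` (estimate, p per term) and `bic_trace`.
#' @export
forward_stepwise_bic <- function(data, response, candidates,
                                 forced = c("age", "sex", "education")) {
  for (col in c(response, candidates, forced))
    if (!col %in% names(data)) stop("missing column: ", col)
  bt <- function(fm) BIC(lm(fm, data = data))
  base_terms <- forced
  fm <- as.formula(paste(response, "~", paste(base_terms, collapse = "+")))
  current_bic <- bt(fm)
  selected <- character(0)
  trace <- current_bic
  remaining <- candidates
  repeat {
    bics <- vapply(remaining, function(cand) {
      f2 <- as.formula(paste(response, "~",
                             paste(c(base_terms, selected, cand), collapse = "+")))
      fit <- lm(f2, data = data)
      if (anyNA(coef(fit))) return(NA_real_)  # collinear
      BIC(fit)
    }, numeric(1))
    if (any(is.na(bics))) {
      warning("skipping collinear candidate(s): ",
              paste(remaining[is.na(bics)], collapse = ", "))
      remaining <- remaining[!is.na(bics)]
      bics <- bics[!is.na(bics)]
    }
    if (length(bics) == 0 || min(bics) >= current_bic) break
    best <- remaining[which.min(bics)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current_bic <- min(bics)
    trace <- c(trace, current_bic)
  }
  final <- lm(as.formula(paste(response, "~",
                               paste(c(base_terms, selected), collapse = "+"))),
              data = data)
  cf <- summary(final)$coefficients
  list(model = final, selected = selected,
       coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, "Estimate"],
                                 p = cf[, "Pr(>|t|)"], row.names = NULL),
       bic_trace = trace)
}

#' Power of a one-way fixed-effects ANOVA
#'
#' Power at level `alpha` for `k` groups of `n` each with Cohen's f effect
#' size, using the noncentral F distribution with noncentrality
#' `lambda = f^2 * k * n`.
#'
#' @param f Cohen's f.
#' @param k number of groups.
#' @param n per-group sample size.
#' @param alpha significance level.
#' @return Power in \[0, 1\].
#' @export
anova_power <- function(f, k, n, alpha = 0.05) {
  if (f <= 0 || k < 2 || n < 2) stop("require f > 0, k >= 2, n >= 2")
  N <- k * n
  crit <- qf(1 - alpha, k - 1, N - k)
  1 - pf(crit, k - 1, N - k, ncp = f^2 * N)
}

#' Per-group sample size for a one-way ANOVA
#'
#' Smallest integer `n` per group such that [anova_power()] reaches the target
#' power. With f = 0.5, three groups, alpha = 0.05 and power 0.8 this is 14.
#'
#' @inheritParams anova_power
#' @param power target power.
#' @param n_max search bound.
#' @return Integer per-group sample size.
#' @export
anova_power_n <- function(f, k, alpha = 0.05, power = 0.8, n_max = 10000L) {
  if (f <= 0 || k < 2) stop("require f > 0 and k >= 2")
  for (n in 2:n_max)
    if (anova_power(f, k, n, alpha) >= power) return(n)
  stop("no n <= n_max reaches the target power")
}

#' Pupil-diameter fatigue check across session halves
#'
#' Splits scenes into the initial and latter halves of the session by stimulus
#' index, averages pupil diameter per participant and half, and tests the
#' group x half interaction with [two_way_interaction()]. A significant
#' interaction would indicate group differences in fatigue/alertness drift.
#'
#' @param data data frame with participant, group, scene-index and pupil
#'   columns.
#' @param pupil,participant,group,scene_index column names.
#' @param n_scenes total number of stimuli in the session (default: max index).
#' @return The [two_way_interaction()] result (stratum = session half).
#' @export
pupil_fatigue_test <- function(data, pupil = "pupil_mm",
                               participant = "participant_id",
                               group = "group", scene_index = "scene_index",
                               n_scenes = NULL) {
  if (!pupil %in% names(data)) stop("missing pupil column: ", pupil)
  for (col in c(participant, group, scene_index))
    if (!col %in% names(data)) stop("missing column: ", col)
  if (is.null(n_scenes)) n_scenes <- max(data[[scene_index]])
  d <- data.frame(value = data[[pupil]],
                  participant_id = data[[participant]],
                  group = data[[group]],
                  stratum = ifelse(data[[scene_index]] <= n_scenes / 2,
                                   "initial", "latter"))
  two_way_interaction(d)
}
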