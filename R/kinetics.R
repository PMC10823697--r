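#' Fit the linear range of a kinetic trace by iterative point elimination
#'
#' Ordinary least squares is fitted to the retained points and single points
#' are eliminated from the ends of the series until the Pearson correlation
#' coefficient reaches `r_min` (the assay criterion was r of at least 0.999);
#' once the threshold is met, end points keep being removed while doing so
#' strictly improves r, so a noiseless saturating trace is trimmed to exactly
#' its linear segment (on noisy data this typically removes at most one extra
#' point). Interior points are never removed: kinetic nonlinearity is
#' saturation (late points) or lag (early points). Two strategies are
#' available:
#'
#' * `"trailing_first"` (default): drop the trailing point while doing so
#'   improves r, otherwise drop whichever end point gives the larger r.
#' * `"best_improvement"`: always drop the end point giving the larger r
#'   (ties go to the trailing end).
#'
#' @param trace a [kinetic_trace()].
#' @param r_min required Pearson correlation coefficient (default 0.999).
#' @param min_points minimum number of retained points (default 5); guards
#'   against degenerate two-point "perfect" fits.
#' @param strategy point-elimination strategy, see above.
#' @return A `linear_fit`: list with `slope` (AU/min), `intercept` (AU), `r`,
#'   `n_used`, `trimmed_points` (indices into the original series) and the
#'   updated `trace` with its `retained` mask.
#' @export
fit_linear_range <- function(trace, r_min = 0.999, min_points = 5L,
                             strategy = c("trailing_first", "best_improvement")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  strategy <- match.arg(strategy)
  if (min_points < 3L) stop("`min_points` must be at least 3")
  n <- length(trace$time)
  if (n < min_points) stop("trace has fewer than `min_points` points")

  pearson_r <- function(i0, i1) {
    tt <- trace$time[i0:i1]; aa <- trace$a420[i0:i1]
    if (stats::sd(aa) == 0 || stats::sd(tt) == 0) return(NA_real_)
    stats::cor(tt, aa)
  }

  i0 <- 1L; i1 <- n
  r <- pearson_r(i0, i1)
  if (is.na(r)) stop("correlation undefined (constant trace); cannot fit")
  while (r < r_min) {
    if (i1 - i0 + 1L <= min_points) {
      stop(sprintf(
        "cannot reach r >= %g with at least %d points (best r = %.6f)",
        r_min, min_points, r))
    }
    r_tail <- pearson_r(i0, i1 - 1L)
    r_head <- pearson_r(i0 + 1L, i1)
    drop_tail <- if (strategy == "trailing_first") {
      (!is.na(r_tail) && r_tail > r) || is.na(r_head) ||
        (!is.na(r_tail) && r_tail >= r_head)
    } else {
      is.na(r_head) || (!is.na(r_tail) && r_tail >= r_head)
    }
    if (drop_tail) {
      i1 <- i1 - 1L; r <- r_tail
    } else {
      i0 <- i0 + 1L; r <- r_head
    }
    if (is.na(r)) stop("correlation became undefined during trimming")
  }
  # refinement: keep dropping end points while r strictly improves
  # (trailing end preferred, then leading)
  while (i1 - i0 + 1L > min_points) {
    r_tail <- pearson_r(i0, i1 - 1L)
    r_head <- pearson_r(i0 + 1L, i1)
    if (!is.na(r_tail) && r_tail > r &&
        (strategy == "trailing_first" || is.na(r_head) || r_tail >= r_head)) {
      i1 <- i1 - 1L; r <- r_tail
    } else if (!is.na(r_head) && r_head > r) {
      i0 <- i0 + 1L; r <- r_head
    } else break
  }

  retained <- rep(FALSE, n); retained[i0:i1] <- TRUE
  fit <- stats::lm.fit(cbind(1, trace$time[retained]),
                       trace$a420[retained])
  trace$retained <- retained
  structure(
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r = r, n_used = sum(retained),
         trimmed_points = which(!retained), trace = trace),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> slope %.4g AU/min, intercept %.4g AU, r = %.6f, %d points (%d trimmed)\n",
    x$slope, x$intercept, x$r, x$n_used, length(x$trimmed_points)))
  invisible(x)
}

#' Reaction geometry and optics for Beer-Lambert activity conversion
#'
#' Defaults describe the liquid ABTS assay well: 20 uL supernatant + 80 uL
#' buffer + 100 uL ABTS = 200 uL in a flat-bottom 96-well plate (path length
#' 0.58 cm for that fill volume), with the molar extinction coefficient of
#' the oxidized ABTS radical cation at 420 nm, 36,000 per M per cm. Epsilon
#' and path length are literature/geometry values and should be set
#' explicitly if the instrument path-corrects.
#'
#' @param epsilon molar extinction coefficient (M^-1 cm^-1).
#' @param path_length optical path length (cm).
#' @param reaction_volume reaction volume (L).
#' @param supernatant_volume supernatant volume in the reaction (L).
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(epsilon = 36000, path_length = 0.58,
                          reaction_volume = 2.0e-4,
                          supernatant_volume = 2.0e-5) {
  vals <- c(epsilon, path_length, reaction_volume, supernatant_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all activity_spec values must be positive")
  }
  structure(list(epsilon = epsilon, path_length = path_length,
                 reaction_volume = reaction_volume,
                 supernatant_volume = supernatant_volume),
            class = "activity_spec")
}

#' Convert a linear-range slope to enzymatic activity
#'
#' Beer-Lambert: a rate of absorbance change `slope` (AU/min) corresponds to
#' a product formation rate `slope / (epsilon * path_length)` in mol/L/min;
#' multiplied by the reaction volume and 1e6 this gives umol oxidized ABTS
#' per minute in the well. With `per_supernatant = TRUE` the activity is
#' rescaled by `reaction_volume / supernatant_volume` to express it per
#' volume of culture supernatant assayed.
#'
#' @param fit a `linear_fit` or a non-negative numeric slope (AU/min).
#' @param spec an [activity_spec()].
#' @param per_supernatant rescale to the supernatant basis? Default `FALSE`
#'   (per reaction well).
#' @return Activity in umol oxidized ABTS / min.
#' @export
activity_from_slope <- function(fit, spec = activity_spec(),
                                per_supernatant = FALSE) {
  slope <- if (inherits(fit, "linear_fit")) fit$slope else fit
  stopifnot(is.numeric(slope), inherits(spec, "activity_spec"))
  if (any(slope < 0)) stop("negative slope: oxidized ABTS cannot decrease")
  act <- slope / (spec$epsilon * spec$path_length) * spec$reaction_volume * 1e6
  if (per_supernatant) act <- act * spec$reaction_volume / spec$supernatant_volume
  act
}

#' Normalize activities to OD600 and compute fold change vs a reference
#'
#' Per replicate, `normalized_activity = activity / od600` (controlling for
#' culture cell density); per strain, `fold_change` is the strain's mean
#' normalized activity divided by the reference strain's mean normalized
#' activity within the same `group` (e.g. assay plate), averaging across
#' replicates.
#'
#' @param results data frame with columns `strain_id`, `replicate`,
#'   `activity` and either an `od600` column or one joined from `od600`.
#' @param od600 optional data frame with columns `strain_id`, `replicate`,
#'   `od600` to merge in.
#' @param reference_strain strain id of the reference.
#' @param group optional column name grouping strains assayed together with
#'   their own reference (default: one group).
#' @return `results` with `normalized_activity` and per-strain `fold_change`
#'   columns.
#' @export
normalize_and_fold <- function(results, od600 = NULL, reference_strain,
                               group = NULL) {
  stopifnot(is.data.frame(results),
            all(c("strain_id", "replicate", "activity") %in% names(results)))
  if (!is.null(od600)) {
    results$od600 <- NULL
    results <- merge(results, od600[c("strain_id", "replicate", "od600")],
                     by = c("strain_id", "replicate"), all.x = TRUE, sort = FALSE)
  }
  if (!"od600" %in% names(results) || any(is.na(results$od600))) {
    stop("missing OD600 value(s)")
  }
  if (any(results$od600 <= 0)) stop("OD600 values must be positive")
  if (!reference_strain %in% results$strain_id) {
    stop("reference strain '", reference_strain, "' not present")
  }
  results$normalized_activity <- results$activity / results$od600
  grp <- if (is.null(group)) rep("all", nrow(results)) else results[[group]]
  results$fold_change <- NA_real_
  for (g in unique(grp)) {
    in_g <- grp == g
    ref <- in_g & results$strain_id == reference_strain
    if (!any(ref)) stop("reference strain missing from group '", g, "'")
    ref_mean <- mean(results$normalized_activity[ref])
    if (ref_mean == 0) stop("reference mean normalized activity is zero")
    strain_means <- tapply(results$normalized_activity[in_g],
                           results$strain_id[in_g], mean)
    results$fold_change[in_g] <-
      unname(strain_means[results$strain_id[in_g]] / ref_mean)
  }
  results
}

#' Significance stars at the 0.05 / 0.01 / 0.005 cutpoints
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return Character vector: `"***"` for p < 0.005, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# Run `expr` with a locally fixed RNG seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One-way ANOVA with Dunnett's many-to-one comparison vs a reference
#'
#' Fits a one-way ANOVA across strains and compares every strain against the
#' reference with Dunnett's single-step adjustment (multivariate-t, via
#' multcomp). The quasi-Monte-Carlo integration of the multivariate t is run
#' under a fixed local seed so results are reproducible.
#'
#' @param data data frame with columns `strain_id` and `value` (e.g.
#'   normalized activity), >= 2 replicates per strain.
#' @param reference_strain the reference level.
#' @param seed seed for the multivariate-t integration (default 1).
#' @param maxpts,abseps integration controls for the multivariate-t
#'   probability; the defaults target an absolute error of 1e-3, which is
#'   ample for significance calls at 0.05/0.01/0.005 even with dozens of
#'   comparisons.
#' @return Data frame with one row per non-reference strain: `strain_id`,
#'   `estimate` (difference of means vs reference), `t`, `p_adj`, `stars`.
#' @export
anova_dunnett <- function(data, reference_strain, seed = 1L,
                          maxpts = 100000L, abseps = 0.001) {
  stopifnot(is.data.frame(data),
            all(c("strain_id", "value") %in% names(data)))
  if (!reference_strain %in% data$strain_id) {
    stop("reference strain '", reference_strain, "' not present")
  }
  counts <- table(data$strain_id)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) stop("every strain needs at least 2 replicates")
  if (all(tapply(data$value, data$strain_id, stats::sd) == 0)) {
    stop("zero within-group variance everywhere; ANOVA undefined")
  }
  data$strain_id <- stats::relevel(factor(data$strain_id), reference_strain)
  fit <- stats::aov(value ~ strain_id, data = data)
  cmp <- multcomp::glht(fit, linfct = multcomp::mcp(strain_id = "Dunnett"))
  smry <- with_fixed_seed(seed, summary(cmp, test = multcomp::adjusted(
    "single-step", maxpts = maxpts, abseps = abseps)))
  out <- data.frame(
    strain_id = sub("^(.*) - .*$", "\\1", names(smry$test$coefficients)),
    estimate = unname(smry$test$coefficients),
    t = unname(smry$test$tstat),
    p_adj = pmin(pmax(as.numeric(smry$test$pvalues), 0), 1),
    stringsAsFactors = FALSE
  )
  out$stars <- significance_stars(out$p_adj)
  out
}

#' One-way ANOVA with Tukey's all-pairs comparison
#'
#' Fits a one-way ANOVA across strains and performs Tukey's honest
#' significant difference test for all pairwise comparisons (studentized
#' range distribution; deterministic).
#'
#' @param data data frame with columns `strain_id` and `value`, >= 2
#'   replicates per strain.
#' @return Data frame with one row per strain pair: `strain_a`, `strain_b`,
#'   `estimate` (mean difference a - b), `p_adj`, `stars`.
#' @export
anova_tukey <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("strain_id", "value") %in% names(data)))
  counts <- table(data$strain_id)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) stop("every strain needs at least 2 replicates")
  if (all(tapply(data$value, data$strain_id, stats::sd) == 0)) {
    stop("zero within-group variance everywhere; ANOVA undefined")
  }
  data$strain_id <- factor(data$strain_id)
  fit <- stats::aov(value ~ strain_id, data = data)
  tk <- stats::TukeyHSD(fit)$strain_id
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    strain_a = vapply(pair, `[`, character(1), 1L),
    strain_b = vapply(pair, `[`, character(1), 2L),
    estimate = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_target - Ct_refgene)_sample - (Ct_target - Ct_refgene)_calibrator`.
#' Vectorized over samples.
#'
#' @param ct_target,ct_refgene Ct of the target and reference gene in the
#'   sample(s).
#' @param calibrator_target,calibrator_refgene Ct of the target and reference
#'   gene in the calibrator.
#' @return Relative expression (fold change vs calibrator).
#' @export
delta_delta_ct <- function(ct_target, ct_refgene,
                           calibrator_target, calibrator_refgene) {
  vals <- c(ct_target, ct_refgene, calibrator_target, calibrator_refgene)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target - ct_refgene) - (calibrator_target - calibrator_refgene)
  2^(-ddct)
}
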