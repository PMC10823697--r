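# Self-contained simulation studies: generate a synthetic data set with known
# ground truth, run the full pipeline on it, and measure recovery. These are
# the package's reference experiments; they also back the acceptance script.

# Deterministic stage sub-seed from a top-level seed, kept inside the 32-bit
# integer range set.seed() requires.
sub_seed <- function(seed, mult, k) {
  as.integer((as.numeric(seed) * mult + k) %% 2147483629)
}

#' Screen-recovery study: can planted positives be re-identified?
#'
#' Simulates a multi-plate, multi-replicate overlay screen with a handful of
#' planted positive strains per plate, runs the complete image-to-hits
#' pipeline (background estimation from blanks, inversion, subtraction, site
#' measurement, normalization, zone correction, modified Z, replicate hit
#' calling) and compares the hit table against the planted truth.
#'
#' Replicates share the layout but have independent per-site biological noise
#' and imaging noise; sub-seeds are derived deterministically from `seed`.
#'
#' @param n_plates number of plates (default 4).
#' @param n_replicates replicates per plate (default 3).
#' @param n_positives_per_plate planted positive strains per plate (default 6).
#' @param effect multiplicative planted effect (default 3).
#' @param n_rows,n_cols grid dimensions (default 16 x 24).
#' @param config a [simulation_config()]; default uses a base signal low
#'   enough that a 3x effect under the edge artifact stays unclipped.
#' @param n_blanks blank plates for the background function (default 6).
#' @param z_threshold,min_replicates hit-calling parameters.
#' @param seed top-level seed; all sub-seeds derive from it.
#' @return List: `sensitivity`, `false_positives`, `n_true`, `n_null`,
#'   `hits` (the full hit table), `planted` (strain ids).
#' @export
simulate_screen_study <- function(n_plates = 4L, n_replicates = 3L,
                                  n_positives_per_plate = 6L, effect = 3.0,
                                  n_rows = 16L, n_cols = 24L,
                                  config = simulation_config(base_signal = 0.15),
                                  n_blanks = 6L,
                                  z_threshold = 2.5, min_replicates = 2L,
                                  seed = 1L) {
  set.seed(seed)
  planted_all <- character(0)
  layouts <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    ids <- outer(seq_len(n_rows) - 1L, seq_len(n_cols) - 1L,
                 function(r, c) sprintf("p%d_s%d.%d", p, r, c))
    pick <- sample(n_rows * n_cols, n_positives_per_plate)
    eff <- stats::setNames(rep(effect, n_positives_per_plate), ids[pick])
    layouts[[p]] <- plate_layout(n_rows, n_cols, strain_ids = ids,
                                 planted_effects = eff)
    planted_all <- c(planted_all, names(eff))
  }

  blanks <- lapply(seq_len(n_blanks), function(i) {
    preprocess_image(simulate_blank_plate(config, seed = sub_seed(seed, 1009, i)))
  })
  fld <- estimate_background(blanks)
  grid <- derive_grid(layouts[[1]], config)

  site_list <- list()
  for (p in seq_len(n_plates)) {
    for (r in seq_len(n_replicates)) {
      sim <- simulate_plate_image(layouts[[p]], config,
                                  seed = sub_seed(seed, 1013, p * 31L + r),
                                  plate_id = paste0("plate", p), replicate = r)
      inv <- preprocess_image(sim$image)
      sub <- subtract_background(inv, fld)
      site_list[[length(site_list) + 1L]] <-
        measure_sites(sub, grid, layouts[[p]])
    }
  }
  sites <- do.call(rbind, site_list)
  attr(sites, "n_rows") <- n_rows; attr(sites, "n_cols") <- n_cols
  res <- score_screen(sites, n_rows, n_cols, z_threshold = z_threshold,
                      min_replicates = min_replicates)

  called_pos <- res$hits$strain_id[res$hits$call == "positive"]
  n_true <- length(planted_all)
  tp <- sum(planted_all %in% called_pos)
  fp <- sum(!(called_pos %in% planted_all))
  list(sensitivity = tp / n_true,
       false_positives = fp,
       n_true = n_true,
       n_null = nrow(res$hits) - n_true,
       hits = res$hits,
       planted = planted_all)
}

#' Fold-change recovery study over repeated simulated activity assays
#'
#' Repeatedly simulates a replicated activity study with the given planted
#' fold effects, runs OD normalization and fold-change estimation, and
#' averages the estimated folds over the repetitions.
#'
#' @param effects named numeric vector of planted folds.
#' @param cv coefficient of variation of replicate activities.
#' @param n_replicates replicates per strain.
#' @param n_seeds number of independent simulated studies.
#' @param seed top-level seed.
#' @return List: `mean_folds` (named, averaged over studies), `all_folds`
#'   (matrix `n_seeds` x strains).
#' @export
fold_recovery_study <- function(effects = c(ski3 = 5.3, arv1 = 5.0, pmt2 = 4.3),
                                cv = 0.1, n_replicates = 3L, n_seeds = 100L,
                                seed = 1L) {
  folds <- matrix(NA_real_, n_seeds, length(effects),
                  dimnames = list(NULL, names(effects)))
  for (i in seq_len(n_seeds)) {
    d <- simulate_activity_study(effects = effects, cv = cv,
                                 n_replicates = n_replicates,
                                 seed = sub_seed(seed, 1019, i))
    nf <- normalize_and_fold(d, reference_strain = "reference")
    first <- !duplicated(nf$strain_id)
    f <- stats::setNames(nf$fold_change[first], nf$strain_id[first])
    folds[i, ] <- f[names(effects)]
  }
  list(mean_folds = colMeans(folds), all_folds = folds)
}

#' Synthetic liquid-assay validation study (stand-in data)
#'
#' A synthetic stand-in for a liquid validation of overlay-screen positives:
#' 66 candidate strains are assayed against a reference in triplicate, 17 of
#' them carrying real effects above twofold (including planted folds 5.3,
#' 5.0 and 4.3) and the remainder drawn near fold 1. The OD-normalization,
#' fold-change and Dunnett stages are then run end to end. All data are
#' simulated; no measured study is loaded.
#'
#' @param n_candidates number of candidate strains (default 66).
#' @param n_real number of strains with real effects (default 17).
#' @param named_effects named folds always included among the real effects.
#' @param cv replicate coefficient of variation.
#' @param n_replicates replicates per strain.
#' @param seed top-level seed.
#' @return List: `stats` (per-strain fold, Dunnett-adjusted p, stars),
#'   `n_significant_positive` (adjusted p < 0.05 and fold > 1),
#'   `named_folds` (estimated folds of the named strains),
#'   `true_effects` (the planted truth).
#' @export
liquid_validation_study <- function(n_candidates = 66L, n_real = 17L,
                                    named_effects = c(ski3 = 5.3, arv1 = 5.0,
                                                      pmt2 = 4.3),
                                    cv = 0.1, n_replicates = 3L, seed = 1L) {
  stopifnot(n_real >= length(named_effects), n_candidates >= n_real)
  set.seed(seed)
  n_other_real <- n_real - length(named_effects)
  other_real <- stats::setNames(
    stats::runif(n_other_real, 2.2, 3.5),
    sprintf("hit%02d", seq_len(n_other_real)))
  n_null <- n_candidates - n_real
  nulls <- stats::setNames(stats::runif(n_null, 0.9, 1.1),
                           sprintf("cand%02d", seq_len(n_null)))
  effects <- c(named_effects, other_real, nulls)

  d <- simulate_activity_study(effects = effects, cv = cv,
                               n_replicates = n_replicates,
                               seed = sub_seed(seed, 1021, 1L))
  nf <- normalize_and_fold(d, reference_strain = "reference")
  dn <- anova_dunnett(data.frame(strain_id = nf$strain_id,
                                 value = nf$normalized_activity),
                      reference_strain = "reference", seed = seed)
  first <- !duplicated(nf$strain_id)
  folds <- stats::setNames(nf$fold_change[first], nf$strain_id[first])
  dn$fold_change <- unname(folds[dn$strain_id])
  n_sig <- sum(dn$p_adj < 0.05 & dn$fold_change > 1)
  list(stats = dn,
       n_significant_positive = n_sig,
       named_folds = folds[names(named_effects)],
       true_effects = effects)
}
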