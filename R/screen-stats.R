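#' Normalize site intensities to the plate median
#'
#' Each site's mean intensity is divided by the median of the mean intensities
#' over flag-1 (normal growth) sites of the plate, so the flag-1 median of the
#' normalized values is exactly 1. Flag-0 sites are excluded from the median
#' but still receive a normalized value. The median of an even count is the
#' mean of the two central order statistics.
#'
#' @param sites data frame with columns `mean_intensity` and `growth_flag`
#'   (one plate, one replicate).
#' @return `sites` with a `normalized` column added; the plate median is
#'   attached as attribute `"plate_median"`.
#' @export
normalize_to_plate_median <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("mean_intensity", "growth_flag") %in% names(sites)))
  ok <- sites$growth_flag == 1L
  if (!any(ok)) stop("all sites are flagged 0; cannot compute a plate median")
  med <- stats::median(sites$mean_intensity[ok])
  if (!is.finite(med) || med <= 0) stop("plate median is zero or undefined")
  sites$normalized <- sites$mean_intensity / med
  attr(sites, "plate_median") <- med
  sites
}

#' Assign concentric-rectangle zone indices
#'
#' Zones are concentric rectangular rings starting at the plate periphery:
#' zone 1 is the outermost ring, indices increase toward the center. With
#' `zone_width = 1` each ring of sites is its own zone; a 16 x 24 grid yields
#' 8 zones.
#'
#' @param n_rows,n_cols grid dimensions (at least 2 x 2).
#' @param zone_width ring thickness in sites.
#' @return Integer matrix `n_rows x n_cols` of zone indices (>= 1).
#' @export
assign_zones <- function(n_rows, n_cols, zone_width = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, zone_width >= 1L)
  r <- matrix(rep(seq_len(n_rows) - 1L, times = n_cols), nrow = n_rows)
  cc <- matrix(rep(seq_len(n_cols) - 1L, each = n_rows), nrow = n_rows)
  ring <- pmin(r, cc, n_rows - 1L - r, n_cols - 1L - cc)
  matrix(as.integer(1L + ring %/% zone_width), n_rows, n_cols)
}

#' Correct edge zones whose median exceeds the plate median
#'
#' The spatial correction for the signal inflation at peripheral sites: the
#' grid is divided into concentric rectangular zones; any zone whose flag-1
#' median of normalized values is above 1.0 (the plate median by definition)
#' has *all* of its values divided by that zone median. Zones at or below 1.0
#' are left unchanged (strict inequality), so the correction never increases
#' a value and is idempotent. A zone with no flag-1 sites is left unchanged
#' with a warning.
#'
#' @param sites data frame with columns `row`, `col`, `normalized`,
#'   `growth_flag` (one plate, one replicate).
#' @param n_rows,n_cols grid dimensions; default taken from attributes set by
#'   [measure_sites()].
#' @param zone_width ring thickness in sites (default 1).
#' @return `sites` with `zone_index` and `zone_corrected` columns added.
#' @export
zone_correct <- function(sites, n_rows = attr(sites, "n_rows"),
                         n_cols = attr(sites, "n_cols"), zone_width = 1L) {
  stopifnot(is.data.frame(sites),
            all(c("row", "col", "normalized", "growth_flag") %in% names(sites)))
  if (is.null(n_rows) || is.null(n_cols)) {
    stop("grid dimensions unknown; pass `n_rows` and `n_cols`")
  }
  zones <- assign_zones(n_rows, n_cols, zone_width)
  sites$zone_index <- zones[cbind(sites$row + 1L, sites$col + 1L)]
  sites$zone_corrected <- sites$normalized
  for (z in sort(unique(sites$zone_index))) {
    in_zone <- sites$zone_index == z
    ok <- in_zone & sites$growth_flag == 1L
    if (!any(ok)) {
      warning("zone ", z, " has no flag-1 sites; left uncorrected")
      next
    }
    zmed <- stats::median(sites$zone_corrected[ok])
    if (zmed > 1.0) {
      sites$zone_corrected[in_zone] <- sites$zone_corrected[in_zone] / zmed
    }
  }
  sites
}

#' Robust modified Z-scores from the median absolute deviation
#'
#' Computes `z = (x - median) / MAD` with
#' `MAD = 1.4826 * median(|x - median|)`, where the median and MAD are taken
#' over flag-1 values only; a score is reported for every value (including
#' flag-0 sites). The factor 1.4826 makes the MAD consistent with the
#' standard deviation under normality.
#'
#' @param values numeric vector (e.g. zone-corrected normalized intensities
#'   of one plate).
#' @param flags optional 0/1 vector; flag-0 values are excluded from the
#'   median and MAD. Default: all flag 1.
#' @return Numeric vector of modified Z-scores, same length as `values`.
#' @export
modified_zscore <- function(values, flags = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(flags)) flags <- rep(1L, length(values))
  if (length(flags) != length(values)) stop("`flags` length mismatch")
  ok <- flags == 1L
  if (sum(ok) < 2L) stop("need at least 2 flag-1 values")
  med <- stats::median(values[ok])
  mad_ <- 1.4826 * stats::median(abs(values[ok] - med))
  if (mad_ == 0) stop("MAD is zero (degenerate plate); cannot score")
  (values - med) / mad_
}

#' Score one plate: normalize, zone-correct, modified Z
#'
#' @param sites data frame from [measure_sites()] (one plate, one replicate),
#'   after [apply_growth_flags()].
#' @inheritParams zone_correct
#' @return `sites` with `normalized`, `zone_index`, `zone_corrected` and
#'   `modified_z` columns.
#' @export
score_plate <- function(sites, n_rows = attr(sites, "n_rows"),
                        n_cols = attr(sites, "n_cols"), zone_width = 1L) {
  sites <- normalize_to_plate_median(sites)
  sites <- zone_correct(sites, n_rows, n_cols, zone_width)
  sites$modified_z <- modified_zscore(sites$zone_corrected, sites$growth_flag)
  sites
}

#' Call replicate-supported hits from per-strain modified Z-scores
#'
#' A strain is a positive hit when at least `min_replicates` replicates have
#' `z >= z_threshold`; a negative hit, symmetrically, when at least
#' `min_replicates` replicates have `z <= -z_threshold`. A strain meeting
#' both (inconsistent replicates) is called `none` with a warning. Flag-0
#' sites and sites without a strain id are excluded.
#'
#' @param scores data frame with columns `strain_id`, `replicate`,
#'   `modified_z` and optionally `growth_flag`.
#' @param z_threshold modified Z-score threshold (default 2.5).
#' @param min_replicates replicates required to support a call (default 2).
#' @return A `hit table`: data frame with one row per strain — replicate
#'   scores `z1..zK`, `mean_z`, counts of qualifying replicates, and `call`
#'   in `{positive, negative, none}` — ordered by decreasing `mean_z`.
#' @export
call_hits <- function(scores, z_threshold = 2.5, min_replicates = 2L) {
  stopifnot(is.data.frame(scores),
            all(c("strain_id", "replicate", "modified_z") %in% names(scores)))
  if (!nrow(scores)) stop("no scores to call hits from")
  keep <- !is.na(scores$strain_id)
  if ("growth_flag" %in% names(scores)) keep <- keep & scores$growth_flag == 1L
  scores <- scores[keep, , drop = FALSE]
  if (!nrow(scores)) stop("no flag-1 scored sites with strain ids")

  reps <- sort(unique(scores$replicate))
  split_z <- split(scores[c("replicate", "modified_z")], scores$strain_id)
  rows <- lapply(names(split_z), function(s) {
    d <- split_z[[s]]
    z <- d$modified_z[match(reps, d$replicate)]
    zz <- z[!is.na(z)]
    n_above <- sum(zz >= z_threshold)
    n_below <- sum(zz <= -z_threshold)
    call <- "none"
    if (n_above >= min_replicates && n_below >= min_replicates) {
      warning("strain ", s, " qualifies as both positive and negative; ",
              "calling none")
    } else if (n_above >= min_replicates) {
      call <- "positive"
    } else if (n_below >= min_replicates) {
      call <- "negative"
    }
    out <- data.frame(strain_id = s, stringsAsFactors = FALSE)
    for (i in seq_along(reps)) out[[paste0("z", i)]] <- z[i]
    out$mean_z <- mean(zz)
    out$n_replicates <- length(zz)
    out$n_above <- n_above
    out$n_below <- n_below
    out$call <- call
    out
  })
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$mean_z), ]
  rownames(hits) <- NULL
  hits
}

#' Score a whole screen and call hits across replicates
#'
#' Runs [score_plate()] independently on every (plate, replicate) group —
#' inter-plate comparability comes solely from per-plate normalization — and
#' calls hits per strain across replicates.
#'
#' @param sites data frame of measured sites for all plates and replicates
#'   (columns as produced by [measure_sites()]).
#' @param n_rows,n_cols grid dimensions.
#' @inheritParams call_hits
#' @param zone_width ring thickness in sites.
#' @return List with `scores` (per-site data frame with score columns) and
#'   `hits` (per-strain hit table).
#' @export
score_screen <- function(sites, n_rows = attr(sites, "n_rows"),
                         n_cols = attr(sites, "n_cols"), zone_width = 1L,
                         z_threshold = 2.5, min_replicates = 2L) {
  stopifnot(is.data.frame(sites))
  grp <- interaction(sites$plate_id, sites$replicate, drop = TRUE)
  scored <- lapply(split(sites, grp), score_plate,
                   n_rows = n_rows, n_cols = n_cols, zone_width = zone_width)
  scores <- do.call(rbind, scored)
  rownames(scores) <- NULL
  hits <- call_hits(scores, z_threshold = z_threshold,
                    min_replicates = min_replicates)
  list(scores = scores, hits = hits)
}
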