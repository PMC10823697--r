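#' Read a plate layout from CSV
#'
#' Expected columns: `row`, `col` (1-based in the file), `strain_id`; empty
#' or missing strain ids mark empty positions. An optional `reference`
#' column (0/1) marks reference-strain positions.
#'
#' @param path CSV file path.
#' @param n_rows,n_cols grid dimensions.
#' @return A [plate_layout()].
#' @export
read_layout_csv <- function(path, n_rows = 16L, n_cols = 24L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "strain_id") %in% names(d))) {
    stop("layout CSV needs columns row, col, strain_id")
  }
  ids <- matrix(NA_character_, n_rows, n_cols)
  ids[cbind(d$row, d$col)] <- d$strain_id
  empty <- which(is.na(ids) | !nzchar(ids), arr.ind = TRUE) - 1L
  ids[is.na(ids) | !nzchar(ids)] <- ""
  ref <- NULL
  if ("reference" %in% names(d)) {
    rr <- d[d$reference == 1, c("row", "col")]
    if (nrow(rr)) ref <- as.matrix(rr) - 1L
  }
  plate_layout(n_rows, n_cols, strain_ids = ids,
               reference_positions = ref,
               empty_positions = if (nrow(empty)) empty else NULL)
}

#' Read manual growth flags from CSV
#'
#' Expected columns: `row`, `col` (1-based in the file), `growth_flag` in
#' `{0, 1}`; optional `plate_id`, `replicate`. Converted to the package's
#' 0-based grid indices.
#'
#' @param path CSV file path.
#' @return Data frame usable with [apply_growth_flags()].
#' @export
read_growth_flags <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "growth_flag") %in% names(d))) {
    stop("flags CSV needs columns row, col, growth_flag")
  }
  d$row <- as.integer(d$row) - 1L
  d$col <- as.integer(d$col) - 1L
  d
}

#' Read kinetic traces from long-format CSV
#'
#' Expected columns: `well`, `strain_id` (or `strain`), `time_min`, `a420`.
#'
#' @param path CSV file path.
#' @return Named list of [kinetic_trace()] objects, one per well.
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("strain" %in% names(d) && !"strain_id" %in% names(d)) {
    d$strain_id <- d$strain
  }
  if (!all(c("well", "strain_id", "time_min", "a420") %in% names(d))) {
    stop("traces CSV needs columns well, strain_id (or strain), time_min, a420")
  }
  wells <- split(d, d$well)
  lapply(wells, function(w) {
    w <- w[order(w$time_min), ]
    kinetic_trace(w$time_min, w$a420, well_id = w$well[1],
                  strain_id = w$strain_id[1])
  })
}

#' Read an OD600-normalized activity table (e.g. a published supplement)
#'
#' Accepts a CSV with columns `strain_id`, `replicate`, and either
#' `normalized_activity` or both `activity` and `od600`.
#'
#' @param path CSV file path.
#' @return Data frame with a `normalized_activity` column.
#' @export
read_activity_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("strain_id", "replicate") %in% names(d))) {
    stop("activity table needs columns strain_id, replicate")
  }
  if (!"normalized_activity" %in% names(d)) {
    if (!all(c("activity", "od600") %in% names(d))) {
      stop("activity table needs normalized_activity, or activity and od600")
    }
    d$normalized_activity <- d$activity / d$od600
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stable hash of a configuration (md5 of its deparsed form) for provenance.
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full overlay-screen pipeline: images to hit table
#'
#' For every plate image: read (or take in memory), invert, subtract the
#' background illumination function estimated from the blank plates, measure
#' per-site mean intensities on the grid, apply manual growth flags; then
#' normalize each plate to its median, zone-correct, compute modified
#' Z-scores, and call replicate-supported hits. Per-plate QC (plate median,
#' flagged-site count, zone medians before/after correction) and provenance
#' (config hash, package version) are reported, and all tables are written
#' to `out_dir` when given.
#'
#' @param config named list with elements:
#'   * `images`: data frame with columns `path` (or `image`: in-memory
#'     `plate_image`), `plate_id`, `replicate`;
#'   * `blanks`: character vector of blank image paths, or list of
#'     `plate_image`s;
#'   * `layout`: a [plate_layout()] or CSV path;
#'   * `grid`: a [grid_spec()];
#'   * optional `flags` (data frame or CSV path), `block_size` (5),
#'     `filter_radius` (7), `zone_width` (1), `z_threshold` (2.5),
#'     `min_replicates` (2), `out_dir`.
#' @return A `screen_report`: list with `sites`, `scores`, `hits`, `qc`,
#'   `config_hash`, `version`.
#' @export
run_screen <- function(config) {
  stopifnot(is.list(config))
  for (f in c("images", "blanks", "layout", "grid")) {
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  }
  block_size <- config$block_size %||% 5L
  filter_radius <- config$filter_radius %||% 7L
  zone_width <- config$zone_width %||% 1L
  z_threshold <- config$z_threshold %||% 2.5
  min_replicates <- config$min_replicates %||% 2L

  layout <- config$layout
  if (is.character(layout)) layout <- read_layout_csv(layout)
  grid <- config$grid
  flags <- config$flags
  if (is.character(flags)) flags <- read_growth_flags(flags)

  blanks <- config$blanks
  if (is.character(blanks)) {
    missing <- blanks[!file.exists(blanks)]
    if (length(missing)) {
      stop("blank image file(s) not found: ", paste(missing, collapse = ", "))
    }
    blanks <- lapply(blanks, read_plate_image)
  }
  if (!length(blanks)) stop("no blank images provided")
  blanks <- lapply(blanks, function(b) {
    if (b$stage == "raw") preprocess_image(b) else b
  })
  field <- estimate_background(blanks, block_size, filter_radius)

  images <- config$images
  site_list <- vector("list", nrow(images))
  for (i in seq_len(nrow(images))) {
    img <- if ("image" %in% names(images)) {
      images$image[[i]]
    } else {
      read_plate_image(images$path[i], plate_id = images$plate_id[i],
                       replicate = images$replicate[i])
    }
    img$plate_id <- as.character(images$plate_id[i])
    img$replicate <- as.integer(images$replicate[i])
    step <- tryCatch({
      inv <- if (img$stage == "raw") preprocess_image(img) else img
      sub <- subtract_background(inv, field)
      st <- measure_sites(sub, grid, layout)
      if (!is.null(flags)) st <- apply_growth_flags(st, flags)
      st
    }, error = function(e) {
      stop("plate ", images$plate_id[i], " replicate ", images$replicate[i],
           ": ", conditionMessage(e), call. = FALSE)
    })
    site_list[[i]] <- step
  }
  sites <- do.call(rbind, site_list)
  attr(sites, "n_rows") <- grid$n_rows
  attr(sites, "n_cols") <- grid$n_cols

  res <- score_screen(sites, n_rows = grid$n_rows, n_cols = grid$n_cols,
                      zone_width = zone_width, z_threshold = z_threshold,
                      min_replicates = min_replicates)

  grp <- interaction(res$scores$plate_id, res$scores$replicate, drop = TRUE)
  qc <- do.call(rbind, lapply(split(res$scores, grp), function(s) {
    ok <- s$growth_flag == 1L
    zones <- sort(unique(s$zone_index))
    zmed_before <- vapply(zones, function(z)
      stats::median(s$normalized[ok & s$zone_index == z]), numeric(1))
    zmed_after <- vapply(zones, function(z)
      stats::median(s$zone_corrected[ok & s$zone_index == z]), numeric(1))
    data.frame(plate_id = s$plate_id[1], replicate = s$replicate[1],
               median_raw = stats::median(s$mean_intensity[ok]),
               n_flagged = sum(!ok), zone = zones,
               zone_median_before = zmed_before,
               zone_median_after = zmed_after,
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL

  report <- structure(
    list(sites = sites, scores = res$scores, hits = res$hits, qc = qc,
         config_hash = config_hash(config[setdiff(names(config), "images")]),
         version = as.character(utils::packageVersion("abtsscreen"))),
    class = "screen_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res$scores, file.path(config$out_dir, "scores.tsv"))
    write_tsv(res$hits, file.path(config$out_dir, "hits.tsv"))
    write_tsv(qc, file.path(config$out_dir, "qc.tsv"))
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  np <- sum(x$hits$call == "positive"); nn <- sum(x$hits$call == "negative")
  cat(sprintf(
    "<screen_report> %d strains scored; %d positive, %d negative hits (v%s, config %s)\n",
    nrow(x$hits), np, nn, x$version, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Run the liquid ABTS assay pipeline: traces to comparison statistics
#'
#' Fits the linear range of every trace, converts slopes to activity
#' (Beer-Lambert), normalizes to OD600, computes fold changes versus the
#' reference strain, and compares strains to the reference by one-way ANOVA
#' with Dunnett's correction.
#'
#' @param config named list with elements:
#'   * `traces`: list of `kinetic_trace`s or a long CSV path;
#'   * `od600`: data frame (`strain_id`, `replicate`, `od600`) or CSV path;
#'   * `reference_strain`;
#'   * optional `r_min` (0.999), `min_points` (5), `activity_spec`
#'     ([activity_spec()]), `per_supernatant` (FALSE), `seed` (1),
#'     `out_dir`.
#' @return List with `fits`, `results` (per-replicate activity table) and
#'   `stats` (per-strain mean, sd, fold change, Dunnett-adjusted p, stars).
#' @export
run_liquid <- function(config) {
  stopifnot(is.list(config))
  for (f in c("traces", "od600", "reference_strain")) {
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  }
  r_min <- config$r_min %||% 0.999
  min_points <- config$min_points %||% 5L
  aspec <- config$activity_spec %||% activity_spec()
  per_sup <- isTRUE(config$per_supernatant)
  seed <- config$seed %||% 1L

  traces <- config$traces
  if (is.character(traces)) traces <- read_traces_csv(traces)
  od <- config$od600
  if (is.character(od)) od <- utils::read.csv(od, stringsAsFactors = FALSE)

  fits <- lapply(traces, fit_linear_range, r_min = r_min,
                 min_points = min_points)
  results <- do.call(rbind, lapply(fits, function(f) {
    data.frame(well = f$trace$well_id, strain_id = f$trace$strain_id,
               slope = f$slope, r = f$r, n_used = f$n_used,
               activity = activity_from_slope(f, aspec, per_sup),
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  # replicate index: order of appearance of wells within each strain
  results$replicate <- stats::ave(seq_len(nrow(results)), results$strain_id,
                                  FUN = seq_along)
  results <- normalize_and_fold(results, od600 = od,
                                reference_strain = config$reference_strain)

  dn <- anova_dunnett(
    data.frame(strain_id = results$strain_id,
               value = results$normalized_activity),
    reference_strain = config$reference_strain, seed = seed)
  agg <- do.call(rbind, lapply(split(results, results$strain_id), function(s) {
    data.frame(strain_id = s$strain_id[1],
               mean_normalized = mean(s$normalized_activity),
               sd_normalized = stats::sd(s$normalized_activity),
               fold_change = s$fold_change[1], stringsAsFactors = FALSE)
  }))
  stats_tbl <- merge(agg, dn[c("strain_id", "p_adj", "stars")],
                     by = "strain_id", all.x = TRUE, sort = FALSE)
  stats_tbl <- stats_tbl[order(-stats_tbl$mean_normalized), ]
  rownames(stats_tbl) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(results, file.path(config$out_dir, "activity.tsv"))
    write_tsv(stats_tbl, file.path(config$out_dir, "stats.tsv"))
  }
  list(fits = fits, results = results, stats = stats_tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
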