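#' Invert a raw plate image for densitometry
#'
#' Colorimetric product darkens the membrane, so the photographed image has
#' low pixel values where activity is high. Inversion (`1 - intensity`) makes
#' signal positive for quantification. RGB input is converted to grayscale
#' first (see [read_plate_image()]).
#'
#' @param raw a `plate_image` at stage `"raw"`.
#' @return A `plate_image` at stage `"inverted"`.
#' @export
preprocess_image <- function(raw) {
  stopifnot(inherits(raw, "plate_image"))
  if (raw$stage != "raw") stop("`preprocess_image` expects a raw-stage image")
  px <- raw$pixels
  if (any(px > 1)) stop("raw intensities must be normalized to [0, 1]")
  plate_image(1 - px, raw$plate_id, raw$replicate, stage = "inverted")
}

#' Background illumination field
#'
#' @param pixels numeric matrix, non-negative.
#' @param block_size block edge (pixels) used for the minimum filter.
#' @param filter_radius radius (pixels) of the median smoothing filter.
#' @return An object of class `background_field`.
#' @export
background_field <- function(pixels, block_size = 5L, filter_radius = 7L) {
  if (!is.matrix(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("background field pixels must be a finite non-negative matrix")
  }
  structure(list(pixels = pixels, block_size = as.integer(block_size),
                 filter_radius = as.integer(filter_radius)),
            class = "background_field")
}

#' @export
print.background_field <- function(x, ...) {
  cat(sprintf("<background_field> %d x %d px, block %d, median radius %d\n",
              nrow(x$pixels), ncol(x$pixels), x$block_size, x$filter_radius))
  invisible(x)
}

# Per-block minimum of a matrix; edge blocks may be smaller than block_size.
block_minimum <- function(px, block_size) {
  bi <- (seq_len(nrow(px)) - 1L) %/% block_size
  bj <- (seq_len(ncol(px)) - 1L) %/% block_size
  mins <- tapply(as.vector(px),
                 list(row = bi[row(px)], col = bj[col(px)]), min)
  # tapply returns a matrix ordered by block indices
  list(mins = mins, bi = bi, bj = bj)
}

#' Estimate the background illumination function from blank plates
#'
#' Mirrors the blank-plate procedure: for each inverted blank image the
#' minimum pixel intensity is taken over non-overlapping `block_size` x
#' `block_size` sections (edge blocks may be truncated); block minima are
#' combined across the blank set by elementwise minimum; the block field is
#' upsampled to pixel resolution (each pixel takes its block's value); and a
#' square median smoothing filter of the given radius removes bright or dim
#' imaging artifacts. The median filter operates on the 16-bit intensity
#' scale, matching the image bit depth, so values are reproduced to within
#' 1/65535.
#'
#' @param blanks list of `plate_image`s at stage `"inverted"`, all the same
#'   size.
#' @param block_size block edge in pixels (default 5).
#' @param filter_radius median filter radius in pixels (default 7).
#' @return A [background_field()].
#' @export
estimate_background <- function(blanks, block_size = 5L, filter_radius = 7L) {
  if (inherits(blanks, "plate_image")) blanks <- list(blanks)
  if (!length(blanks)) stop("need at least one blank image")
  if (!all(vapply(blanks, inherits, logical(1), "plate_image"))) {
    stop("`blanks` must be plate_image objects")
  }
  stages <- vapply(blanks, function(b) b$stage, character(1))
  if (any(stages != "inverted")) stop("blank images must be at stage 'inverted'")
  dims <- vapply(blanks, function(b) dim(b$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("blank images have mismatched dimensions")
  }

  combined <- NULL
  for (b in blanks) {
    bm <- block_minimum(b$pixels, block_size)
    combined <- if (is.null(combined)) bm$mins else pmin(combined, bm$mins)
  }
  bi <- (seq_len(nrow(blanks[[1]]$pixels)) - 1L) %/% block_size
  bj <- (seq_len(ncol(blanks[[1]]$pixels)) - 1L) %/% block_size
  field <- combined[cbind(rep(bi + 1L, times = length(bj)),
                          rep(bj + 1L, each = length(bi)))]
  field <- matrix(field, nrow = length(bi))
  if (filter_radius > 0L) {
    field <- EBImage::medianFilter(pmin(pmax(field, 0), 1), filter_radius)
    field <- as.matrix(field)
  }
  background_field(pmax(field, 0), block_size, filter_radius)
}

#' Subtract the background illumination function from an image
#'
#' Output pixels are clamped at zero: intensities are physical signal, so
#' sub-background pixels carry no information.
#'
#' @param image a `plate_image` at stage `"inverted"`.
#' @param field a [background_field()] of the same dimensions.
#' @return A `plate_image` at stage `"background_subtracted"`.
#' @export
subtract_background <- function(image, field) {
  stopifnot(inherits(image, "plate_image"), inherits(field, "background_field"))
  if (image$stage != "inverted") stop("image must be at stage 'inverted'")
  if (!identical(dim(image$pixels), dim(field$pixels))) {
    stop("image and background field dimensions differ")
  }
  plate_image(pmax(image$pixels - field$pixels, 0),
              image$plate_id, image$replicate,
              stage = "background_subtracted")
}

#' Measure mean intensity inside the quantification circle at every grid site
#'
#' A pixel belongs to a site's circle when its center lies within
#' `circle_diameter / 2` (Euclidean) of the site center. Records are returned
#' in row-major site order with 0-based grid indices, an A1-style well name,
#' the strain id from the layout (`NA` at empty positions) and a growth flag
#' initialized to 1 (empty layout positions get 0).
#'
#' @param image a `plate_image` at stage `"background_subtracted"`.
#' @param grid a [grid_spec()]; every circle must lie fully inside the image.
#' @param layout optional [plate_layout()] with matching dimensions.
#' @return Data frame of per-site records (`plate_id`, `replicate`, `row`,
#'   `col`, `site`, `strain_id`, `mean_intensity`, `growth_flag`).
#' @export
measure_sites <- function(image, grid, layout = NULL) {
  stopifnot(inherits(image, "plate_image"), inherits(grid, "grid_spec"))
  if (image$stage != "background_subtracted") {
    stop("image must be at stage 'background_subtracted'")
  }
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "plate_layout"))
    if (layout$n_rows != grid$n_rows || layout$n_cols != grid$n_cols) {
      stop("layout and grid dimensions differ")
    }
  }
  px <- image$pixels
  r <- grid$circle_diameter / 2
  h <- nrow(px); w <- ncol(px)

  rows <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  cx <- grid$origin_x + grid$pitch_x * cols
  cy <- grid$origin_y + grid$pitch_y * rows
  if (any(cx - r < 0.5) || any(cx + r > w + 0.5) ||
      any(cy - r < 0.5) || any(cy + r > h + 0.5)) {
    stop("quantification circle extends outside the image")
  }

  means <- numeric(length(rows))
  for (k in seq_along(rows)) {
    ys <- max(1L, floor(cy[k] - r)):min(h, ceiling(cy[k] + r))
    xs <- max(1L, floor(cx[k] - r)):min(w, ceiling(cx[k] + r))
    d2 <- outer((ys - cy[k])^2, (xs - cx[k])^2, `+`)
    inside <- d2 <= r * r
    means[k] <- mean(px[ys, xs][inside])
  }

  strain <- rep(NA_character_, length(rows))
  flag <- rep(1L, length(rows))
  if (!is.null(layout)) {
    strain <- layout$strain_ids[cbind(rows + 1L, cols + 1L)]
    if (nrow(layout$empty_positions)) {
      empty_key <- paste(layout$empty_positions[, 1], layout$empty_positions[, 2])
      is_empty <- paste(rows, cols) %in% empty_key
      strain[is_empty] <- NA_character_
      flag[is_empty] <- 0L
    }
  }
  out <- data.frame(
    plate_id = image$plate_id, replicate = image$replicate,
    row = rows, col = cols, site = well_name(rows, cols),
    strain_id = strain, mean_intensity = means, growth_flag = flag,
    stringsAsFactors = FALSE
  )
  attr(out, "n_rows") <- grid$n_rows
  attr(out, "n_cols") <- grid$n_cols
  out
}

#' Apply manual growth flags to measured sites
#'
#' The screen's manual inspection step: sites with no or abnormal growth are
#' flagged 0 so they do not distort plate medians. Intensities are left
#' untouched; flagged sites are excluded downstream from medians and hit
#' calls. Sites absent from the flag table keep flag 1 (normal growth was the
#' default; manual flags were the exception).
#'
#' @param sites data frame from [measure_sites()].
#' @param flags data frame with columns `row`, `col` (0-based grid indices)
#'   and `growth_flag` in `{0, 1}`; optionally `plate_id`/`replicate` to
#'   scope flags to one plate image.
#' @return `sites` with updated `growth_flag`.
#' @export
apply_growth_flags <- function(sites, flags) {
  stopifnot(is.data.frame(sites), is.data.frame(flags))
  if (!all(c("row", "col", "growth_flag") %in% names(flags))) {
    stop("`flags` needs columns row, col, growth_flag")
  }
  if (!all(flags$growth_flag %in% c(0L, 1L))) {
    stop("growth flags must be 0 or 1")
  }
  scope <- rep(TRUE, nrow(flags))
  if ("plate_id" %in% names(flags)) scope <- scope & flags$plate_id %in% sites$plate_id
  if ("replicate" %in% names(flags)) scope <- scope & flags$replicate %in% sites$replicate
  flags <- flags[scope, , drop = FALSE]
  key_sites <- paste(sites$row, sites$col)
  key_flags <- paste(flags$row, flags$col)
  unknown <- setdiff(key_flags, key_sites)
  if (length(unknown)) {
    stop("growth flag refers to unknown grid position(s): ",
         paste(unknown, collapse = "; "))
  }
  m <- match(key_sites, key_flags)
  upd <- !is.na(m)
  sites$growth_flag[upd] <- as.integer(flags$growth_flag[m[upd]])
  sites
}
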