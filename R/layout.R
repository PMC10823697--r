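#' Colony-array layout
#'
#' Describes a colony array: grid dimensions, the strain pinned at each site,
#' which sites hold the reference strain, which sites are intentionally empty,
#' and (for simulation) the multiplicative expression effect planted for each
#' strain (1.0 = reference-like; > 1 more secreted enzyme, < 1 less).
#'
#' Grid coordinates are 0-based row-major internally; user-facing files use
#' 1-based rows/columns and A1-style well names (A1..P24 on a 16 x 24 array).
#'
#' @param n_rows,n_cols grid dimensions (default 16 x 24 = 384 sites).
#' @param strain_ids character matrix `n_rows x n_cols` of strain identifiers;
#'   defaults to `"sR.C"` names.
#' @param reference_positions 2-column matrix of 0-based (row, col) positions
#'   carrying the reference strain.
#' @param planted_effects named numeric vector: strain id -> multiplicative
#'   effect, all > 0. Strains absent from the map have effect 1.
#' @param empty_positions 2-column matrix of 0-based (row, col) positions with
#'   no colony.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(n_rows = 16L, n_cols = 24L, strain_ids = NULL,
                         reference_positions = NULL,
                         planted_effects = numeric(0),
                         empty_positions = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  if (is.null(strain_ids)) {
    strain_ids <- outer(seq_len(n_rows) - 1L, seq_len(n_cols) - 1L,
                        function(r, c) sprintf("s%d.%d", r, c))
  }
  if (!is.matrix(strain_ids) || nrow(strain_ids) != n_rows ||
      ncol(strain_ids) != n_cols) {
    stop("`strain_ids` must be an n_rows x n_cols matrix")
  }
  reference_positions <- as_position_matrix(reference_positions)
  empty_positions <- as_position_matrix(empty_positions)
  check_positions(reference_positions, n_rows, n_cols, "reference_positions")
  check_positions(empty_positions, n_rows, n_cols, "empty_positions")
  if (nrow(reference_positions) && nrow(empty_positions)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (any(key(reference_positions) %in% key(empty_positions))) {
      stop("reference_positions and empty_positions must be disjoint")
    }
  }
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects)))) {
      stop("`planted_effects` must be a named vector")
    }
    if (any(!is.finite(planted_effects)) || any(planted_effects <= 0)) {
      stop("planted effects must be positive")
    }
    unknown <- setdiff(names(planted_effects), strain_ids)
    if (length(unknown)) {
      stop("planted effect refers to unknown strain(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, strain_ids = strain_ids,
         reference_positions = reference_positions,
         planted_effects = planted_effects,
         empty_positions = empty_positions),
    class = "plate_layout"
  )
}

as_position_matrix <- function(x) {
  if (is.null(x)) return(matrix(integer(0), ncol = 2L))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != 2L) stop("positions must be (row, col) pairs")
  x
}

check_positions <- function(pos, n_rows, n_cols, what) {
  if (!nrow(pos)) return(invisible())
  if (any(pos[, 1] < 0L) || any(pos[, 1] >= n_rows) ||
      any(pos[, 2] < 0L) || any(pos[, 2] >= n_cols)) {
    stop(what, " out of grid bounds")
  }
  invisible()
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d (%d sites), %d planted effect(s), %d empty\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols,
              length(x$planted_effects), nrow(x$empty_positions)))
  invisible(x)
}

#' Quantification grid geometry
#'
#' Geometry of the measurement grid laid over a plate image: where site
#' centers sit and the diameter of the circle used to average pixel
#' intensities at each site (the screen used a 101-pixel circle centered in
#' each of the 384 grid boxes). Grid placement is supplied, not auto-detected.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param origin_x,origin_y pixel coordinates of the center of site (0, 0);
#'   x runs along image columns, y along image rows (1-based pixel centers).
#' @param pitch_x,pitch_y center-to-center spacing in pixels.
#' @param circle_diameter diameter (pixels) of the quantification circle; must
#'   not exceed the pitch.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 16L, n_cols = 24L, origin_x, origin_y,
                      pitch_x, pitch_y, circle_diameter = 101) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pitch_x > 0, pitch_y > 0,
            circle_diameter > 0)
  if (circle_diameter > min(pitch_x, pitch_y)) {
    stop("circle_diameter must not exceed the grid pitch")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, origin_x = origin_x,
         origin_y = origin_y, pitch_x = pitch_x, pitch_y = pitch_y,
         circle_diameter = circle_diameter),
    class = "grid_spec"
  )
}

# Site center in pixel coordinates (x = column axis, y = row axis), 0-based
# grid indices.
site_center <- function(grid, row, col) {
  list(x = grid$origin_x + grid$pitch_x * col,
       y = grid$origin_y + grid$pitch_y * row)
}

#' A1-style well name from 0-based grid indices
#'
#' @param row,col 0-based grid indices (vectorized).
#' @return Character vector like `"A1"`, `"P24"`.
#' @export
well_name <- function(row, col) {
  stopifnot(all(row >= 0L), all(row < 26L), all(col >= 0L))
  paste0(LETTERS[row + 1L], col + 1L)
}
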