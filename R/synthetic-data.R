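#' Simulation settings for synthetic plate images and blanks
#'
#' Parameters of the synthetic colony-array imagery used to exercise the
#' densitometry pipeline against known ground truth. Colonies are rendered as
#' uniform disks with a Gaussian-blurred edge; the spatial edge artifact (the
#' signal inflation seen at sites near the plate periphery) is multiplicative
#' on colony signal and shaped by the concentric-rectangle zone index, so it
#' has exactly the geometry the zone correction targets. A smooth, config-
#' deterministic background illumination field and per-pixel Gaussian noise
#' complete the image. `signal_cv` adds per-site multiplicative biological
#' noise (colony-to-colony variation in secreted activity).
#'
#' Intensities are kept in `[0, 1]`; `base_signal` times the largest planted
#' effect times `(1 + edge_amplitude)` plus `background_field_scale` should
#' stay at or below 1 to avoid clipping.
#'
#' @param image_width,image_height image size in pixels.
#' @param colony_radius colony disk radius in pixels.
#' @param base_signal disk intensity of a reference-like colony, in `[0, 1]`.
#' @param edge_amplitude strength of the concentric-rectangle edge artifact
#'   (0 disables it); the outermost ring is inflated by `1 + edge_amplitude`.
#' @param background_field_scale peak intensity of the smooth background
#'   illumination field.
#' @param noise_sd per-pixel additive Gaussian noise SD (intensity units).
#' @param signal_cv per-site multiplicative noise CV on colony signal.
#' @param edge_sigma Gaussian blur sigma (pixels) of the colony edge.
#' @param seed default random seed for the generators.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(image_width = 480L, image_height = 320L,
                              colony_radius = 6, base_signal = 0.18,
                              edge_amplitude = 0.3,
                              background_field_scale = 0.10,
                              noise_sd = 0.01, signal_cv = 0.1,
                              edge_sigma = 1.0, seed = 1L) {
  vals <- c(image_width = image_width, image_height = image_height,
            colony_radius = colony_radius, base_signal = base_signal,
            edge_amplitude = edge_amplitude,
            background_field_scale = background_field_scale,
            noise_sd = noise_sd, signal_cv = signal_cv,
            edge_sigma = edge_sigma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all simulation parameters must be finite and non-negative")
  }
  structure(
    list(image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         colony_radius = colony_radius, base_signal = base_signal,
         edge_amplitude = edge_amplitude,
         background_field_scale = background_field_scale,
         noise_sd = noise_sd, signal_cv = signal_cv,
         edge_sigma = edge_sigma, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Measurement grid matching a simulated plate
#'
#' Site centers are placed on a regular lattice filling the image, so a
#' layout of `n_rows x n_cols` sites maps to pitches
#' `image_width / n_cols` and `image_height / n_rows`.
#'
#' @param layout a [plate_layout()].
#' @param config a [simulation_config()].
#' @param circle_diameter quantification circle diameter in pixels; default
#'   slightly larger than the rendered colony.
#' @return A [grid_spec()].
#' @export
derive_grid <- function(layout, config,
                        circle_diameter = 2 * config$colony_radius + 3) {
  pitch_x <- config$image_width / layout$n_cols
  pitch_y <- config$image_height / layout$n_rows
  grid_spec(n_rows = layout$n_rows, n_cols = layout$n_cols,
            origin_x = pitch_x / 2, origin_y = pitch_y / 2,
            pitch_x = pitch_x, pitch_y = pitch_y,
            circle_diameter = circle_diameter)
}

# Smooth, strictly config-deterministic illumination field (gradient plus a
# broad Gaussian bump), peaking at background_field_scale.
background_field_pixels <- function(config) {
  w <- config$image_width; h <- config$image_height
  u <- matrix(rep((seq_len(w) - 0.5) / w, each = h), nrow = h)
  v <- matrix(rep((seq_len(h) - 0.5) / h, times = w), nrow = h)
  g <- 0.4 + 0.35 * u + 0.25 * exp(-((u - 0.3)^2 + (v - 0.4)^2) / 0.18)
  config$background_field_scale * g
}

# Edge-artifact weight per site: 1 on the outermost concentric rectangle,
# decreasing linearly to 0 at the center ring.
zone_factor_matrix <- function(n_rows, n_cols, zone_width = 1L) {
  z <- assign_zones(n_rows, n_cols, zone_width)
  nz <- max(z)
  if (nz == 1L) return(matrix(1, n_rows, n_cols))
  (nz - z) / (nz - 1)
}

# Blurred-disk radial profile: 1 well inside the colony, 0 outside, smooth
# roll-off of width edge_sigma at the rim.
disk_profile <- function(d, radius, sigma) {
  if (sigma <= 0) return(as.numeric(d <= radius))
  stats::pnorm((radius - d) / sigma)
}

# Paint one colony of amplitude `amp` at pixel center (cx, cy) onto `img`
# (matrix indexed [row, col] = [y, x]). Operates on a local window only.
paint_colony <- function(img, cx, cy, amp, radius, sigma) {
  reach <- radius + 4 * max(sigma, 0.5)
  y0 <- max(1L, floor(cy - reach)); y1 <- min(nrow(img), ceiling(cy + reach))
  x0 <- max(1L, floor(cx - reach)); x1 <- min(ncol(img), ceiling(cx + reach))
  ys <- y0:y1; xs <- x0:x1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  img[ys, xs] <- img[ys, xs] + amp * disk_profile(d, radius, sigma)
  img
}

#' Simulate a colony-array plate image with known ground truth
#'
#' Renders one plate of the overlay screen: each occupied site contributes a
#' blurred disk whose amplitude is
#' `base_signal * effect * (1 + edge_amplitude * zone_factor) * site_noise`,
#' on top of the background illumination field and per-pixel noise. Empty
#' sites contribute no colony signal. By default the image is returned in
#' camera orientation (`"raw"`: colonies dark on light membrane, i.e.
#' `1 - signal`), so it flows through [preprocess_image()] like a photograph;
#' `orientation = "signal"` returns the inverted-space image directly.
#'
#' @param layout a [plate_layout()] carrying strain ids and planted effects.
#' @param config a [simulation_config()].
#' @param seed random seed; identical seeds give bit-identical images.
#' @param plate_id,replicate identity stamped on the image and ground truth.
#' @param orientation `"raw"` (default) or `"signal"`.
#' @return A list with elements `image` (a `plate_image`), and `truth`: a
#'   data frame of per-site true expression and growth status plus attributes
#'   `positive_strains` / `negative_strains` (planted effect > 1 / < 1).
#' @export
simulate_plate_image <- function(layout, config, seed = config$seed,
                                 plate_id = "plate1", replicate = 1L,
                                 orientation = c("raw", "signal")) {
  stopifnot(inherits(layout, "plate_layout"), inherits(config, "simulation_config"))
  orientation <- match.arg(orientation)
  grid <- derive_grid(layout, config)
  set.seed(seed)

  nr <- layout$n_rows; nc <- layout$n_cols
  effects <- matrix(1, nr, nc)
  if (length(layout$planted_effects)) {
    idx <- match(layout$strain_ids, names(layout$planted_effects))
    hit <- !is.na(idx)
    effects[hit] <- layout$planted_effects[idx[hit]]
  }
  growth <- matrix("normal", nr, nc)
  if (nrow(layout$empty_positions)) {
    growth[layout$empty_positions + 1L] <- "none"
  }
  zf <- zone_factor_matrix(nr, nc)
  site_noise <- matrix(1, nr, nc)
  if (config$signal_cv > 0) {
    site_noise[] <- pmax(stats::rnorm(nr * nc, 1, config$signal_cv), 0)
  }
  amp <- config$base_signal * effects *
    (1 + config$edge_amplitude * zf) * site_noise
  amp[growth == "none"] <- 0

  img <- background_field_pixels(config)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (amp[r, cc] <= 0) next
      ctr <- site_center(grid, r - 1L, cc - 1L)
      img <- paint_colony(img, ctr$x, ctr$y, amp[r, cc],
                          config$colony_radius, config$edge_sigma)
    }
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                        nrow = nrow(img))
  }
  img <- pmin(pmax(img, 0), 1)
  if (orientation == "raw") {
    image <- plate_image(1 - img, plate_id, replicate, stage = "raw")
  } else {
    image <- plate_image(img, plate_id, replicate, stage = "inverted")
  }

  rows <- rep(seq_len(nr) - 1L, times = nc)
  cols <- rep(seq_len(nc) - 1L, each = nr)
  truth <- data.frame(
    plate_id = plate_id, replicate = as.integer(replicate),
    row = rows, col = cols,
    strain_id = as.vector(layout$strain_ids),
    true_effect = as.vector(effects),
    growth = as.vector(growth),
    growth_flag = as.integer(as.vector(growth) == "normal"),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$row, truth$col), ]
  rownames(truth) <- NULL
  attr(truth, "positive_strains") <-
    names(layout$planted_effects)[layout$planted_effects > 1]
  attr(truth, "negative_strains") <-
    names(layout$planted_effects)[layout$planted_effects < 1]
  list(image = image, truth = truth)
}

#' Simulate a blank plate (background field plus noise, no colonies)
#'
#' Emulates the blank membrane plates imaged to build the background
#' illumination function.
#'
#' @inheritParams simulate_plate_image
#' @return A `plate_image`.
#' @export
simulate_blank_plate <- function(config, seed = config$seed,
                                 plate_id = "blank", replicate = 1L,
                                 orientation = c("raw", "signal")) {
  stopifnot(inherits(config, "simulation_config"))
  orientation <- match.arg(orientation)
  set.seed(seed)
  img <- background_field_pixels(config)
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                        nrow = nrow(img))
  }
  img <- pmin(pmax(img, 0), 1)
  if (orientation == "raw") {
    plate_image(1 - img, plate_id, replicate, stage = "raw")
  } else {
    plate_image(img, plate_id, replicate, stage = "inverted")
  }
}

#' Simulate an ABTS kinetic absorbance trace
#'
#' Produces an A420-versus-time series with an initial linear phase of slope
#' `true_slope` up to `linear_until`, followed by a smooth exponential
#' approach to a plateau (substrate depletion). The saturating phase has a
#' continuous first derivative at the breakpoint:
#' `A(t) = A(linear_until) + true_slope * tau * (1 - exp(-(t - linear_until)/tau))`.
#'
#' @param true_slope linear-phase slope in AU/min; must be non-negative
#'   (oxidized ABTS accumulates).
#' @param intercept absorbance at time 0 (AU).
#' @param linear_until end of the linear phase (min); must not exceed
#'   `total_time`.
#' @param total_time total monitored time (min); default two hours.
#' @param read_interval time between reads (min); default every minute.
#' @param noise_sd additive Gaussian noise SD (AU).
#' @param seed random seed.
#' @param tau saturation time constant (min).
#' @param well_id,strain_id identifiers carried on the trace.
#' @return A `kinetic_trace`: list with `time` (min), `a420`, identifiers and
#'   a `retained` logical mask (all `TRUE` until fitting).
#' @export
simulate_kinetic_trace <- function(true_slope, intercept = 0.05,
                                   linear_until = 120, total_time = 120,
                                   read_interval = 1, noise_sd = 0,
                                   seed = 1L, tau = 10,
                                   well_id = "A1", strain_id = "strain") {
  if (!is.finite(true_slope) || true_slope < 0) {
    stop("`true_slope` must be non-negative (oxidized ABTS accumulates)")
  }
  if (linear_until > total_time) stop("`linear_until` must not exceed `total_time`")
  if (read_interval <= 0) stop("`read_interval` must be positive")
  set.seed(seed)
  tm <- seq(0, total_time, by = read_interval)
  a <- intercept + true_slope * tm
  sat <- tm > linear_until
  if (any(sat)) {
    a_break <- intercept + true_slope * linear_until
    a[sat] <- a_break + true_slope * tau * (1 - exp(-(tm[sat] - linear_until) / tau))
  }
  if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
  kinetic_trace(time = tm, a420 = a, well_id = well_id, strain_id = strain_id)
}

#' Kinetic trace container
#'
#' @param time time points in minutes, strictly increasing, at least 3.
#' @param a420 absorbance at 420 nm, same length as `time`, finite.
#' @param well_id,strain_id identifiers.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, a420, well_id = "A1", strain_id = "strain") {
  if (length(time) < 3L) stop("a kinetic trace needs at least 3 points")
  if (length(a420) != length(time)) stop("`time` and `a420` lengths differ")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (any(!is.finite(a420))) stop("`a420` must be finite")
  structure(
    list(time = as.numeric(time), a420 = as.numeric(a420),
         well_id = well_id, strain_id = strain_id,
         retained = rep(TRUE, length(time))),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> well %s (%s): %d reads over %.0f min, %d retained\n",
              x$well_id, x$strain_id, length(x$time), max(x$time),
              sum(x$retained)))
  invisible(x)
}

#' Simulate a replicated activity study with planted fold effects
#'
#' Generates per-strain replicate OD600-normalized activities around
#' `effect * reference_mean` with coefficient of variation `cv`, together with
#' OD600 readings; raw activity is reconstructed as
#' `normalized_activity * od600` so the downstream normalization and
#' fold-change computation can recover the planted effects. The reference
#' strain (effect 1) is always included.
#'
#' @param n_strains number of non-reference strains; strains beyond those
#'   named in `effects` get effect 1.
#' @param effects named numeric vector of planted fold effects (> 0).
#' @param n_replicates biological replicates per strain (>= 2).
#' @param cv coefficient of variation of normalized activity (>= 0).
#' @param seed random seed.
#' @param reference_strain name of the reference strain.
#' @param reference_mean mean normalized activity of the reference strain
#'   (activity / OD600 units).
#' @param od_mean,od_cv mean and CV of the OD600 readings.
#' @return Data frame with columns `strain_id`, `replicate`, `activity`,
#'   `od600` (and the generating `true_effect`).
#' @export
simulate_activity_study <- function(n_strains = length(effects),
                                    effects = numeric(0),
                                    n_replicates = 3L, cv = 0.1, seed = 1L,
                                    reference_strain = "reference",
                                    reference_mean = 1.0,
                                    od_mean = 10, od_cv = 0.05) {
  if (cv < 0) stop("`cv` must be non-negative")
  if (n_replicates < 2L) stop("`n_replicates` must be at least 2")
  if (any(effects <= 0)) stop("effects must be positive")
  n_strains <- max(n_strains, length(effects))
  ids <- names(effects)
  if (length(effects) && is.null(ids)) {
    ids <- sprintf("strain%02d", seq_along(effects))
  }
  if (n_strains > length(effects)) {
    extra <- sprintf("null%02d", seq_len(n_strains - length(effects)))
    effects <- c(stats::setNames(effects, ids), stats::setNames(
      rep(1, length(extra)), extra))
  } else {
    effects <- stats::setNames(effects, ids)
  }
  effects <- c(stats::setNames(1, reference_strain), effects)

  set.seed(seed)
  out <- do.call(rbind, lapply(names(effects), function(s) {
    mu <- effects[[s]] * reference_mean
    norm <- if (cv > 0) stats::rnorm(n_replicates, mu, cv * mu) else rep(mu, n_replicates)
    norm <- pmax(norm, 1e-9)
    od <- if (od_cv > 0) stats::rnorm(n_replicates, od_mean, od_cv * od_mean) else rep(od_mean, n_replicates)
    od <- pmax(od, 1e-3)
    data.frame(strain_id = s, replicate = seq_len(n_replicates),
               activity = norm * od, od600 = od,
               true_effect = effects[[s]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
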