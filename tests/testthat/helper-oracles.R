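# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: plain sort-based medians, double loops over pixels.

# Median via explicit order statistics (even count = mean of the two central).
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

# Brute-force modified Z: MAD = 1.4826 * median(|x - median|).
oracle_modified_z <- function(x) {
  med <- oracle_median(x)
  mad_ <- 1.4826 * oracle_median(abs(x - med))
  (x - med) / mad_
}

# Mean intensity within a circle by a naive double loop over every pixel.
oracle_circle_mean <- function(px, cx, cy, radius) {
  total <- 0; count <- 0L
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      if ((i - cy)^2 + (j - cx)^2 <= radius^2) {
        total <- total + px[i, j]
        count <- count + 1L
      }
    }
  }
  total / count
}

# Monte-Carlo null of the Dunnett max-|t| statistic: k groups of size n,
# reference first. Returns adjusted p for each observed |t|.
oracle_dunnett_mc <- function(t_obs, k, n, n_draws = 1e5, seed = 42) {
  set.seed(seed)
  df <- k * (n - 1L)
  maxt <- replicate(n_draws, {
    y <- matrix(rnorm(k * n), nrow = n)
    m <- colMeans(y)
    s2 <- sum((y - rep(m, each = n))^2) / df
    tt <- (m[-1] - m[1]) / sqrt(s2 * 2 / n)
    max(abs(tt))
  })
  vapply(abs(t_obs), function(t0) mean(maxt >= t0), numeric(1))
}

# Monte-Carlo null of the Tukey studentized-range statistic.
oracle_tukey_mc <- function(q_obs, k, n, n_draws = 1e5, seed = 42) {
  set.seed(seed)
  df <- k * (n - 1L)
  qs <- replicate(n_draws, {
    y <- matrix(rnorm(k * n), nrow = n)
    m <- colMeans(y)
    s2 <- sum((y - rep(m, each = n))^2) / df
    (max(m) - min(m)) / sqrt(s2 / n)
  })
  vapply(q_obs, function(q0) mean(qs >= q0), numeric(1))
}

# Small fully-specified measured-sites data frame for scoring tests.
make_sites <- function(values, n_rows, n_cols, flags = NULL,
                       plate_id = "p1", replicate = 1L,
                       strain_ids = NULL) {
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  if (is.null(flags)) flags <- rep(1L, n_rows * n_cols)
  if (is.null(strain_ids)) strain_ids <- sprintf("s%d.%d", rows, cols)
  d <- data.frame(plate_id = plate_id, replicate = replicate,
                  row = rows, col = cols,
                  site = well_name(rows, cols),
                  strain_id = strain_ids,
                  mean_intensity = values, growth_flag = flags,
                  stringsAsFactors = FALSE)
  attr(d, "n_rows") <- n_rows
  attr(d, "n_cols") <- n_cols
  d
}

# Wrap a pixel matrix as a background-subtracted plate_image, bypassing the
# preprocessing stages, for direct measurement tests.
as_subtracted <- function(px, plate_id = "p1", replicate = 1L) {
  plate_image(px, plate_id, replicate, stage = "background_subtracted")
}
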