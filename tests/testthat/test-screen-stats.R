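test_that("plate-median normalization matches hand-evaluated medians", {
  st <- make_sites(c(2, 4, 6, 8), 2L, 2L)
  out <- normalize_to_plate_median(st)
  expect_equal(out$normalized, c(0.4, 0.8, 1.2, 1.6))
  expect_equal(attr(out, "plate_median"), 5)

  # all raws equal -> all normalized 1
  expect_equal(normalize_to_plate_median(make_sites(rep(3, 4), 2L, 2L))$normalized,
               rep(1, 4))

  # flagged-0 sites are excluded from the median but still normalized
  st2 <- make_sites(c(1, 100, 1, 1), 2L, 2L, flags = c(1L, 0L, 1L, 1L))
  out2 <- normalize_to_plate_median(st2)
  expect_equal(attr(out2, "plate_median"), 1)
  expect_equal(out2$normalized, c(1, 100, 1, 1))
  expect_equal(median(out2$normalized[out2$growth_flag == 1]), 1)

  expect_error(normalize_to_plate_median(
    make_sites(c(1, 2), 1L, 2L, flags = c(0L, 0L))), "flagged 0")
  expect_error(normalize_to_plate_median(
    make_sites(c(0, 0), 1L, 2L)), "zero")
})

test_that("concentric-rectangle zones partition the grid as derived by hand", {
  z <- assign_zones(16L, 24L, 1L)
  expect_equal(max(z), 8L)              # min(16,24)/2 rings
  expect_equal(z[1, 1], 1L)             # corner on the outermost ring
  expect_equal(z[8, 8], 8L); expect_equal(z[9, 17], 8L)  # central block
  expect_true(all(table(z) > 0))
  expect_equal(sum(table(z)), 384L)

  expect_equal(assign_zones(2L, 2L), matrix(1L, 2, 2))

  # width-2 rings halve the zone count
  expect_equal(max(assign_zones(16L, 24L, 2L)), 4L)
})

test_that("zone correction divides only zones whose median exceeds 1", {
  # 4x4 toy: outer ring 1.2, inner 2x2 block 0.9
  ring <- pmin(rep(0:3, each = 4), rep(0:3, times = 4),
               3 - rep(0:3, each = 4), 3 - rep(0:3, times = 4))
  vals <- ifelse(ring == 0, 1.2, 0.9)
  st <- make_sites(vals, 4L, 4L)
  st$normalized <- vals
  out <- zone_correct(st, 4L, 4L)
  expect_equal(out$zone_corrected[out$zone_index == 1], rep(1.0, 12))
  expect_equal(out$zone_corrected[out$zone_index == 2], rep(0.9, 4))

  # uniform plate of exactly 1.0 is untouched (strict inequality at 1.0)
  stu <- make_sites(rep(1, 16), 4L, 4L)
  stu$normalized <- rep(1, 16)
  expect_equal(zone_correct(stu, 4L, 4L)$zone_corrected, rep(1, 16))

  # zone median exactly 1.0: boundary left unchanged
  stb <- make_sites(vals, 4L, 4L)
  stb$normalized <- ifelse(ring == 0, 1.0, 1.5)
  outb <- zone_correct(stb, 4L, 4L)
  expect_equal(outb$zone_corrected[outb$zone_index == 1], rep(1.0, 12))
  expect_equal(outb$zone_corrected[outb$zone_index == 2], rep(1.0, 4))
})

test_that("zone correction never increases values and is idempotent", {
  for (s in 1:25) {
    set.seed(s)
    st <- make_sites(runif(8 * 12, 0.1, 1), 8L, 12L)
    st <- normalize_to_plate_median(st)
    once <- zone_correct(st, 8L, 12L)
    expect_true(all(once$zone_corrected <= once$normalized + 1e-15))
    twice <- once
    twice$normalized <- twice$zone_corrected
    twice <- zone_correct(twice[setdiff(names(twice), "zone_index")], 8L, 12L)
    expect_equal(twice$zone_corrected, once$zone_corrected, tolerance = 1e-12)
  }
})

test_that("a zone with no flag-1 sites is left uncorrected with a warning", {
  st <- make_sites(c(2, 2, 2, 2, 1, 1, 1, 1, 2, 2, 2, 2), 3L, 4L)
  st$growth_flag[st$row == 1] <- 0L   # the width-3 grid's inner ring is row 1
  st <- normalize_to_plate_median(st)
  expect_warning(out <- zone_correct(st, 3L, 4L), "no flag-1")
  inner <- out$zone_index == 2
  expect_equal(out$zone_corrected[inner], out$normalized[inner])
})

test_that("modified Z-scores reproduce the MAD formula", {
  z <- modified_zscore(c(1, 2, 3, 4, 100))
  expect_equal(z[3], 0)                      # the median element
  expect_equal(z[5], 97 / 1.4826, tolerance = 1e-12)
  expect_equal(z[1], -2 / 1.4826, tolerance = 1e-12)

  # location-scale invariance
  set.seed(31)
  x <- rnorm(50)
  expect_equal(modified_zscore(3 * x + 7), modified_zscore(x), tolerance = 1e-12)

  # flag-0 values are scored but excluded from median and MAD
  zf <- modified_zscore(c(1, 2, 3, 1000), flags = c(1, 1, 1, 0))
  expect_equal(zf[1:3], oracle_modified_z(c(1, 2, 3)))

  expect_error(modified_zscore(rep(2, 10)), "MAD is zero")
  expect_error(modified_zscore(c(1, 2), flags = c(1, 0)), "at least 2")
})

test_that("modified Z matches brute-force evaluation on random vectors", {
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(sample(5:200, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    expect_equal(modified_zscore(x), oracle_modified_z(x), tolerance = 1e-13)
  }
})

test_that("hit calling applies the >= 2.5 in >= 2 replicates rule", {
  mk <- function(z) data.frame(strain_id = "s", replicate = seq_along(z),
                               modified_z = z)
  expect_equal(call_hits(mk(c(2.6, 2.7, 1.0)))$call, "positive")
  expect_equal(call_hits(mk(c(2.6, 1.0, 1.0)))$call, "none")
  expect_equal(call_hits(mk(c(0, 0, 0)))$call, "none")
  expect_equal(call_hits(mk(c(-2.6, -2.6, 0)))$call, "negative")
  expect_equal(call_hits(mk(c(2.5, 2.5, 0)))$call, "positive")  # >= is inclusive

  empty <- data.frame(strain_id = character(0), replicate = integer(0),
                      modified_z = numeric(0))
  expect_error(call_hits(empty), "no scores")

  # flag-0 replicates do not support a call
  d <- mk(c(2.6, 2.7, 1.0)); d$growth_flag <- c(1L, 0L, 1L)
  expect_equal(call_hits(d)$call, "none")

  # a strain cannot be both positive and negative
  d2 <- data.frame(strain_id = "s", replicate = 1:4,
                   modified_z = c(2.6, 2.6, -2.6, -2.6))
  expect_warning(h <- call_hits(d2), "both")
  expect_equal(h$call, "none")
})

test_that("hit table reports mean z and orders strains by it", {
  d <- data.frame(strain_id = rep(c("a", "b"), each = 3), replicate = rep(1:3, 2),
                  modified_z = c(3, 3, 3, 5, 5, 5))
  h <- call_hits(d)
  expect_equal(h$strain_id, c("b", "a"))
  expect_equal(h$mean_z, c(5, 3))
  expect_equal(h$z1, c(5, 3))
  expect_equal(h$call, c("positive", "positive"))
})

test_that("score_plate composes normalization, zone correction and scoring", {
  set.seed(41)
  st <- make_sites(runif(8 * 12, 0.2, 0.8), 8L, 12L)
  sc <- score_plate(st)
  expect_equal(median(sc$normalized[sc$growth_flag == 1]), 1)
  expect_true(all(c("zone_index", "zone_corrected", "modified_z") %in% names(sc)))
  expect_equal(sc$modified_z,
               oracle_modified_z(sc$zone_corrected), tolerance = 1e-12)
})

test_that("bit-identical replicate plates give identical z; planted 3x is recovered", {
  lay <- plate_layout(8L, 12L, planted_effects = c(s4.6 = 3.0))
  cfg <- simulation_config(image_width = 240L, image_height = 160L,
                           noise_sd = 0.002, signal_cv = 0.05,
                           edge_amplitude = 0.3, background_field_scale = 0)
  grid <- derive_grid(lay, cfg)
  sims <- lapply(1:3, function(r) {
    sim <- simulate_plate_image(lay, cfg, seed = 100 + r, replicate = r,
                                orientation = "signal")
    st <- measure_sites(as_subtracted(sim$image$pixels, "p1", r), grid, lay)
    attr(st, "n_rows") <- 8L; attr(st, "n_cols") <- 12L
    st
  })
  sites <- do.call(rbind, sims)
  attr(sites, "n_rows") <- 8L; attr(sites, "n_cols") <- 12L
  res <- score_screen(sites, 8L, 12L)
  hit <- res$hits[res$hits$strain_id == "s4.6", ]
  expect_equal(hit$call, "positive")
  expect_true(all(c(hit$z1, hit$z2, hit$z3) >= 2.5))

  # identical replicates give identical scores
  st1 <- sims[[1]]
  st2 <- sims[[1]]; st2$replicate <- 2L
  both <- rbind(st1, st2)
  attr(both, "n_rows") <- 8L; attr(both, "n_cols") <- 12L
  r2 <- score_screen(both, 8L, 12L)
  z1 <- r2$scores$modified_z[r2$scores$replicate == 1]
  z2 <- r2$scores$modified_z[r2$scores$replicate == 2]
  expect_identical(z1, z2)
})
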