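test_that("a perfectly linear trace is fitted without trimming", {
  tr <- simulate_kinetic_trace(0.01, intercept = 0.03, linear_until = 120,
                               total_time = 120, noise_sd = 0)
  ft <- fit_linear_range(tr)
  expect_equal(length(ft$trimmed_points), 0L)
  expect_equal(ft$r, 1)
  expect_equal(ft$slope, 0.01, tolerance = 1e-12)
  expect_equal(ft$intercept, 0.03, tolerance = 1e-12)
})

test_that("saturating traces are trimmed back to the linear segment", {
  # smooth exponential saturation
  tr <- simulate_kinetic_trace(0.02, intercept = 0.05, linear_until = 60,
                               total_time = 120, noise_sd = 0, tau = 10)
  ft <- fit_linear_range(tr)
  expect_gte(ft$r, 0.999)
  expect_equal(ft$slope, 0.02, tolerance = 1e-9)
  expect_true(all(ft$trimmed_points > 61))   # only trailing points removed

  # hard plateau
  tm <- 0:120
  hard <- kinetic_trace(tm, 0.05 + 0.02 * pmin(tm, 60))
  fh <- fit_linear_range(hard)
  expect_equal(fh$slope, 0.02, tolerance = 1e-9)
  expect_equal(fh$n_used, 61L)

  # an initial lag phase is trimmed from the leading end
  lag <- kinetic_trace(tm, 0.05 + 0.02 * pmax(tm - 20, 0))
  fl <- fit_linear_range(lag)
  expect_equal(fl$slope, 0.02, tolerance = 1e-9)
  expect_true(all(fl$trimmed_points <= 21))
})

test_that("degenerate and unreachable fits are rejected informatively", {
  tm <- 0:20
  expect_error(fit_linear_range(kinetic_trace(tm, rep(0.2, 21))),
               "constant trace")
  set.seed(8)
  noisy <- kinetic_trace(tm, rnorm(21, 0.5, 0.5))
  expect_error(fit_linear_range(noisy, r_min = 0.99999),
               "best r")
  expect_error(fit_linear_range(kinetic_trace(0:3, c(0, 1, 2, 3)),
                                min_points = 5L), "fewer than")
})

test_that("Beer-Lambert conversion matches the hand-evaluated example", {
  # 0.036 AU/min, eps 36,000, path 0.58 cm, 200 uL: 0.036/20880 * 2e-4 * 1e6
  expect_equal(activity_from_slope(0.036), 3.448276e-4, tolerance = 1e-6)
  expect_equal(activity_from_slope(0), 0)
  expect_equal(activity_from_slope(0.072), 2 * activity_from_slope(0.036))

  # homogeneity: degree 1 in slope, degree -1 in epsilon and path length
  s1 <- activity_spec(epsilon = 18000)
  expect_equal(activity_from_slope(0.036, s1), 2 * activity_from_slope(0.036))
  s2 <- activity_spec(path_length = 0.29)
  expect_equal(activity_from_slope(0.036, s2), 2 * activity_from_slope(0.036))

  # supernatant basis rescales by reaction/supernatant volume (10x)
  expect_equal(activity_from_slope(0.036, per_supernatant = TRUE),
               10 * activity_from_slope(0.036))

  expect_error(activity_from_slope(-0.01), "negative slope")
  expect_error(activity_spec(epsilon = -1), "positive")
})

test_that("OD normalization and fold change behave as ratios of means", {
  d <- data.frame(strain_id = rep(c("reference", "a"), each = 2),
                  replicate = rep(1:2, 2),
                  activity = c(1, 3, 2, 6), od600 = c(1, 1, 1, 1))
  nf <- normalize_and_fold(d, reference_strain = "reference")
  expect_equal(nf$fold_change[nf$strain_id == "a"][1], 2)
  expect_equal(nf$fold_change[nf$strain_id == "reference"][1], 1)

  # doubling od600 and activity leaves normalized activity unchanged
  d2 <- d; d2$activity <- d$activity * 2; d2$od600 <- d$od600 * 2
  nf2 <- normalize_and_fold(d2, reference_strain = "reference")
  expect_equal(nf2$normalized_activity, nf$normalized_activity)

  expect_error(normalize_and_fold(d, reference_strain = "missing"),
               "not present")
  d3 <- d; d3$od600[2] <- NA
  expect_error(normalize_and_fold(d3, reference_strain = "reference"),
               "missing OD600")
})

test_that("Dunnett reduces to the two-sided t test with one comparison", {
  set.seed(13)
  d <- data.frame(strain_id = rep(c("ref", "a"), each = 5),
                  value = c(rnorm(5, 1), rnorm(5, 1.4)))
  dn <- anova_dunnett(d, "ref")
  tt <- t.test(value ~ strain_id, d, var.equal = TRUE)$p.value
  expect_equal(dn$p_adj, tt, tolerance = 1e-4)
})

test_that("groups with equal means give adjusted p near 1", {
  d <- data.frame(strain_id = rep(c("ref", "a", "b"), each = 4),
                  value = rep(c(0.1, -0.1, 0.05, -0.05), times = 3))
  dn <- anova_dunnett(d, "ref")
  expect_true(all(dn$p_adj > 0.999))
  tk <- anova_tukey(d)
  expect_true(all(tk$p_adj > 0.999))
})

test_that("Dunnett adjustment never reduces the per-comparison p", {
  for (s in 1:10) {
    set.seed(s)
    d <- data.frame(strain_id = rep(c("ref", "a", "b", "c"), each = 3),
                    value = rnorm(12, rep(c(0, 0.5, 1, 2), each = 3)))
    dn <- anova_dunnett(d, "ref")
    fit <- aov(value ~ relevel(factor(strain_id), "ref"), d)
    mse <- sum(fit$residuals^2) / fit$df.residual
    means <- tapply(d$value, d$strain_id, mean)
    t_raw <- (means[dn$strain_id] - means["ref"]) / sqrt(mse * 2 / 3)
    p_raw <- 2 * pt(-abs(t_raw), fit$df.residual)
    expect_true(all(dn$p_adj >= unname(p_raw) - 1e-6))
    # monotone in |t|
    ord <- order(abs(dn$t))
    expect_true(all(diff(dn$p_adj[ord]) <= 1e-6))
  }
})

test_that("Dunnett adjusted p matches a Monte-Carlo max-|t| null", {
  set.seed(17)
  d <- data.frame(strain_id = rep(c("ref", "a", "b"), each = 3),
                  value = c(1.02, 0.95, 1.01, 1.25, 1.18, 1.30, 0.99, 1.08, 1.02))
  dn <- anova_dunnett(d, "ref")
  p_mc <- oracle_dunnett_mc(dn$t, k = 3L, n = 3L, n_draws = 1e5)
  expect_equal(dn$p_adj, p_mc, tolerance = 0.005)
})

test_that("Tukey matches the t test for two groups and an MC oracle for three", {
  set.seed(19)
  d2 <- data.frame(strain_id = rep(c("a", "b"), each = 5),
                   value = c(rnorm(5, 0), rnorm(5, 0.8)))
  tk2 <- anova_tukey(d2)
  expect_equal(tk2$p_adj,
               t.test(value ~ strain_id, d2, var.equal = TRUE)$p.value,
               tolerance = 1e-8)

  d3 <- data.frame(strain_id = rep(c("a", "b", "c"), each = 3),
                   value = c(1.0, 1.1, 0.9, 1.5, 1.6, 1.45, 1.05, 0.95, 1.1))
  tk3 <- anova_tukey(d3)
  means <- tapply(d3$value, d3$strain_id, mean)
  fit <- aov(value ~ strain_id, d3)
  mse <- sum(fit$residuals^2) / fit$df.residual
  q_obs <- abs(means[tk3$strain_a] - means[tk3$strain_b]) / sqrt(mse / 3)
  p_mc <- oracle_tukey_mc(unname(q_obs), k = 3L, n = 3L, n_draws = 1e5)
  expect_equal(tk3$p_adj, p_mc, tolerance = 0.005)
})

test_that("ANOVA helpers validate their inputs", {
  d <- data.frame(strain_id = rep(c("ref", "a"), each = 2), value = rep(1, 4))
  expect_error(anova_dunnett(d, "ref"), "zero within-group variance")
  expect_error(anova_dunnett(data.frame(strain_id = "x", value = 1), "x"),
               "at least")
  expect_error(anova_dunnett(data.frame(strain_id = c("a", "a"),
                                        value = c(1, 2)), "ref"),
               "not present")
})

test_that("delta-delta-Ct gives the expected fold changes", {
  expect_equal(delta_delta_ct(20, 15, 20, 15), 1)     # ddCt = 0
  expect_equal(delta_delta_ct(19, 15, 20, 15), 2)     # ddCt = -1
  expect_equal(delta_delta_ct(20, 15, 22, 15), 4)     # worked example
  expect_error(delta_delta_ct(NA, 15, 20, 15), "finite")
})

test_that("significance stars follow the 0.05/0.01/0.005 cutpoints", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.004)),
               c("", "*", "**", "***"))
})

test_that("slope recovery on noisy linear data stays within 3 SE", {
  misses <- 0L
  for (s in 1:100) {
    tr <- simulate_kinetic_trace(0.02, intercept = 0.05, linear_until = 120,
                                 total_time = 120, noise_sd = 0.003, seed = s)
    ft <- fit_linear_range(tr, r_min = 0.99)
    tt <- ft$trace$time[ft$trace$retained]
    se <- sqrt(sum((ft$trace$a420[ft$trace$retained] -
                      ft$intercept - ft$slope * tt)^2) /
                 (ft$n_used - 2) / sum((tt - mean(tt))^2))
    if (abs(ft$slope - 0.02) > 3 * se) misses <- misses + 1L
  }
  expect_lte(misses, 5L)   # ~0.3% nominal miss rate; allow slack at n = 100
})
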