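uniform_mat <- function(n) matrix(0.1, n, 10)

test_that("quartile partition sizes and ordering", {
  Tm <- uniform_mat(8); Pm <- uniform_mat(8)
  p8 <- pairs_from_matrices(Tm, Pm, similarity = seq(10, 80, by = 10))
  q <- quartile_partition(p8)
  expect_equal(as.vector(table(q)), rep(2L, 4))
  expect_equal(as.character(q[p8$similarity_pct >= 70]), rep("Q1", 2))
  expect_equal(as.character(q[p8$similarity_pct <= 20]), rep("Q4", 2))

  ties <- pairs_from_matrices(uniform_mat(9), uniform_mat(9), similarity = 50)
  qt <- quartile_partition(ties)
  expect_lte(diff(range(table(qt))), 1)
  expect_identical(quartile_partition(ties), qt)  # stable under ties

  set.seed(10)
  p160 <- pairs_from_matrices(uniform_mat(160), uniform_mat(160),
                              similarity = runif(160, 0, 100))
  expect_equal(as.vector(table(quartile_partition(p160))), rep(40L, 4))
  expect_error(quartile_partition(p160[1:3, ]), "at least 4")
})

test_that("detrending centres every state exactly and kills shuffled correlation", {
  set.seed(11)
  Tm <- t(replicate(60, rand_abundance()))
  Pm <- t(replicate(60, rand_abundance()))
  d <- detrend_abundances(pairs_from_matrices(Tm, Pm))
  for (i in 1:10) {
    expect_lt(abs(mean(d[[paste0("tutor_p", i)]])), 1e-12)
    expect_lt(abs(mean(d[[paste0("pupil_p", i)]])), 1e-12)
  }
  uni <- detrend_abundances(pairs_from_matrices(uniform_mat(5),
                                                uniform_mat(5)))
  expect_true(all(abs(as.matrix(uni[, paste0("tutor_p", 1:10)])) < 1e-12))

  # shuffling the pairing of detrended birds leaves ~zero correlation
  Td <- as.matrix(d[, paste0("tutor_p", 1:10)])
  Pd <- as.matrix(d[, paste0("pupil_p", 1:10)])
  set.seed(12)
  cors <- replicate(400, cor(as.vector(Td[sample(nrow(Td)), ]),
                             as.vector(Pd)))
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.01)
})

test_that("abundance regression recovers generating slopes", {
  set.seed(13)
  Tm <- t(replicate(80, rand_abundance()))
  ident <- abundance_regression(pairs_from_matrices(Tm, Tm))
  expect_equal(ident$slope, 1, tolerance = 1e-9)
  expect_equal(ident$residual_R2, 1, tolerance = 1e-9)

  Pm_ind <- t(replicate(200, rand_abundance()))
  Tm_ind <- t(replicate(200, rand_abundance()))
  indep <- abundance_regression(pairs_from_matrices(Tm_ind, Pm_ind))
  expect_lt(indep$residual_R2, 0.05)

  Tm2 <- t(replicate(200, rand_abundance()))
  noise <- matrix(rnorm(2000, 0, 0.01), 200, 10)
  Pm2 <- 0.5 * Tm2 + 0.5 * 0.1 + noise
  Pm2 <- Pm2 / rowSums(Pm2)
  mix <- abundance_regression(pairs_from_matrices(Tm2, Pm2))
  expect_lt(abs(mix$slope - 0.5), 0.1)

  expect_error(abundance_regression(pairs_from_matrices(uniform_mat(5),
                                                        uniform_mat(5))),
               "degenerate")
})

test_that("cluster bootstrap and mixed-model backends run", {
  set.seed(14)
  Tm <- t(replicate(40, rand_abundance()))
  Pm <- 0.7 * Tm + 0.3 * 0.1
  Pm <- Pm / rowSums(Pm)
  pr <- pairs_from_matrices(Tm, Pm)
  boot <- abundance_regression(pr, cluster_boot = 50, seed = 2)
  expect_gt(boot$slope_se_boot, 0)
  if (requireNamespace("lme4", quietly = TRUE)) {
    lm2 <- abundance_regression(pr, method = "lmer")
    expect_lt(abs(lm2$slope - boot$slope), 0.15)
  }
})

test_that("diagonal bias: exact imitation, concentrated tutors, undefined cases", {
  set.seed(15)
  Tm <- t(replicate(20, rand_abundance()))
  same <- diagonal_bias(pairs_from_matrices(Tm, Tm))
  expect_equal(same$statistic, 0)

  conc_T <- matrix(rep(c(0.9, rep(0.1 / 9, 9)), 10), 10, byrow = TRUE)
  conc <- diagonal_bias(pairs_from_matrices(conc_T, uniform_mat(10)))
  expect_equal(conc$observed_bias, 1)
  expect_equal(conc$reverse_bias, 0)

  low <- matrix(0.1, 2, 10)
  expect_error(diagonal_bias(pairs_from_matrices(low, low), threshold = 0.5),
               "undefined")
})

test_that("balancing colonies show a positive diagonal bias detected by the shuffle test", {
  col <- simulate_colony(colony_spec(n_pairs = 100, balancing_exponent = 0.5,
                                     seed = 16))
  b <- direction_shuffle_test(col$pairs, n_shuffles = 1000, seed = 4)
  expect_gt(b$statistic, 0)
  expect_lte(b$p_value, 0.05)
  expect_error(direction_shuffle_test(col$pairs, n_shuffles = 0), "at least 100")
})

test_that("direction shuffle p-values are well-calibrated on role-symmetric data", {
  # colonies without balancing (beta = 1), roles randomly pre-swapped so the
  # pair direction carries no information
  set.seed(17)
  swap_roles <- function(df, swap) {
    tc <- paste0("tutor_p", 1:10); pc <- paste0("pupil_p", 1:10)
    tmp <- df[swap, tc]; df[swap, tc] <- df[swap, pc]; df[swap, pc] <- tmp
    df
  }
  ps <- replicate(11, {
    col <- simulate_colony(colony_spec(n_pairs = 60, balancing_exponent = 1,
                                       seed = sample.int(1e6, 1)))
    df <- swap_roles(col$pairs, runif(60) < 0.5)
    direction_shuffle_test(df, n_shuffles = 200,
                           seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(median(ps), 0.2)
  expect_lte(median(ps), 0.8)
})

test_that("gain curve reproduces the worked example and the identity case", {
  Tm <- rbind(c(0.08, 0.10, 0.12, 0.70, rep(0, 6)))
  Pm <- rbind(c(0.15, 0.20, 0.25, 0.40, rep(0, 6)))
  g <- gain_curve(pairs_from_matrices(Tm, Pm))
  expect_equal(g$gain[g$bin_center == 0.1], 2)
  expect_equal(g$median_pupil[g$bin_center == 0.1], 0.2)

  set.seed(18)
  Tm2 <- t(replicate(50, rand_abundance()))
  gid <- gain_curve(pairs_from_matrices(Tm2, Tm2))
  for (k in seq_len(nrow(gid))) {
    ct <- gid$bin_center[k]
    expect_gte(gid$gain[k], (ct - 0.05) / ct - 1e-9)
    expect_lte(gid$gain[k], (ct + 0.05) / ct + 1e-9)
  }
})

test_that("flattening colonies amplify rare states and attenuate common ones", {
  col <- simulate_colony(colony_spec(n_pairs = 100, balancing_exponent = 0.6,
                                     seed = 19))
  g <- gain_curve(col$pairs, bin_width = 0.05)
  g <- g[g$n >= 10, ]
  expect_gt(g$gain[g$bin_center == 0.05], 1)
  hi <- g[g$bin_center > 0.15, ]
  expect_true(all(hi$gain < 1))
})

test_that("gain-curve slopes order the balancing exponents", {
  slopes <- vapply(c(0.6, 0.8, 1.0), function(beta) {
    col <- simulate_colony(colony_spec(n_pairs = 100,
                                       balancing_exponent = beta, seed = 11))
    g <- gain_curve(col$pairs)
    g <- g[g$n >= 5, ]
    unname(coef(lm(log(gain) ~ log(bin_center / 0.1), data = g))[2])
  }, 0)
  expect_true(slopes[1] < slopes[2] && slopes[2] < slopes[3])
})

test_that("pooled quartile diversity: identity, concavity and colony contrast", {
  Tm <- t(replicate(12, c(0.5, 0.5, rep(0, 8))))
  same <- pooled_quartile_diversity(pairs_from_matrices(Tm, Tm))
  expect_equal(same$bottom_pooled_bits, 1, tolerance = 1e-9)
  expect_equal(same$top_pooled_bits, same$top_mean_bits, tolerance = 1e-9)

  # disjoint low-diversity morphs pool to more than their mean
  morphs <- do.call(rbind, lapply(1:12, function(i) {
    p <- rep(0, 10); p[(i %% 5) + 1] <- 1; p
  }))
  mix <- pooled_quartile_diversity(pairs_from_matrices(morphs, morphs))
  expect_gt(mix$bottom_pooled_bits, mix$bottom_mean_bits)

  col <- simulate_colony(colony_spec(n_pairs = 120, seed = 20))
  pq <- pooled_quartile_diversity(col$pairs, by = "tutor_diversity")
  expect_lt(pq$bottom_pooled_bits, pq$top_pooled_bits)
  expect_error(pooled_quartile_diversity(col$pairs[1:4, ]), "at least 8")
})

test_that("mean song features average voiced windows", {
  fs <- 44100
  tone <- audio_clip(0.6 * sin(2 * pi * 1000 * seq_len(fs / 5) / fs), fs)
  mf <- mean_song_features(compute_features(tone))
  expect_lt(abs(mf["mean_pitch"] - 1000) / 1000, 0.02)

  two <- audio_clip(c(0.6 * sin(2 * pi * 500 * seq_len(fs / 5) / fs),
                      numeric(fs %/% 20),
                      0.6 * sin(2 * pi * 1500 * seq_len(fs / 5) / fs)), fs)
  mf2 <- mean_song_features(compute_features(two))
  expect_lt(abs(mf2["mean_pitch"] - 1000), 60)
  expect_error(mean_song_features(
    compute_features(audio_clip(rep(1e-9, fs %/% 10), fs))), "silent")
})

test_that("influence feature ranges: nesting, degenerate and single-pair cases", {
  set.seed(21)
  n <- 16
  # low-influence tutors are pitch-extreme; top quartile is pitch-central
  infl <- c(rep(90, 4), rep(60, 8), rep(10, 4))
  pitch <- c(rnorm(4, 1200, 50), rnorm(8, 1400, 200),
             c(2600, 2800, 500, 450))
  pr <- pairs_from_matrices(uniform_mat(n), uniform_mat(n))
  pr$influence_pct <- infl
  feats <- data.frame(bird_id = pr$tutor_id, mean_pitch = pitch,
                      mean_fm = 5, mean_entropy = -2)
  rg <- influence_feature_ranges(pr, feats)
  top <- rg[rg$feature == "mean_pitch" & rg$quartile == "top", ]
  bot <- rg[rg$feature == "mean_pitch" & rg$quartile == "bottom", ]
  expect_gt(top$lo, bot$lo)
  expect_lt(top$hi, bot$hi)

  feats2 <- data.frame(bird_id = pr$tutor_id, mean_pitch = 1000,
                       mean_fm = 5, mean_entropy = -2)
  rg2 <- influence_feature_ranges(pr, feats2)
  expect_true(all(rg2$lo == rg2$hi))

  pr4 <- pr[1:4, ]; pr4$influence_pct <- c(80, 60, 40, 20)
  rg3 <- influence_feature_ranges(pr4, feats[1:4, ])
  expect_true(all(rg3$lo == rg3$hi))
})

test_that("reversal table reports per-tutor direction of diversity change", {
  Tm <- t(replicate(6, rand_abundance()))
  same <- reversal_table(pairs_from_matrices(Tm, Tm))
  expect_true(all(same$direction == "tie"))

  pr <- pairs_from_matrices(uniform_mat(2), uniform_mat(2))
  pr$tutor_id <- "T1"
  pr$tutor_diversity_bits <- 3.0
  pr$pupil_diversity_bits <- c(3.0 - 0.05, 3.0 + 0.05)
  rt <- reversal_table(pr)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$mean_pupil_diversity_bits, 3.0, tolerance = 1e-12)

  col <- simulate_colony(colony_spec(n_pairs = 120,
                                     balancing_exponent = 0.6, seed = 22))
  rt2 <- reversal_table(col$pairs)
  low <- rt2[rt2$tutor_diversity_bits <
               median(rt2$tutor_diversity_bits), ]
  expect_gt(mean(low$direction == "increase"), 0.5)
})

test_that("family CV analysis: degenerate and closed-form cases", {
  pr <- pairs_from_matrices(uniform_mat(8), uniform_mat(8), similarity = 70)
  pr$lineage_id <- rep(c("A", "B"), each = 4)
  pr$clutch_id <- rep(c("A1", "A2", "B1", "B2"), each = 2)
  fc <- family_cv_analysis(pr)
  expect_true(all(fc$within$cv == 0))
  expect_equal(fc$across_cv, 0)

  pr$similarity_pct <- rep(c(40, 80), each = 4)
  fc2 <- family_cv_analysis(pr)
  expect_true(all(fc2$within$cv == 0))
  expect_equal(fc2$across_cv, sd(c(40, 80)) / 60, tolerance = 1e-12)

  pr$lineage_id <- "A"; pr$clutch_id <- "A1"
  expect_error(family_cv_analysis(pr), "two clutches")

  col <- simulate_colony(colony_spec(n_pairs = 150, seed = 23))
  fc3 <- family_cv_analysis(col$pairs)
  expect_gt(fc3$across_cv, mean(fc3$within$cv))
})

test_that("Bonferroni utility adjusts and flags at the 0.01 level", {
  out <- bonferroni_adjust(c(0.001, 0.004, 0.2))
  expect_equal(out$p_adj, pmin(1, c(0.003, 0.012, 0.6)))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
})
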