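test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(rep(0.1, 10)), log2(10), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(rep(0.2, 5), rep(0, 5))), log2(5),
               tolerance = 1e-12)
  one <- c(1, rep(0, 9))
  expect_equal(shannon_diversity(one), 0)
  expect_error(shannon_diversity(c(rep(0.2, 4), 0.1, rep(0, 5), 0.1)[1:10] * 2),
               "sum to 1")
})

test_that("entropy is bounded, permutation-invariant and concave under pooling", {
  set.seed(5)
  for (i in 1:50) {
    p <- rand_abundance()
    h <- shannon_diversity(p)
    expect_gte(h, 0)
    expect_lte(h, log2(10) + 1e-12)
    expect_equal(shannon_diversity(sample(p)), h, tolerance = 1e-12)
  }
  for (i in 1:25) {
    vs <- lapply(1:4, function(j)
      abundance_vector(rand_abundance(), sample(500:3000, 1)))
    w <- vapply(vs, function(v) v$n_windows, 0)
    mean_h <- sum(w * vapply(vs, shannon_diversity, 0)) / sum(w)
    expect_gte(pooled_diversity(vs) - mean_h, -1e-12)
  }
})

test_that("pooled diversity edge cases", {
  a <- abundance_vector(c(1, rep(0, 9)), 100)
  b <- abundance_vector(c(0, 1, rep(0, 8)), 100)
  expect_equal(pooled_diversity(list(a, b)), 1)
  expect_equal(shannon_diversity(a), 0)
  same <- abundance_vector(rand_abundance(), 200)
  expect_equal(pooled_diversity(list(same, same)), shannon_diversity(same))
  expect_error(pooled_diversity(list()), "no abundance")
})

test_that("state abundances count states and normalise", {
  expect_equal(state_abundances(c(1, 1, 2, 2))$p,
               c(.5, .5, rep(0, 8)))
  expect_equal(state_abundances(rep(7L, 12))$p[7], 1)
  expect_error(state_abundances(integer(0)), "empty")
  set.seed(6)
  s <- sample(1:10, 1000, replace = TRUE)
  p <- state_abundances(s)$p
  expect_true(all(abs(p - 0.1) < 4 * sqrt(0.1 * 0.9 / 1000)))
})

test_that("partition recovers a known 10-cluster feature-space template", {
  pop <- template_population()
  part <- fit_partition(pop$track, partition_config(min_windows = 5000))
  seqs <- assign_states(pop$track, part)
  expect_gte(mean(seqs$states == pop$states), 0.95)
})

test_that("pitch edges land near the true density minima between modes", {
  pop <- template_population(n_per_state = 2000, seed = 8)
  part <- fit_partition(pop$track, partition_config(min_windows = 5000))
  # true minima of the generating mixture: midway between adjacent modes,
  # found by brute-force search on the analytic density
  modes <- c(500, 900, 1600, 2700)
  wts <- c(0.2, 0.3, 0.3, 0.2)
  dens <- function(x) colSums(wts * sapply(x, function(xx)
    stats::dnorm(xx, modes, 60)) )
  for (k in 1:3) {
    grid <- seq(modes[k], modes[k + 1], by = 1)
    true_min <- grid[which.min(dens(grid))]
    expect_lt(abs(part$pitch_edges[k] - true_min) / true_min, 0.10)
  }
})

test_that("degenerate pitch distributions are rejected", {
  flat <- feature_track(pitch_hz = rep(1000, 12000),
                        fm_deg = rnorm(12000), wiener_entropy = -1)
  expect_error(fit_partition(flat), "degenerate")
  small <- feature_track(pitch_hz = rnorm(100, 1000, 50),
                         fm_deg = rnorm(100), wiener_entropy = -1)
  expect_error(fit_partition(small), "too few")
})

test_that("assignment is exhaustive, deterministic and respects the tie rule", {
  pop <- template_population()
  part <- fit_partition(pop$track, partition_config(min_windows = 5000))
  # 10,000 random windows anywhere in the fitted pitch range never fail
  set.seed(9)
  rnd <- feature_track(pitch_hz = runif(10000, 320, 2950),
                       fm_deg = abs(rnorm(10000, 0, 8)),
                       fm_sign = sample(c(-1L, 0L, 1L), 10000, TRUE),
                       wiener_entropy = -runif(10000, 0, 5))
  s <- assign_states(rnd, part)
  expect_true(all(s$states %in% 1:10))
  expect_identical(assign_states(rnd, part)$states, s$states)

  # windows placed exactly at the fitted centres map to their own labels
  centre_rows <- do.call(rbind, lapply(1:4, function(r) {
    rg <- part$regions[[r]]
    mid <- mean(if (r == 1) c(320, part$pitch_edges[1]) else
      if (r == 4) c(part$pitch_edges[3], 2950) else
        part$pitch_edges[c(r - 1, r)])
    data.frame(pitch = mid, fms = rg$centers[, 1] * rg$scale[1],
               went = rg$centers[, 2] * rg$scale[2], label = rg$labels)
  }))
  tr <- feature_track(pitch_hz = centre_rows$pitch,
                      fm_deg = abs(centre_rows$fms),
                      fm_sign = sign(centre_rows$fms),
                      wiener_entropy = pmin(0, centre_rows$went))
  got <- assign_states(tr, part)$states
  # entropy centres can sit above 0 before clipping; compare where valid
  valid <- centre_rows$went <= 0
  expect_equal(got[valid], centre_rows$label[valid])

  expect_error(assign_states(feature_track(1000, 1, -1, voiced = FALSE),
                             part), "silent")
})

test_that("hand-specified partitions load from JSON and break ties downward", {
  spec <- list(schema = "finchsong/state_partition/1",
               pitch_edges = c(700, 1300, 2100),
               states_per_region = c(2L, 3L, 3L, 2L),
               regions = list(
                 list(centers = rbind(c(-1, -1), c(1, -1)),
                      scale = c(1, 1), labels = c(1L, 2L)),
                 list(centers = rbind(c(-1, -1), c(0, -1), c(1, -1)),
                      scale = c(1, 1), labels = c(3L, 4L, 5L)),
                 list(centers = rbind(c(-1, -1), c(0, -1), c(1, -1)),
                      scale = c(1, 1), labels = c(6L, 7L, 8L)),
                 list(centers = rbind(c(-1, -1), c(1, -1)),
                      scale = c(1, 1), labels = c(9L, 10L))),
               config = list(), n_windows = 0)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  part <- read_partition(path)
  expect_equal(part$pitch_edges, c(700, 1300, 2100))
  # exactly equidistant between region-1 centres: lower label wins
  eq <- feature_track(pitch_hz = 500, fm_deg = 0, fm_sign = 0,
                      wiener_entropy = -1)
  expect_equal(assign_states(eq, part)$states, 1L)
  # and windows at the centres map to their own labels
  at <- feature_track(pitch_hz = c(500, 500, 1000, 1000, 1000),
                      fm_deg = c(1, 1, 1, 0, 1), fm_sign = c(-1, 1, -1, 0, 1),
                      wiener_entropy = -1)
  expect_equal(assign_states(at, part)$states, c(1L, 2L, 3L, 4L, 5L))
  unlink(path)
})

test_that("partitions survive a JSON round-trip", {
  pop <- template_population()
  part <- fit_partition(pop$track, partition_config(min_windows = 5000))
  path <- tempfile(fileext = ".json")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(back$pitch_edges, part$pitch_edges, tolerance = 1e-12)
  s1 <- assign_states(pop$track, part)$states
  s2 <- assign_states(pop$track, back)$states
  expect_identical(s1, s2)
  unlink(path)
})

test_that("audio corpus: fitted partition recovers generating states and abundances", {
  sc <- state_corpus()
  tot <- 0; correct <- 0
  for (b in seq_along(sc$tracks)) {
    s <- assign_states(sc$tracks[[b]], sc$partition)
    ok <- !is.na(sc$truth[[b]])
    tot <- tot + sum(ok)
    correct <- correct + sum(s$states[ok] == sc$truth[[b]][ok])
  }
  expect_gte(correct / tot, 0.9)
})
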