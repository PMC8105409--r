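test_that("segmentation finds generator syllables with tight boundaries", {
  arch <- state_archetypes(90)
  sp <- song_spec(arch[c(1, 4, 7, 9, 5)], gap_ms = 30, n_repeats = 1,
                  seed = 41)
  clip <- synth_song(sp)
  tab <- segment_syllables(compute_features(clip))
  truth <- attr(clip, "syllables")
  expect_equal(nrow(tab), 5)
  expect_lt(max(abs(tab$onset_s - truth$onset_s)), 0.005)
  expect_lt(max(abs(tab$offset_s - truth$offset_s)), 0.005)
})

test_that("a continuous tone is one syllable; silence is none", {
  fs <- 44100
  tone <- audio_clip(0.5 * sin(2 * pi * 800 * seq_len(fs / 2) / fs), fs)
  expect_equal(nrow(segment_syllables(compute_features(tone))), 1)
  sil <- audio_clip(rep(1e-9, fs / 4), fs)
  expect_equal(nrow(segment_syllables(compute_features(sil))), 0)
})

test_that("clustering recovers three well-separated archetypes, 20 tokens each", {
  centers <- rbind(c(80, 600, 5, -2.5, 0.9),
                   c(150, 1600, 1, -4.0, 0.95),
                   c(60, 2700, 8, -0.8, 0.3))
  tab <- fake_syllable_table(centers, n_each = 20)
  out <- cluster_types(tab)
  expect_equal(sort(unique(out$type)), 1:3)
  expect_equal(unname(as.vector(table(out$type))), c(20, 20, 20))
  # labels agree with the generating archetype (same partition)
  expect_equal(length(unique(paste(out$type, attr(tab, "truth")))), 3)
})

test_that("identical syllables form a single type and tiny tables do not error", {
  centers <- rbind(c(100, 900, 3, -2, 0.8))
  tab <- fake_syllable_table(centers, n_each = 10, jitter = 0.001)
  expect_equal(unique(cluster_types(tab)$type), 1L)
  one <- tab[1, , drop = FALSE]
  class(one) <- c("syllable_table", "data.frame")
  expect_equal(cluster_types(one)$type, 1L)
})

test_that("cluster partition is invariant to row order", {
  centers <- rbind(c(80, 600, 5, -2.5, 0.9),
                   c(150, 1600, 1, -4.0, 0.95),
                   c(60, 2700, 8, -0.8, 0.3))
  tab <- fake_syllable_table(centers, n_each = 15, seed = 6)
  out1 <- cluster_types(tab)
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  class(tab2) <- c("syllable_table", "data.frame")
  out2 <- cluster_types(tab2)
  # same partition: co-membership agrees after inverting the permutation
  expect_equal(out2$type, out1$type[perm])
})

test_that("type diversity matches closed forms", {
  mk <- function(types) {
    n <- length(types)
    structure(data.frame(onset_s = as.numeric(seq_len(n)),
                         offset_s = seq_len(n) + 0.1,
                         duration_ms = rep(100, n), mean_pitch = rep(1, n),
                         mean_fm = rep(1, n),
                         mean_wiener_entropy = rep(-1, n),
                         mean_continuity = rep(1, n),
                         type = types, bout = rep(1L, n)),
              class = c("syllable_table", "data.frame"))
  }
  expect_equal(type_diversity(mk(rep(1:4, 5))), 2)
  expect_equal(type_diversity(mk(rep(1, 7))), 0)
  expect_equal(type_diversity(mk(c(1, 1, 2, 3))), 1.5)
  expect_error(type_diversity(mk(integer(0))), "empty")
  expect_error(type_diversity(mk(c(NA_integer_, 1L))), "not assigned")
})

test_that("syntax entropy: cycles, repeats, uniform transitions", {
  mk <- function(types, bout = 1L) {
    n <- length(types)
    structure(data.frame(onset_s = as.numeric(seq_len(n)),
                         offset_s = seq_len(n) + 0.1,
                         duration_ms = rep(100, n), mean_pitch = rep(1, n),
                         mean_fm = rep(1, n),
                         mean_wiener_entropy = rep(-1, n),
                         mean_continuity = rep(1, n),
                         type = types, bout = rep(bout, length.out = n)),
              class = c("syllable_table", "data.frame"))
  }
  # 30-syllable cycle has 29 transitions, so frequencies miss uniform by one
  expect_equal(syntax_entropy(mk(rep(1:3, 10))), log2(3), tolerance = 0.005)
  expect_equal(syntax_entropy(mk(rep(1L, 6))), 0)
  set.seed(8)
  expect_lt(abs(syntax_entropy(mk(sample(1:3, 3000, TRUE))) - log2(9)), 0.05)
  expect_error(syntax_entropy(mk(1L)), "at least 2")
  # bigrams never span bout boundaries
  two_bouts <- mk(c(1L, 2L, 1L, 2L), bout = c(1L, 1L, 2L, 2L))
  expect_equal(syntax_entropy(two_bouts), 0)  # only 1->2 transitions remain
})

test_that("recombination: fused tutor syllables in the pupil are merges", {
  null <- null_model()
  arch <- state_archetypes(100)
  tut <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(45, 45),
                              n_repeats = 3, seed = 21))
  mrg <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(0, 45),
                              n_repeats = 3, seed = 22))
  ft <- compute_features(tut); fm <- compute_features(mrg)
  st <- segment_syllables(ft); sm <- segment_syllables(fm)
  ev <- detect_recombination(ft, fm, st, sm, null)
  expect_true(all(ev$kind == "merge"))
  expect_gte(nrow(ev), 1)

  # anti-symmetry: swapping the roles turns merges into splits
  ev_rev <- detect_recombination(fm, ft, sm, st, null)
  expect_true(all(ev_rev$kind == "split"))
  expect_equal(nrow(ev_rev), nrow(ev))
})

test_that("recombination: a faithful pupil yields no events", {
  null <- null_model()
  arch <- state_archetypes(100)
  tut <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(45, 45),
                              n_repeats = 3, seed = 21))
  cp <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(45, 45),
                             n_repeats = 3, seed = 25))
  ft <- compute_features(tut); fc <- compute_features(cp)
  ev <- detect_recombination(ft, fc, segment_syllables(ft),
                             segment_syllables(fc), null)
  expect_equal(nrow(ev), 0)
})

test_that("recombination: a gap inserted mid-syllable is a split", {
  null <- null_model()
  arch <- state_archetypes(100)
  # tutor syllable = two fused elements; pupil opens a 30 ms gap inside it
  tut <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(0, 45),
                              n_repeats = 3, seed = 31))
  spl <- synth_song(song_spec(arch[c(1, 4, 9)], gaps_ms = c(30, 45),
                              n_repeats = 3, seed = 32))
  ft <- compute_features(tut); fs2 <- compute_features(spl)
  ev <- detect_recombination(ft, fs2, segment_syllables(ft),
                             segment_syllables(fs2), null)
  expect_true(all(ev$kind == "split"))
  expect_gte(nrow(ev), 1)
})
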