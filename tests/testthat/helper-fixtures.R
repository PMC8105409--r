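# Shared fixtures, built lazily and cached for the duration of the test run.
# Everything is generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

rand_abundance <- function() {
  p <- stats::rgamma(10, 5)
  p / sum(p)
}

# 20 unrelated synthetic birds + fitted similarity null
null_corpus <- function() fixture("null_corpus", function() {
  set.seed(4821)
  lapply(1:20, function(b) compute_features(synth_song(
    song_spec_for_abundance(rand_abundance(), seed = 1000 + b,
                            song_ms = 2000))))
})

null_model <- function() fixture("null_model", function() {
  build_null(null_corpus(), seed = 5, n_samples = 8000)
})

# the tutor ABC / pupil ABCDEF construction: three tutor elements (states
# 1, 4, 7) copied exactly, three improvised elements (6, 9, 10) of equal
# total duration, acoustically distant from the tutor's states
abc_pair <- function() fixture("abc_pair", function() {
  arch <- state_archetypes(100)
  tut <- synth_song(song_spec(arch[c(1, 4, 7)], gap_ms = 45,
                              n_repeats = 3, seed = 11))
  pup <- synth_song(song_spec(arch[c(1, 4, 7, 6, 9, 10)], gap_ms = 45,
                              n_repeats = 3, seed = 12))
  list(tutor = compute_features(tut), pupil = compute_features(pup))
})

# 12-bird audio corpus with per-window ground-truth states and a fitted
# partition (used by the vocal-state and end-to-end tests)
state_corpus <- function() fixture("state_corpus", function() {
  set.seed(42)
  tracks <- list(); truth <- list()
  for (b in 1:12) {
    clip <- synth_song(song_spec_for_abundance(rand_abundance(), seed = b,
                                               song_ms = 3200))
    trk <- compute_features(clip)
    el <- attr(clip, "elements")
    st <- rep(NA_integer_, nrow(trk))
    for (r in seq_len(nrow(el)))
      st[trk$time_s >= el$onset_s[r] + 0.012 &
           trk$time_s <= el$offset_s[r] - 0.012] <- el$state[r]
    tracks[[b]] <- trk
    truth[[b]] <- st[trk$voiced]
  }
  list(tracks = tracks, truth = truth, partition = fit_partition(tracks))
})

# synthetic feature-space population drawn from a known 10-cluster template
template_population <- function(n_per_state = 1500, seed = 7) {
  set.seed(seed)
  pitch_mode <- c(500, 500, 900, 900, 900, 1600, 1600, 1600, 2700, 2700)
  fms_c <- c(-6, 6, -6, 0, 6, -7, 0, 7, -6, 6)
  went_c <- c(-2.7, -2.7, -2.3, -3.9, -0.9, -0.8, -3.9, -0.8, -2.2, -2.2)
  st <- rep(1:10, each = n_per_state)
  pitch <- stats::rnorm(length(st), pitch_mode[st], 60)
  fms <- stats::rnorm(length(st), fms_c[st], 1.2)
  went <- pmin(0, stats::rnorm(length(st), went_c[st], 0.3))
  track <- feature_track(pitch_hz = pmax(320, pitch), fm_deg = abs(fms),
                         fm_sign = sign(fms), wiener_entropy = went)
  list(track = track, states = st)
}

# fabricated syllable table from k archetype centres (clustering unit tests)
fake_syllable_table <- function(centers, n_each = 20, jitter = 0.03,
                                seed = 3) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    M <- matrix(rep(as.numeric(centers[k, ]), n_each), nrow = n_each,
                byrow = TRUE)
    M * (1 + jitter * matrix(stats::runif(length(M), -1, 1), nrow = n_each))
  }))
  n <- nrow(rows)
  ord <- sample.int(n)
  out <- data.frame(onset_s = seq_len(n) * 0.2,
                    offset_s = seq_len(n) * 0.2 + 0.1,
                    duration_ms = rows[ord, 1], mean_pitch = rows[ord, 2],
                    mean_fm = rows[ord, 3], mean_wiener_entropy = rows[ord, 4],
                    mean_continuity = rows[ord, 5],
                    type = NA_integer_, bout = 1L)
  attr(out, "truth") <- rep(seq_len(nrow(centers)), each = n_each)[ord]
  class(out) <- c("syllable_table", "data.frame")
  out
}

# minimal pairs table from tutor/pupil abundance matrices
pairs_from_matrices <- function(Tm, Pm, similarity = NULL) {
  n <- nrow(Tm)
  df <- data.frame(tutor_id = sprintf("T%03d", seq_len(n)),
                   pupil_id = sprintf("P%03d", seq_len(n)),
                   relation = "biological",
                   clutch_id = "C1", lineage_id = "L1",
                   similarity_pct = if (is.null(similarity)) 50 else similarity,
                   influence_pct = 50,
                   tutor_diversity_bits = apply(Tm, 1, shannon_diversity),
                   pupil_diversity_bits = apply(Pm, 1, shannon_diversity))
  df[, paste0("tutor_p", 1:10)] <- Tm
  df[, paste0("pupil_p", 1:10)] <- Pm
  df
}
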