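#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

normalize_p <- function(p) {
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) stop("abundance vector sums to zero")
  p / s
}

#' Specification of one synthetic syllable element
#'
#' A syllable element is a harmonic stack with a linear fundamental
#' trajectory, mixed with broadband noise. \code{noise_fraction} controls
#' Wiener entropy (0 = pure harmonic, 1 = pure noise); \code{amplitude_db}
#' shifts the rendered level relative to the generator's default.
#'
#' @param duration_ms Element duration, >= 20 ms.
#' @param f0_start_hz,f0_end_hz Fundamental frequency endpoints, 300-3000 Hz.
#' @param n_harmonics Number of harmonics (amplitudes 1/k).
#' @param noise_fraction Noise power fraction in \code{[0, 1]}.
#' @param amplitude_db Level offset in dB (0 = default level).
#' @param state Optional integer label of the vocal state this element is
#'   designed to occupy (generator ground truth).
#' @return A list of class \code{syllable_spec}.
#' @export
syllable_spec <- function(duration_ms, f0_start_hz, f0_end_hz,
                          n_harmonics = 3, noise_fraction = 0.05,
                          amplitude_db = 0, state = NA_integer_) {
  if (duration_ms < 20) stop("syllable duration must be >= 20 ms")
  if (f0_start_hz < 300 || f0_start_hz > 3000 ||
      f0_end_hz < 300 || f0_end_hz > 3000)
    stop("fundamental must lie in 300-3000 Hz")
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must be in [0, 1]")
  structure(list(duration_ms = duration_ms, f0_start_hz = f0_start_hz,
                 f0_end_hz = f0_end_hz, n_harmonics = n_harmonics,
                 noise_fraction = noise_fraction, amplitude_db = amplitude_db,
                 state = as.integer(state)),
            class = "syllable_spec")
}

#' Specification of a synthetic song
#'
#' A song is a motif of syllable elements repeated \code{n_repeats} times.
#' Junction gaps within the motif come from \code{gaps_ms} (length one less
#' than the motif); a gap of 0 fuses adjacent elements into a single
#' amplitude-threshold syllable, so composite syllables can traverse several
#' vocal states while the motif keeps 2-6 syllable units.
#'
#' @param motif List of \code{\link{syllable_spec}}.
#' @param gap_ms Default gap between syllables and between motif repeats, ms.
#' @param gaps_ms Optional per-junction gaps within the motif.
#' @param n_repeats Number of motif repetitions.
#' @param seed Integer seed controlling the noise realisation.
#' @return A list of class \code{song_spec}.
#' @export
song_spec <- function(motif, gap_ms = 40, gaps_ms = NULL, n_repeats = 3,
                      seed = 1) {
  if (length(motif) == 0L) stop("motif must be non-empty")
  stopifnot(all(vapply(motif, inherits, TRUE, "syllable_spec")))
  if (is.null(gaps_ms)) gaps_ms <- rep(gap_ms, max(0L, length(motif) - 1L))
  if (length(gaps_ms) != length(motif) - 1L)
    stop("gaps_ms must have one entry per within-motif junction")
  total_ms <- n_repeats * (sum(vapply(motif, `[[`, 0, "duration_ms")) +
                             sum(gaps_ms)) + (n_repeats - 1) * gap_ms
  if (total_ms > 10000) stop("song exceeds 10 s")
  structure(list(motif = motif, gap_ms = gap_ms, gaps_ms = gaps_ms,
                 n_repeats = n_repeats, seed = seed),
            class = "song_spec")
}

render_element <- function(sp, fs, band_top = 8600, ramp_on = TRUE,
                           ramp_off = TRUE) {
  n <- round(sp$duration_ms / 1000 * fs)
  tt <- seq_len(n) / fs
  f0 <- sp$f0_start_hz + (sp$f0_end_hz - sp$f0_start_hz) * (tt - tt[1]) /
    (sp$duration_ms / 1000)
  phase <- 2 * pi * cumsum(f0) / fs
  harm <- numeric(n)
  for (k in seq_len(sp$n_harmonics)) {
    if (k * max(f0) > min(band_top, fs / 2 * 0.95)) break
    harm <- harm + sin(k * phase) / k
  }
  if (stats::sd(harm) > 0) harm <- harm / stats::sd(harm)
  noise <- stats::rnorm(n)
  noise <- noise / stats::sd(noise)
  y <- sqrt(1 - sp$noise_fraction) * harm + sqrt(sp$noise_fraction) * noise
  # 5 ms raised-cosine ramps at syllable boundaries only (fused element
  # junctions must not dip below the amplitude threshold)
  nr <- min(round(0.005 * fs), n %/% 2L)
  if (nr > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    if (ramp_on) y[seq_len(nr)] <- y[seq_len(nr)] * ramp
    if (ramp_off) y[(n - nr + 1L):n] <- y[(n - nr + 1L):n] * rev(ramp)
  }
  0.25 * 10^(sp$amplitude_db / 20) * y
}

#' Render a synthetic song to audio
#'
#' Deterministic given \code{spec$seed}. Ground-truth syllable boundaries
#' (elements fused across zero-length gaps) and per-element intervals with
#' their designed vocal states are attached as attributes
#' \code{"syllables"} and \code{"elements"}.
#'
#' @param spec A \code{\link{song_spec}}.
#' @param sample_rate Sampling rate, Hz.
#' @param pad_ms Leading/trailing silence, ms.
#' @return An \code{\link{audio_clip}} with truth attributes.
#' @export
synth_song <- function(spec, sample_rate = 44100, pad_ms = 60) {
  stopifnot(inherits(spec, "song_spec"))
  fs <- sample_rate
  with_seed(spec$seed, {
    pieces <- list(numeric(round(pad_ms / 1000 * fs)))
    el <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                     state = integer(0), syllable = integer(0))
    t_cur <- pad_ms / 1000
    syl_id <- 0L
    m <- length(spec$motif)
    for (r in seq_len(spec$n_repeats)) {
      for (i in seq_len(m)) {
        new_syl <- i == 1L || spec$gaps_ms[i - 1L] > 0
        if (new_syl) syl_id <- syl_id + 1L
        sp <- spec$motif[[i]]
        gap_after <- if (i < m) spec$gaps_ms[i] else spec$gap_ms
        y <- render_element(sp, fs, ramp_on = new_syl,
                            ramp_off = gap_after > 0)
        pieces[[length(pieces) + 1L]] <- y
        el <- rbind(el, data.frame(onset_s = t_cur,
                                   offset_s = t_cur + length(y) / fs,
                                   state = sp$state, syllable = syl_id))
        t_cur <- t_cur + length(y) / fs
        gap <- gap_after
        if (r == spec$n_repeats && i == m) gap <- pad_ms
        if (gap > 0) {
          pieces[[length(pieces) + 1L]] <- numeric(round(gap / 1000 * fs))
          t_cur <- t_cur + round(gap / 1000 * fs) / fs
        }
      }
    }
    x <- unlist(pieces, use.names = FALSE)
    pk <- max(abs(x))
    if (pk > 0.95) x <- x * 0.95 / pk
    clip <- audio_clip(x, fs)
    syl <- do.call(rbind, lapply(split(el, el$syllable), function(d)
      data.frame(onset_s = min(d$onset_s), offset_s = max(d$offset_s))))
    rownames(syl) <- NULL
    attr(clip, "syllables") <- syl
    attr(clip, "elements") <- el
    attr(clip, "spec") <- spec
    clip
  })
}

#' The ten vocal-state archetype elements
#'
#' One syllable element template per vocal state, arranged so the pooled
#' pitch density has four modes (very-low/low/medium/high fundamental) and,
#' within each pitch region, elements separate in the (signed FM, Wiener
#' entropy) plane: down- and up-modulated sweeps in the outer regions,
#' down/unmodulated/up elements in the two central regions, with the
#' unmodulated central elements (states 4 and 7) rendered as clean harmonic
#' stacks and the up-modulated central elements (5 and 8) noisier.
#'
#' @param duration_ms Default element duration, ms.
#' @return List of 10 \code{\link{syllable_spec}} templates, states 1-10.
#' @export
state_archetypes <- function(duration_ms = 80) {
  d <- duration_ms
  list(
    syllable_spec(d, 590, 395, 3, 0.05, state = 1),    # very low, down
    syllable_spec(d, 395, 590, 3, 0.05, state = 2),    # very low, up
    syllable_spec(d, 1100, 730, 3, 0.05, state = 3),   # low, down
    syllable_spec(d, 890, 890, 2, 0.01, state = 4),    # low, sparse stack
    syllable_spec(d, 730, 1100, 3, 0.45, state = 5),   # low, up, noisy
    syllable_spec(d, 1950, 1330, 3, 0.45, state = 6),  # medium, down, noisy
    syllable_spec(d, 1600, 1600, 2, 0.01, state = 7),  # medium, sparse stack
    syllable_spec(d, 1330, 1950, 3, 0.45, state = 8),  # medium, up, noisy
    syllable_spec(d, 2980, 2380, 2, 0.05, state = 9),  # high, down
    syllable_spec(d, 2380, 2980, 2, 0.05, state = 10)) # high, up
}

#' Sample a 10-state abundance vector with a prescribed Shannon diversity
#'
#' Draws a random direction on the simplex and applies the power transform
#' \code{p^gamma} (renormalised), solving for the exponent that attains the
#' requested entropy. Used to emulate the observed left-tailed song
#' diversity distribution.
#'
#' @param diversity_bits Target entropy in bits, in (0, 3.3219].
#' @param n_states Number of states.
#' @return Abundance vector of length \code{n_states}.
#' @export
abundance_for_diversity <- function(diversity_bits, n_states = 10) {
  if (diversity_bits <= 0 || diversity_bits > log2(n_states) + 1e-9)
    stop("diversity out of range")
  q <- normalize_p(stats::rgamma(n_states, shape = 5) + 1e-6)
  h <- function(g) shannon_diversity(normalize_p(q^g)) - diversity_bits
  if (h(0) < 0) stop("unreachable diversity")          # h(0) = log2(n)
  g_hi <- 1
  while (h(g_hi) > 0 && g_hi < 64) g_hi <- g_hi * 2
  if (h(g_hi) > 0) return(normalize_p(q^g_hi))
  g <- stats::uniroot(h, c(0, g_hi), tol = 1e-10)$root
  normalize_p(q^g)
}

#' Sample a tutor target diversity (bits)
#'
#' Left-tailed distribution with median ~3.1 bits and support truncated at
#' 2.3 bits, emulating the shape of colony song-diversity histograms.
#'
#' @param n Number of draws.
#' @return Numeric vector of diversities in bits.
#' @export
sample_tutor_diversity <- function(n) {
  3.3219 - pmin(stats::rgamma(n, shape = 2, rate = 7.63), 1.02)
}

#' Build a song specification realising a target abundance vector
#'
#' Allocates voiced time across the ten archetype elements in proportion to
#' \code{p_target} (states receiving less than one minimal element are
#' dropped), shuffles the elements, groups them into 2-6 amplitude-threshold
#' syllables by zeroing within-syllable gaps, and repeats the motif to reach
#' roughly \code{song_ms} of song.
#'
#' @param p_target Target abundance vector (length 10).
#' @param total_voiced_ms Voiced time per motif, ms.
#' @param song_ms Approximate total song length, ms.
#' @param f0_jitter Relative jitter applied to each element's fundamental
#'   (bird individuality).
#' @param dur_jitter,nf_jitter Relative jitter on element duration and
#'   noise fraction (bird individuality).
#' @param seed Integer seed.
#' @return A \code{\link{song_spec}} with attribute \code{"p_target"}.
#' @export
song_spec_for_abundance <- function(p_target, total_voiced_ms = 720,
                                    song_ms = 2800, f0_jitter = 0.08,
                                    dur_jitter = 0.2, nf_jitter = 0.5,
                                    seed = 1) {
  p_target <- normalize_p(p_target)
  with_seed(seed, {
    arch <- state_archetypes()
    min_el <- 24
    keep <- which(p_target * total_voiced_ms >= min_el)
    if (length(keep) == 0L) keep <- which.max(p_target)
    dur <- p_target[keep] * total_voiced_ms
    # chop long allocations into ~80 ms elements so sweep slopes (hence FM)
    # stay in the archetype range regardless of abundance
    keep <- rep(keep, pmax(1L, round(dur / 80)))
    dur <- unlist(lapply(dur, function(d) {
      k <- max(1L, round(d / 80)); rep(d / k, k)
    }))
    ord <- sample(seq_along(keep))
    keep <- keep[ord]; dur <- dur[ord]
    motif <- vector("list", length(keep))
    # one jitter per state per bird: the bird sings a consistent variant,
    # but different birds differ well beyond the copy jitter
    jmap <- lapply(1:10, function(s)
      list(f0 = 1 + f0_jitter * stats::runif(2, -1, 1),
           du = 1 + dur_jitter * stats::runif(1, -1, 1),
           nf = 1 + nf_jitter * stats::runif(1, -1, 1)))
    for (k in seq_along(keep)) {
      a <- arch[[keep[k]]]
      j <- jmap[[keep[k]]]
      motif[[k]] <- syllable_spec(max(24, dur[k] * j$du),
                                  min(3000, max(300, a$f0_start_hz * j$f0[1])),
                                  min(3000, max(300, a$f0_end_hz * j$f0[2])),
                                  a$n_harmonics,
                                  min(0.6, a$noise_fraction * j$nf),
                                  state = a$state)
    }
    m <- length(motif)
    n_syl <- max(2L, min(6L, ceiling(m / 2)))
    syl_of <- sort(rep_len(seq_len(n_syl), m))
    gaps <- ifelse(diff(syl_of) == 0, 0, round(stats::runif(m - 1, 35, 55)))
    motif_ms <- sum(vapply(motif, `[[`, 0, "duration_ms")) + sum(gaps)
    reps <- max(2L, min(8L, round(song_ms / (motif_ms + 40))))
    sp <- song_spec(motif, gap_ms = 45, gaps_ms = gaps, n_repeats = reps,
                    seed = stats::runif(1, 1, 2^30))
    attr(sp, "p_target") <- p_target
    sp
  })
}

#' Realised state-duration abundance of a song specification
#'
#' Ground-truth abundance implied by element durations and state labels.
#'
#' @param spec A \code{song_spec}.
#' @return Length-10 abundance vector.
#' @export
spec_abundance <- function(spec) {
  st <- vapply(spec$motif, `[[`, 0L, "state")
  du <- vapply(spec$motif, `[[`, 0, "duration_ms")
  if (anyNA(st)) stop("spec has unlabelled elements")
  p <- numeric(10)
  for (i in seq_along(st)) p[st[i]] <- p[st[i]] + du[i]
  normalize_p(p)
}
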