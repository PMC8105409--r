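#' Segment a song into syllables by amplitude threshold
#'
#' Syllables are the voiced segments of the track (gaps shorter than
#' \code{min_gap_ms} closed, segments shorter than \code{min_dur_ms}
#' dropped), each summarised by its duration and mean features over the
#' voiced windows it spans.
#'
#' @param track A \code{feature_track}.
#' @param min_dur_ms Minimum syllable duration, ms.
#' @param min_gap_ms Gaps shorter than this are closed, ms.
#' @return A \code{syllable_table}: data frame with columns
#'   \code{onset_s}, \code{offset_s}, \code{duration_ms}, \code{mean_pitch},
#'   \code{mean_fm}, \code{mean_wiener_entropy}, \code{mean_continuity},
#'   \code{type} (NA until \code{\link{cluster_types}} is run) and
#'   \code{bout} (all 1 for a single-bout track).
#' @export
segment_syllables <- function(track, min_dur_ms = 15, min_gap_ms = 5) {
  seg <- voiced_segments(track, min_gap_ms = min_gap_ms,
                         min_dur_ms = min_dur_ms)
  rows <- lapply(seq_len(nrow(seg)), function(k) {
    in_syl <- track$voiced & track$time_s >= seg$onset_s[k] &
      track$time_s <= seg$offset_s[k]
    data.frame(onset_s = seg$onset_s[k], offset_s = seg$offset_s[k],
               duration_ms = (seg$offset_s[k] - seg$onset_s[k]) * 1000,
               mean_pitch = mean(track$pitch_hz[in_syl]),
               mean_fm = mean(track$fm_deg[in_syl]),
               mean_wiener_entropy = mean(track$wiener_entropy[in_syl]),
               mean_continuity = mean(track$spectral_continuity[in_syl]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               duration_ms = numeric(0), mean_pitch = numeric(0),
               mean_fm = numeric(0), mean_wiener_entropy = numeric(0),
               mean_continuity = numeric(0))
  out$type <- rep(NA_integer_, nrow(out))
  out$bout <- rep(1L, nrow(out))
  class(out) <- c("syllable_table", "data.frame")
  out
}

#' Cluster syllables into types
#'
#' Single-linkage (nearest-neighbour) agglomerative clustering on z-scored
#' duration and mean features, cut at a fixed height in z-units. Labels are
#' canonicalised (1 = largest cluster, ties broken by mean pitch) so the
#' partition does not depend on row order.
#'
#' @param table A \code{syllable_table}.
#' @param cutoff_z Merge-distance cutoff in z-units.
#' @param min_scales Per-feature floors on the standardisation scale
#'   (duration ms, pitch Hz, FM deg, entropy, continuity): variation below
#'   these measurement-noise floors is not allowed to inflate distances,
#'   so indistinguishable syllables collapse into one type.
#' @return The table with the \code{type} column filled.
#' @export
cluster_types <- function(table, cutoff_z = 1.5,
                          min_scales = c(2, 20, 1, 0.1, 0.02)) {
  stopifnot(inherits(table, "syllable_table"))
  n <- nrow(table)
  if (n == 0L) return(table)
  if (n < 2L) { table$type <- 1L; return(table) }
  M <- as.matrix(table[, c("duration_ms", "mean_pitch", "mean_fm",
                           "mean_wiener_entropy", "mean_continuity")])
  sds <- apply(M, 2, stats::sd)
  sds[is.na(sds)] <- 0
  sds <- pmax(sds, min_scales)
  Z <- sweep(sweep(M, 2, colMeans(M)), 2, sds, "/")
  hc <- stats::hclust(stats::dist(Z), method = "single")
  raw <- stats::cutree(hc, h = cutoff_z)
  # canonical labels: by decreasing size, ties by increasing mean pitch
  sizes <- table(raw)
  mp <- tapply(table$mean_pitch, raw, mean)
  ord <- order(-as.numeric(sizes), as.numeric(mp))
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  table$type <- as.integer(remap[as.character(raw)])
  table
}

#' Shannon diversity of syllable types, bits
#'
#' Entropy of the relative frequencies of syllable types.
#'
#' @param table A labelled \code{syllable_table}.
#' @return Entropy in bits.
#' @export
type_diversity <- function(table) {
  stopifnot(inherits(table, "syllable_table"))
  if (nrow(table) == 0L) stop("empty syllable table")
  if (anyNA(table$type)) stop("syllable types not assigned")
  p <- as.numeric(table(table$type)) / nrow(table)
  -sum(p * log2(p))
}

#' Song-syntax (bigram) entropy, bits
#'
#' Shannon entropy of the distribution of ordered syllable-type bigrams
#' within bouts; no bigram spans a bout boundary.
#'
#' @param table A labelled \code{syllable_table} in temporal order, with a
#'   \code{bout} column.
#' @return Entropy in bits.
#' @export
syntax_entropy <- function(table) {
  stopifnot(inherits(table, "syllable_table"))
  if (nrow(table) < 2L) stop("need at least 2 syllables for syntax entropy")
  if (anyNA(table$type)) stop("syllable types not assigned")
  bg <- unlist(lapply(split(seq_len(nrow(table)), table$bout), function(ix) {
    ix <- ix[order(table$onset_s[ix])]
    if (length(ix) < 2L) return(character(0))
    paste(table$type[ix[-length(ix)]], table$type[ix[-1L]], sep = ">")
  }))
  if (length(bg) == 0L) stop("no within-bout transitions")
  p <- as.numeric(table(bg)) / length(bg)
  -sum(p * log2(p))
}

#' Detect syllable recombination (merging / splitting) between songs
#'
#' Uses significant similarity sections between the tutor (reference) and
#' pupil songs to trace which pupil syllables the copied material of each
#' tutor syllable lands in. A merge is one pupil syllable receiving
#' near-complete copies (coverage at least \code{coverage_min}) of two or
#' more disjoint tutor syllables; a split is one well-covered tutor
#' syllable whose copy is distributed over two or more disjoint pupil
#' syllables. The coverage requirement operationalises the restriction to
#' clearly and fully imitated syllables.
#'
#' @param tutor,pupil \code{feature_track}s.
#' @param tutor_sylls,pupil_sylls Their \code{syllable_table}s.
#' @param null A \code{similarity_null}.
#' @param alpha Section significance level.
#' @param coverage_min Minimum fraction of a tutor syllable's voiced frames
#'   that must be matched for it to count as copied.
#' @param min_part Minimum fraction of a tutor syllable's matched frames
#'   that a pupil syllable must receive to count as one part of a split.
#' @return Data frame of events: \code{kind} ("merge"/"split"),
#'   \code{tutor_intervals}, \code{pupil_intervals} (each a semicolon-joined
#'   list of \code{start-end} second ranges). Zero rows when boundaries are
#'   consistent.
#' @export
detect_recombination <- function(tutor, pupil, tutor_sylls, pupil_sylls,
                                 null, alpha = 0.05, coverage_min = 0.8,
                                 min_part = 0.15) {
  det <- similarity_sections(tutor, pupil, null, alpha)
  n1 <- length(det$covered)
  # per-frame best alignment: for each covered tutor frame take the section
  # mapping with the smallest section p
  t_syl <- syllable_of(det$ref_time_s, tutor_sylls)
  p_syl_of_target <- syllable_of(det$target_time_s, pupil_sylls)

  if (nrow(det$sections) == 0L)
    return(empty_recomb())

  # frame-level map tutor frame -> pupil frame, preferring stronger sections
  map <- rep(NA_integer_, n1)
  ord <- order(det$sections$section_p)
  for (s in ord) {
    sec <- det$sections[s, ]
    ii <- sec$ref_from:sec$ref_to
    jj <- ii - sec$ref_from + sec$target_from
    take <- is.na(map[ii])
    map[ii[take]] <- jj[take]
  }

  events <- list()
  frames_of <- function(tsy) which(t_syl == tsy)
  n_tsyl <- nrow(tutor_sylls); n_psyl <- nrow(pupil_sylls)

  cover <- vapply(seq_len(n_tsyl), function(tsy) {
    fr <- frames_of(tsy)
    if (length(fr) == 0L) return(0)
    mean(!is.na(map[fr]))
  }, 0)

  # splits: tutor syllable well covered, copy lands in >= 2 pupil syllables
  for (tsy in seq_len(n_tsyl)) {
    if (cover[tsy] < coverage_min) next
    fr <- frames_of(tsy); fr <- fr[!is.na(map[fr])]
    dest <- p_syl_of_target[map[fr]]
    dest <- dest[!is.na(dest)]
    if (length(dest) == 0L) next
    tab <- table(dest) / length(dest)
    parts <- as.integer(names(tab)[tab >= min_part])
    if (length(parts) >= 2L) {
      events[[length(events) + 1L]] <- data.frame(
        kind = "split",
        tutor_intervals = fmt_iv(tutor_sylls[tsy, ]),
        pupil_intervals = fmt_iv(pupil_sylls[parts, ]))
    }
  }

  # merges: one pupil syllable receives >= 2 fully covered tutor syllables
  for (psy in seq_len(n_psyl)) {
    srcs <- integer(0)
    for (tsy in seq_len(n_tsyl)) {
      if (cover[tsy] < coverage_min) next
      fr <- frames_of(tsy); fr <- fr[!is.na(map[fr])]
      dest <- p_syl_of_target[map[fr]]
      dest <- dest[!is.na(dest)]
      if (length(dest) > 0L && mean(dest == psy) >= coverage_min)
        srcs <- c(srcs, tsy)
    }
    if (length(srcs) >= 2L) {
      events[[length(events) + 1L]] <- data.frame(
        kind = "merge",
        tutor_intervals = fmt_iv(tutor_sylls[srcs, ]),
        pupil_intervals = fmt_iv(pupil_sylls[psy, ]))
    }
  }
  if (length(events) == 0L) return(empty_recomb())
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

syllable_of <- function(time_s, sylls) {
  if (nrow(sylls) == 0L) return(rep(NA_integer_, length(time_s)))
  idx <- findInterval(time_s, sylls$onset_s)
  idx[idx == 0L] <- NA_integer_
  off <- sylls$offset_s[idx]
  idx[!is.na(idx) & time_s > off + 1e-9] <- NA_integer_
  idx
}

fmt_iv <- function(rows) {
  paste(sprintf("%.3f-%.3f", rows$onset_s, rows$offset_s), collapse = ";")
}

empty_recomb <- function() {
  data.frame(kind = character(0), tutor_intervals = character(0),
             pupil_intervals = character(0))
}
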