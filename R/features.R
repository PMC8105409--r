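#' Feature extraction configuration
#'
#' Defaults follow standard zebra finch song analysis practice: 10 ms
#' analysis windows advanced in 1 ms steps, an uncalibrated amplitude scale
#' on which a full-scale sinusoid reads \code{baseline_db} (70 dB) and
#' windows below \code{threshold_db} (50 dB) are treated as silence, and a
#' 300-8600 Hz analysis band covering zebra finch song energy.
#'
#' @param window_ms FFT window length, ms.
#' @param step_ms Window step, ms.
#' @param threshold_db Voicing threshold, dB (uncalibrated scale).
#' @param baseline_db dB value assigned to a full-scale sinusoid.
#' @param band_hz Two-element analysis band in Hz.
#' @param wiener_smooth_bins Width (bins) of the Daniell smoother applied to
#'   each window's power spectrum before Wiener entropy; smoothing removes
#'   the chi-squared bias of raw periodogram bins so a flat true spectrum
#'   measures near 0.
#' @param fm_lag_ms Half-lag (ms) for spectro-temporal derivatives used by
#'   frequency modulation and its sign.
#' @param pitch_range_hz Fundamental-frequency search range, Hz.
#' @param pitch_gate Minimum normalised autocorrelation peak (goodness of
#'   pitch) below which pitch falls back to the spectral mean frequency.
#' @param fm_sign_min_deg FM magnitude below which modulation sign is 0.
#' @return A list of class \code{feature_config}.
#' @export
feature_config <- function(window_ms = 10, step_ms = 1,
                           threshold_db = 50, baseline_db = 70,
                           band_hz = c(300, 8600),
                           wiener_smooth_bins = 16,
                           fm_lag_ms = 5,
                           pitch_range_hz = c(300, 3000),
                           pitch_gate = 0.3,
                           fm_sign_min_deg = 2) {
  stopifnot(window_ms > 0, step_ms > 0, threshold_db > 0,
            length(band_hz) == 2L, band_hz[1] < band_hz[2],
            length(pitch_range_hz) == 2L, pitch_range_hz[1] < pitch_range_hz[2])
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 threshold_db = threshold_db, baseline_db = baseline_db,
                 band_hz = band_hz, wiener_smooth_bins = wiener_smooth_bins,
                 fm_lag_ms = fm_lag_ms, pitch_range_hz = pitch_range_hz,
                 pitch_gate = pitch_gate, fm_sign_min_deg = fm_sign_min_deg),
            class = "feature_config")
}

# moving average along rows (frequency) with edge-shrinking window
smooth_rows <- function(M, k) {
  if (k <= 1L) return(M)
  n <- nrow(M)
  cs <- apply(M, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  h <- k %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  (upper - lower) / (hi - lo + 1L)
}

#' Construct a feature track directly from feature values
#'
#' Builds the per-window feature table that \code{\link{compute_features}}
#' produces, from caller-supplied values. Intended for simulation studies in
#' feature space (e.g. sampling windows from a known vocal-state template)
#' where no waveform exists.
#'
#' @param pitch_hz,fm_deg,wiener_entropy Numeric vectors, one per window.
#' @param fm_sign Modulation sign in \{-1, 0, 1\} (recycled).
#' @param spectral_continuity,amplitude_db Recycled numeric vectors.
#' @param voiced Logical mask (recycled).
#' @param window_ms,step_ms,threshold_db Metadata recorded on the track.
#' @param bird_id Optional identifier stored as an attribute.
#' @return A \code{feature_track} data frame.
#' @export
feature_track <- function(pitch_hz, fm_deg, wiener_entropy,
                          fm_sign = 0, spectral_continuity = 1,
                          amplitude_db = 70, voiced = TRUE,
                          window_ms = 10, step_ms = 1, threshold_db = 50,
                          bird_id = NULL) {
  n <- length(pitch_hz)
  tr <- data.frame(
    time_s = (seq_len(n) - 1) * step_ms / 1000 + window_ms / 2000,
    amplitude_db = rep_len(amplitude_db, n),
    pitch_hz = pitch_hz,
    fm_deg = rep_len(fm_deg, n),
    fm_sign = rep_len(fm_sign, n),
    wiener_entropy = pmin(0, rep_len(wiener_entropy, n)),
    spectral_continuity = rep_len(spectral_continuity, n),
    voiced = rep_len(as.logical(voiced), n))
  attr(tr, "meta") <- list(window_ms = window_ms, step_ms = step_ms,
                           threshold_db = threshold_db, sample_rate = NA_real_)
  attr(tr, "bird_id") <- bird_id
  class(tr) <- c("feature_track", "data.frame")
  tr
}

#' Sliding-window acoustic features of a song bout
#'
#' Computes, for every analysis window, amplitude (dB, uncalibrated),
#' pitch (Hz, autocorrelation estimator with harmonicity gate and
#' spectral-mean-frequency fallback), frequency modulation (degrees in
#' \code{[0, 90]}, from the ratio of time- to frequency-direction spectral
#' derivatives; 45 degrees corresponds to spectral energy drifting one
#' frequency bin per millisecond), modulation sign (-1 down, +1 up, 0
#' unmodulated), Wiener entropy (natural log of the ratio of geometric to
#' arithmetic mean of the smoothed band power spectrum; 0 for a flat
#' spectrum, strongly negative for tones) and spectral continuity (clipped
#' correlation of band spectra one window-length apart). Windows whose
#' amplitude reaches \code{config$threshold_db} are marked voiced.
#'
#' @param clip An \code{\link{audio_clip}}.
#' @param config A \code{\link{feature_config}}.
#' @return A \code{feature_track}: data frame with one row per window and
#'   columns \code{time_s}, \code{amplitude_db}, \code{pitch_hz},
#'   \code{fm_deg}, \code{fm_sign}, \code{wiener_entropy},
#'   \code{spectral_continuity}, \code{voiced}; window metadata in
#'   \code{attr(, "meta")}.
#' @export
compute_features <- function(clip, config = feature_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  x <- clip$samples
  if (!all(is.finite(x))) stop("non-finite samples")
  dur_ms <- length(x) / fs * 1000
  if (dur_ms < config$window_ms) stop("clip too short")

  nw <- round(config$window_ms * fs / 1000)
  n_win <- floor((dur_ms - config$window_ms) / config$step_ms + 1e-9) + 1L
  starts_ms <- (seq_len(n_win) - 1L) * config$step_ms
  idx0 <- pmin(floor(starts_ms * fs / 1000) + 1L, length(x) - nw + 1L)

  W <- matrix(x[outer(0:(nw - 1L), idx0, "+")], nrow = nw)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1L)) / (nw - 1L))
  W <- W * hann
  nfft <- 2^ceiling(log2(nw))
  Wp <- rbind(W, matrix(0, nfft - nw, n_win))
  Fc <- stats::mvfft(Wp)
  P <- Mod(Fc)^2                              # nfft x n_win

  nh <- nfft %/% 2L + 1L
  freqs <- (0:(nh - 1L)) * fs / nfft
  bi <- which(freqs >= config$band_hz[1] & freqs <= config$band_hz[2])
  Pb <- P[bi, , drop = FALSE]
  fb <- freqs[bi]

  # amplitude on a scale where a full-scale sine reads baseline_db
  sine_ref <- nfft * sum(hann^2) * 0.5
  band_pow <- colSums(Pb)
  amplitude_db <- 10 * log10(band_pow / sine_ref + 1e-300) + config$baseline_db
  voiced <- amplitude_db >= config$threshold_db

  # smoothed band spectrum for entropy / FM / continuity
  S <- smooth_rows(Pb, as.integer(config$wiener_smooth_bins))
  am <- colMeans(S)
  eps <- 1e-10 * (am + 1e-300)
  wiener <- pmin(0, colMeans(log(sweep(S, 2, eps, "+"))) - log(am + eps))

  # pitch: normalised autocorrelation via inverse FFT of the power spectrum
  r <- Re(stats::mvfft(P, inverse = TRUE)) / nfft
  r0 <- pmax(r[1L, ], 1e-300)
  lmin <- max(2L, floor(fs / config$pitch_range_hz[2]))
  lmax <- min(nfft %/% 2L - 1L, ceiling(fs / config$pitch_range_hz[1]))
  centroid <- colSums(Pb * fb) / (band_pow + 1e-300)
  pitch <- centroid
  goodness <- numeric(n_win)
  Rn <- sweep(r[1:(lmax + 2L), , drop = FALSE], 2, r0, "/")
  lags <- lmin:lmax
  for (j in seq_len(n_win)) {
    if (!voiced[j]) next
    rj <- Rn[, j]                           # rj[k] is lag k - 1
    seg <- rj[lags + 1L]
    pk <- max(seg)
    goodness[j] <- pk
    if (pk < config$pitch_gate) next        # low harmonicity: keep centroid
    # smallest local maximum within 90% of the global peak (octave guard)
    lm <- which(seg >= 0.9 * pk &
                  seg >= c(-Inf, seg[-length(seg)]) &
                  seg >= c(seg[-1L], -Inf))
    l <- lags[lm[1L]]
    den <- rj[l] - 2 * rj[l + 1L] + rj[l + 2L]
    delta <- if (abs(den) > 1e-12) 0.5 * (rj[l] - rj[l + 2L]) / den else 0
    delta <- max(-0.5, min(0.5, delta))
    pitch[j] <- fs / (l + delta)
  }
  pitch <- pmax(pitch, 1e-6)

  # FM from spectro-temporal derivatives of a lightly smoothed band spectrum
  Sf <- smooth_rows(Pb, 3L)
  L <- max(1L, round(config$fm_lag_ms / config$step_ms))
  fm <- numeric(n_win); fm_sign <- integer(n_win)
  if (n_win > 2L * L) {
    j_mid <- (L + 1L):(n_win - L)
    dT <- (Sf[, j_mid + L, drop = FALSE] - Sf[, j_mid - L, drop = FALSE]) /
      (2 * L * config$step_ms)                       # power per ms
    dF <- (Sf[c(2:nrow(Sf), nrow(Sf)), , drop = FALSE] -
             Sf[c(1L, 1:(nrow(Sf) - 1L)), , drop = FALSE]) / 2
    dFm <- dF[, j_mid, drop = FALSE]
    nT <- sqrt(colSums(dT^2))
    nF <- sqrt(colSums(dFm^2))
    fm[j_mid] <- atan(nT / (nF + 1e-300)) * 180 / pi
    # a peak drifting up in frequency anti-correlates its time and
    # frequency derivatives
    dC <- -colSums(dT * dFm)
    fm_sign[j_mid] <- ifelse(fm[j_mid] < config$fm_sign_min_deg, 0L,
                             ifelse(dC >= 0, 1L, -1L))
  }

  # spectral continuity: correlation of band spectra one window-length apart
  L2 <- max(1L, round(config$window_ms / config$step_ms))
  cont <- numeric(n_win)
  if (n_win > 2L * L2) {
    j_mid <- (L2 + 1L):(n_win - L2)
    A <- Pb[, j_mid - L2, drop = FALSE]; B <- Pb[, j_mid + L2, drop = FALSE]
    A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
    cc <- colSums(A * B) / (sqrt(colSums(A^2) * colSums(B^2)) + 1e-300)
    cont[j_mid] <- pmax(0, cc)
  }

  tr <- data.frame(
    time_s = (starts_ms + config$window_ms / 2) / 1000,
    amplitude_db = amplitude_db,
    pitch_hz = pitch,
    fm_deg = fm,
    fm_sign = fm_sign,
    wiener_entropy = wiener,
    spectral_continuity = cont,
    voiced = voiced)
  attr(tr, "meta") <- list(window_ms = config$window_ms,
                           step_ms = config$step_ms,
                           threshold_db = config$threshold_db,
                           sample_rate = fs, config = unclass(config))
  class(tr) <- c("feature_track", "data.frame")
  tr
}

#' Voiced segments of a feature track
#'
#' Maximal runs of voiced windows, after closing gaps shorter than
#' \code{min_gap_ms} and discarding runs shorter than \code{min_dur_ms}.
#' Interval endpoints are window-centre times.
#'
#' @param track A \code{feature_track}.
#' @param min_gap_ms Gaps shorter than this are merged, ms.
#' @param min_dur_ms Runs shorter than this are dropped, ms.
#' @return Data frame with columns \code{onset_s}, \code{offset_s}; zero rows
#'   if nothing is voiced.
#' @export
voiced_segments <- function(track, min_gap_ms = 5, min_dur_ms = 15) {
  stopifnot(inherits(track, "feature_track"))
  v <- track$voiced
  if (!any(v)) return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(i = starts[r$values], j = ends[r$values])
  # merge across short gaps
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (k in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      gap_ms <- (track$time_s[seg$i[k]] - track$time_s[last$j]) * 1000
      if (gap_ms < min_gap_ms) {
        keep[[length(keep)]]$j <- seg$j[k]
      } else keep[[length(keep) + 1L]] <- seg[k, ]
    }
    seg <- do.call(rbind, keep)
  }
  out <- data.frame(onset_s = track$time_s[seg$i], offset_s = track$time_s[seg$j])
  out[(out$offset_s - out$onset_s) * 1000 >= min_dur_ms, , drop = FALSE]
}

#' Write a feature track to CSV with a sidecar JSON of its configuration
#'
#' @param track A \code{feature_track}.
#' @param path CSV output path; the sidecar is \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_feature_track <- function(track, path) {
  stopifnot(inherits(track, "feature_track"))
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  jsonlite::write_json(attr(track, "meta"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
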