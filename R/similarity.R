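sim_features <- c("pitch_hz", "fm_deg", "wiener_entropy", "spectral_continuity")

voiced_features <- function(track) {
  stopifnot(inherits(track, "feature_track"))
  v <- track$voiced
  list(X = as.matrix(as.data.frame(track)[v, sim_features]),
       time_s = track$time_s[v],
       step_ms = attr(track, "meta")$step_ms)
}

#' Fit the empirical null model for similarity scoring
#'
#' Samples 70 ms window pairs from songs of distinct (unrelated) birds and
#' records the empirical distribution of their feature distances. Distances
#' are Euclidean over the four song features (pitch, frequency modulation,
#' Wiener entropy, spectral continuity), z-scored against the pooled
#' population moments and averaged over the aligned frames of the window.
#' A later observed distance is converted to a p-value by its rank in this
#' distribution (the probability of an unrelated pair being at least as
#' close), so a distance of 0 receives the minimum attainable p of
#' \code{1/(n_samples + 1)}.
#'
#' @param tracks List of at least 20 \code{feature_track}s, one per bird.
#' @param seed Integer seed.
#' @param n_samples Number of null window pairs.
#' @param window_ms Similarity window, ms.
#' @return Object of class \code{similarity_null}.
#' @export
build_null <- function(tracks, seed = 1, n_samples = 10000, window_ms = 70) {
  if (length(tracks) < 20L) stop("need at least 20 tracks from distinct birds")
  vf <- lapply(tracks, voiced_features)
  step_ms <- vf[[1L]]$step_ms
  W <- max(2L, round(window_ms / step_ms))
  pool <- do.call(rbind, lapply(vf, `[[`, "X"))
  mu <- colMeans(pool); sdv <- apply(pool, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Z <- lapply(vf, function(f) sweep(sweep(f$X, 2, mu), 2, sdv, "/"))
  ok <- which(vapply(Z, nrow, 0L) >= W)
  if (length(ok) < 20L) stop("need at least 20 tracks with >= 70 ms voiced")
  with_seed(seed, {
    a <- sample(ok, n_samples, replace = TRUE)
    b <- vapply(a, function(i) sample(setdiff(ok, i), 1L), 0L)
    d <- numeric(n_samples)
    fd <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      Xa <- Z[[a[s]]]; Xb <- Z[[b[s]]]
      ia <- sample.int(nrow(Xa) - W + 1L, 1L)
      ib <- sample.int(nrow(Xb) - W + 1L, 1L)
      diff <- Xa[ia:(ia + W - 1L), , drop = FALSE] -
        Xb[ib:(ib + W - 1L), , drop = FALSE]
      fdist <- sqrt(rowSums(diff^2))
      d[s] <- mean(fdist)
      fd[s] <- fdist[1L]
    }
    structure(list(distances = sort(d), frame_distances = sort(fd),
                   mu = mu, sd = sdv, W = W,
                   step_ms = step_ms, window_ms = window_ms,
                   n_tracks = length(tracks), seed = seed),
              class = "similarity_null")
  })
}

#' Convert distances to empirical p-values under the null
#' @param d Numeric distances.
#' @param null A \code{similarity_null}.
#' @return p-values in \code{(0, 1]}.
#' @export
null_p_value <- function(d, null) {
  stopifnot(inherits(null, "similarity_null"))
  n <- length(null$distances)
  (findInterval(d, null$distances) + 1) / (n + 1)
}

#' Serialise / load a similarity null model (JSON)
#' @param null A \code{similarity_null}.
#' @param path JSON path.
#' @return \code{path} / the null model.
#' @export
write_null <- function(null, path) {
  stopifnot(inherits(null, "similarity_null"))
  jsonlite::write_json(c(list(schema = "finchsong/similarity_null/1"),
                         unclass(null)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "finchsong/similarity_null/1"))
    stop("unrecognised null-model schema")
  obj$schema <- NULL
  obj$distances <- as.numeric(obj$distances)
  obj$frame_distances <- as.numeric(obj$frame_distances)
  obj$mu <- stats::setNames(as.numeric(obj$mu), sim_features)
  obj$sd <- stats::setNames(as.numeric(obj$sd), sim_features)
  structure(obj, class = "similarity_null")
}

# core: similarity sections between two tracks (frame-indexed, no jitter)
similarity_sections <- function(reference, target, null, alpha = 0.05,
                                motif_s = NULL) {
  stopifnot(inherits(null, "similarity_null"))
  rf <- voiced_features(reference); tf <- voiced_features(target)
  keep <- rep(TRUE, nrow(rf$X))
  if (!is.null(motif_s))
    keep <- rf$time_s >= motif_s[1] & rf$time_s <= motif_s[2]
  X <- sweep(sweep(rf$X[keep, , drop = FALSE], 2, null$mu), 2, null$sd, "/")
  Y <- sweep(sweep(tf$X, 2, null$mu), 2, null$sd, "/")
  W <- null$W
  n1 <- nrow(X); n2 <- nrow(Y)
  if (n1 < W || n2 < W) stop("track too short for similarity window")
  D2 <- outer(rowSums(X^2), rep(1, n2)) +
    outer(rep(1, n1), rowSums(Y^2)) - 2 * X %*% t(Y)
  D <- sqrt(pmax(D2, 0))
  m1 <- n1 - W + 1L; m2 <- n2 - W + 1L
  S <- matrix(0, m1, m2)
  for (k in 0:(W - 1L))
    S <- S + D[(1L + k):(m1 + k), (1L + k):(m2 + k)]
  P <- matrix(null_p_value(S / W, null), m1, m2)
  sig <- P < alpha
  # frame-level gate: inside a significant section, a reference frame only
  # counts as covered if its own aligned frame distance is null-improbable
  # (sharpens section boundaries at copied/improvised junctions)
  frame_cut <- stats::quantile(null$frame_distances, alpha, names = FALSE)

  covered <- rep(FALSE, n1)
  secs <- list()
  for (off in (-(m1 - 1L)):(m2 - 1L)) {
    i0 <- max(1L, 1L - off); i1 <- min(m1, m2 - off)
    if (i1 < i0) next
    ii <- i0:i1
    idx <- cbind(ii, ii + off)
    sd_diag <- sig[idx]
    if (!any(sd_diag)) next
    r <- rle(sd_diag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      rows <- ii[starts[q]:ends[q]]
      pv <- P[cbind(rows, rows + off)]
      # adjacent windows overlap by all but one frame, so combine evidence
      # only across non-overlapping blocks, and correct for the effective
      # number of independent cells searched
      pb <- pv[seq(1L, length(pv), by = W)]
      stat <- -2 * sum(log(pb))
      sp <- stats::pchisq(stat, df = 2 * length(pb), lower.tail = FALSE)
      sp <- min(1, sp * max(1, (m1 / W) * (m2 / W)))
      if (sp < alpha) {
        ra <- rows[1L]; rb <- rows[length(rows)] + W - 1L
        ta <- rows[1L] + off; tb <- rows[length(rows)] + off + W - 1L
        fr <- ra:rb
        covered[fr[D[cbind(fr, fr + off)] < frame_cut]] <- TRUE
        secs[[length(secs) + 1L]] <-
          data.frame(ref_from = ra, ref_to = rb,
                     target_from = ta, target_to = tb, section_p = sp)
      }
    }
  }
  sections <- if (length(secs)) do.call(rbind, secs) else
    data.frame(ref_from = integer(0), ref_to = integer(0),
               target_from = integer(0), target_to = integer(0),
               section_p = numeric(0))
  list(covered = covered, sections = sections,
       ref_time_s = rf$time_s[keep], target_time_s = tf$time_s,
       step_ms = rf$step_ms, W = W)
}

#' Asymmetric percent similarity between two songs
#'
#' The proportion of the reference song (by default its full voiced
#' portion; optionally a motif interval) covered by statistically
#' significant similarity sections in the target song. Sections are maximal
#' diagonal-contiguous runs of 70 ms windows whose distances are improbably
#' small under the unrelated-bird null, retained when their Fisher-combined
#' p-value is below \code{alpha}. The calculation is repeated with the
#' reference boundaries jittered by up to 10 ms (emulating manual motif
#' outlining) and the median percentage is reported.
#'
#' @param reference,target \code{feature_track}s; the reference is the song
#'   whose coverage is measured (the tutor for similarity, the pupil for
#'   influence).
#' @param null A fitted \code{\link{build_null}} model.
#' @param alpha Section significance level.
#' @param repeats Number of jittered repeats (median reported).
#' @param seed Integer seed for the jitter.
#' @param motif_s Optional \code{c(start, end)} seconds restricting the
#'   reference to a motif.
#' @param direction Label recorded on the result.
#' @return Object of class \code{similarity_result}: \code{similarity_pct},
#'   \code{sections} (data frame of intervals in seconds with p-values),
#'   \code{direction}, \code{repeats_pct}.
#' @export
similarity_score <- function(reference, target, null, alpha = 0.05,
                             repeats = 5, seed = 1, motif_s = NULL,
                             direction = "tutor_ref") {
  det <- similarity_sections(reference, target, null, alpha, motif_s)
  n1 <- length(det$covered)
  jit_frames <- max(1L, round(10 / det$step_ms))
  pcts <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      if (r == 1L) { a <- 1L; b <- n1 } else {
        a <- 1L + sample.int(jit_frames + 1L, 1L) - 1L
        b <- n1 - (sample.int(jit_frames + 1L, 1L) - 1L)
      }
      if (b <= a) { a <- 1L; b <- n1 }
      100 * mean(det$covered[a:b])
    }, 0)
  })
  sections <- det$sections
  out_sections <- data.frame(
    ref_onset_s = det$ref_time_s[sections$ref_from],
    ref_offset_s = det$ref_time_s[sections$ref_to],
    target_onset_s = det$target_time_s[sections$target_from],
    target_offset_s = det$target_time_s[sections$target_to],
    section_p = sections$section_p)
  structure(list(similarity_pct = stats::median(pcts),
                 sections = out_sections, direction = direction,
                 repeats_pct = pcts, alpha = alpha),
            class = "similarity_result")
}

#' Percent influence of a tutor song on a pupil song
#'
#' The similarity computation run in reverse: the pupil's song is the
#' covered reference, so the score measures how much of the pupil's song
#' traces back to the tutor. A pupil that copies its tutor's motif and then
#' appends improvised material keeps full tutor-referenced similarity but
#' loses influence in proportion to the improvised share.
#'
#' @inheritParams similarity_score
#' @param tutor,pupil \code{feature_track}s.
#' @return A \code{similarity_result} with \code{direction = "pupil_ref"}.
#' @export
influence_score <- function(tutor, pupil, null, alpha = 0.05, repeats = 5,
                            seed = 1, motif_s = NULL) {
  similarity_score(reference = pupil, target = tutor, null = null,
                   alpha = alpha, repeats = repeats, seed = seed,
                   motif_s = motif_s, direction = "pupil_ref")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result (%s): %.1f%%, %d sections>\n",
              x$direction, x$similarity_pct, nrow(x$sections)))
  invisible(x)
}
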