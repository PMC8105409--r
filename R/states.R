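#' Abundance vector of vocal states
#'
#' @param p Numeric vector of 10 non-negative proportions summing to 1.
#' @param n_windows Number of voiced windows the proportions summarise.
#' @return Object of class \code{abundance_vector}.
#' @export
abundance_vector <- function(p, n_windows = NA_integer_) {
  p <- as.numeric(p)
  if (length(p) != 10L) stop("abundance vector must have 10 entries")
  if (any(p < 0)) stop("negative abundance")
  if (!is.na(n_windows) && n_windows > 0 && abs(sum(p) - 1) > 1e-9)
    stop("abundances must sum to 1")
  structure(list(p = p, n_windows = as.integer(n_windows)),
            class = "abundance_vector")
}

as_p <- function(x) {
  if (inherits(x, "abundance_vector")) x$p else as.numeric(x)
}

#' Shannon song diversity in bits
#'
#' \eqn{-\sum_i p_i \log_2 p_i} over the vocal-state abundances, with
#' \eqn{0 \log 0 = 0}. Bounded by \eqn{\log_2 10 \approx 3.32} bits for 10
#' states.
#'
#' @param p An \code{\link{abundance_vector}} or numeric vector of
#'   proportions summing to 1.
#' @return Entropy in bits.
#' @export
shannon_diversity <- function(p) {
  p <- as_p(p)
  if (any(p < -1e-12)) stop("negative abundance")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Diversity of the pooled song of several birds
#'
#' Entropy of the count-weighted mean abundance vector. By concavity of
#' entropy this is at least the weighted mean of the individual diversities.
#'
#' @param vectors List of \code{\link{abundance_vector}}s (or numeric
#'   vectors; equal weights are used where window counts are missing).
#' @return Pooled entropy in bits.
#' @export
pooled_diversity <- function(vectors) {
  if (length(vectors) == 0L) stop("no abundance vectors to pool")
  if (inherits(vectors, "abundance_vector") || is.numeric(vectors))
    vectors <- list(vectors)
  P <- vapply(vectors, as_p, numeric(10))
  w <- vapply(vectors, function(v)
    if (inherits(v, "abundance_vector") && !is.na(v$n_windows))
      as.numeric(v$n_windows) else NA_real_, 0)
  if (anyNA(w)) w <- rep(1, length(vectors))
  shannon_diversity(normalize_p(as.vector(P %*% w)))
}

#' Vocal-state abundances of a state sequence
#'
#' @param seq A \code{vocal_state_sequence} (from
#'   \code{\link{assign_states}}) or an integer vector of states 1-10.
#' @return An \code{\link{abundance_vector}}.
#' @export
state_abundances <- function(seq) {
  s <- if (inherits(seq, "vocal_state_sequence")) seq$states else as.integer(seq)
  if (length(s) == 0L) stop("empty state sequence")
  if (any(s < 1L | s > 10L)) stop("states must lie in 1..10")
  abundance_vector(tabulate(s, 10L) / length(s), length(s))
}

#' Partition-fitting configuration
#'
#' @param min_windows Minimum pooled voiced windows required.
#' @param states_per_region Cluster counts for the very-low/low/medium/high
#'   pitch regions; must sum to 10.
#' @param pitch_bw_adjust Multiplier on the Silverman bandwidth of the
#'   pooled pitch density.
#' @param kde_n Grid size for the per-region 2-D density.
#' @param kde_h Kernel bandwidth for the per-region density, in robust
#'   standard-deviation units.
#' @param min_peak_sep Minimum separation of density peaks, in within-region
#'   standard-deviation units.
#' @param pitch_range_hz Pitch range used when fitting the region
#'   boundaries; windows whose pitch falls outside (typically low-harmonicity
#'   windows measured by the spectral-mean fallback) are excluded from the
#'   fit, though assignment still clips them to the nearest region.
#' @return List of class \code{partition_config}.
#' @export
partition_config <- function(min_windows = 10000,
                             states_per_region = c(2L, 3L, 3L, 2L),
                             pitch_bw_adjust = 1,
                             kde_n = 60,
                             kde_h = 0.25,
                             min_peak_sep = 0.4,
                             pitch_range_hz = c(300, 3000)) {
  if (sum(states_per_region) != 10L) stop("state counts must sum to 10")
  structure(list(min_windows = min_windows,
                 states_per_region = as.integer(states_per_region),
                 pitch_bw_adjust = pitch_bw_adjust,
                 kde_n = kde_n, kde_h = kde_h, min_peak_sep = min_peak_sep,
                 pitch_range_hz = pitch_range_hz),
            class = "partition_config")
}

# local maxima of a 2-D grid (strictly above 8-neighbourhood)
grid_peaks <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- NULL
  zp <- matrix(-Inf, nr + 2L, nc + 2L)
  zp[2:(nr + 1L), 2:(nc + 1L)] <- z
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- zp[2:(nr + 1L) + di, 2:(nc + 1L) + dj]
    out <- if (is.null(out)) z >= nb else out & (z >= nb)
  }
  which(out & z > 0, arr.ind = TRUE)
}

#' Fit the population-level ten-state partition of acoustic space
#'
#' Pools voiced windows across tracks; places three pitch boundaries at the
#' three deepest local minima of the smoothed pooled pitch density (giving
#' four pitch regions); then, within each region, locates cluster centres
#' in the (signed frequency modulation, Wiener entropy) plane by 2-D
#' density-peak detection, keeping a fixed number of states per region
#' (default 2/3/3/2). Every voiced window maps to exactly one state:
#' pitches outside the fitted range clip to the nearest region, and
#' assignment is nearest-centre (in per-region standardised units) with
#' ties going to the lower state label. Within a region, centres are
#' labelled in order of increasing signed FM, so the central-region
#' unmodulated states receive the middle labels (4 and 7).
#'
#' @param tracks A \code{feature_track} or list of them.
#' @param config A \code{\link{partition_config}}.
#' @return Object of class \code{state_partition}.
#' @export
fit_partition <- function(tracks, config = partition_config()) {
  if (inherits(tracks, "feature_track")) tracks <- list(tracks)
  pool <- do.call(rbind, lapply(tracks, function(tr) {
    stopifnot(inherits(tr, "feature_track"))
    v <- tr$voiced
    data.frame(pitch = tr$pitch_hz[v],
               fms = tr$fm_deg[v] * tr$fm_sign[v],
               went = tr$wiener_entropy[v])
  }))
  if (nrow(pool) < config$min_windows)
    stop("too few pooled voiced windows (", nrow(pool), " < ",
         config$min_windows, ")")
  pool <- pool[pool$pitch >= config$pitch_range_hz[1] &
                 pool$pitch <= config$pitch_range_hz[2], , drop = FALSE]

  d <- stats::density(pool$pitch, adjust = config$pitch_bw_adjust, n = 1024)
  y <- d$y
  is_min <- c(FALSE, y[2:(length(y) - 1)] < y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] <= y[3:length(y)], FALSE)
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  modes <- d$x[is_max]
  mins <- which(is_min & d$x > min(modes) & d$x < max(modes))
  if (length(modes) < 4L || length(mins) < 3L)
    stop("degenerate pitch distribution")
  sel <- mins[order(y[mins])][1:3]
  pitch_edges <- sort(d$x[sel])

  region <- findInterval(pool$pitch, pitch_edges) + 1L
  offsets <- cumsum(c(0L, config$states_per_region))[1:4]
  regions <- vector("list", 4L)
  for (r in 1:4) {
    k <- config$states_per_region[r]
    sub <- pool[region == r, , drop = FALSE]
    if (nrow(sub) < 10L * k) stop("degenerate pitch distribution")
    robust_scale <- function(x) {
      s <- stats::mad(x)
      if (is.na(s) || s < 1e-8) s <- stats::sd(x)
      if (is.na(s) || s < 1e-8) s <- 1
      s
    }
    s1 <- robust_scale(sub$fms); s2 <- robust_scale(sub$went)
    u <- sub$fms / s1; v <- sub$went / s2
    kd <- MASS::kde2d(u, v, n = config$kde_n,
                      h = c(config$kde_h, config$kde_h) * 4,
                      lims = c(stats::quantile(u, c(0.005, 0.995)),
                               stats::quantile(v, c(0.005, 0.995))))
    pk <- grid_peaks(kd$z)
    if (nrow(pk) < k) stop("fewer density modes than required in region ", r)
    ord <- order(kd$z[pk], decreasing = TRUE)
    chosen <- matrix(NA_real_, 0, 2)
    for (i in ord) {
      cand <- c(kd$x[pk[i, 1]], kd$y[pk[i, 2]])
      if (nrow(chosen) == 0L ||
          min(sqrt(rowSums(sweep(chosen, 2, cand)^2))) >= config$min_peak_sep)
        chosen <- rbind(chosen, cand)
      if (nrow(chosen) == k) break
    }
    if (nrow(chosen) < k) stop("fewer density modes than required in region ", r)
    chosen <- chosen[order(chosen[, 1]), , drop = FALSE]  # by signed FM
    regions[[r]] <- list(centers = unname(chosen), scale = c(s1, s2),
                         labels = offsets[r] + seq_len(k))
  }
  structure(list(pitch_edges = pitch_edges, regions = regions,
                 states_per_region = config$states_per_region,
                 config = unclass(config), n_windows = nrow(pool)),
            class = "state_partition")
}

#' Assign vocal states to the voiced windows of a track
#'
#' Every voiced window receives exactly one state 1-10: the pitch region is
#' found by the fitted boundaries (out-of-range pitches clip to the outer
#' regions), then the nearest cluster centre in the region's standardised
#' (signed FM, Wiener entropy) plane; ties take the lower label.
#'
#' @param track A \code{feature_track} with at least one voiced window.
#' @param partition A fitted \code{state_partition}.
#' @param bird_id Optional identifier carried on the result.
#' @return Object of class \code{vocal_state_sequence} with elements
#'   \code{states} (integer vector) and \code{bird_id}.
#' @export
assign_states <- function(track, partition, bird_id = attr(track, "bird_id")) {
  stopifnot(inherits(track, "feature_track"),
            inherits(partition, "state_partition"))
  v <- track$voiced
  if (!any(v)) stop("silent recording")
  pitch <- track$pitch_hz[v]
  fms <- track$fm_deg[v] * track$fm_sign[v]
  went <- track$wiener_entropy[v]
  region <- findInterval(pitch, partition$pitch_edges) + 1L
  states <- integer(length(pitch))
  for (r in 1:4) {
    idx <- which(region == r)
    if (length(idx) == 0L) next
    rg <- partition$regions[[r]]
    # centres are stored in standardised units
    u <- fms[idx] / rg$scale[1]; w <- went[idx] / rg$scale[2]
    d2 <- outer(u, rg$centers[, 1], "-")^2 + outer(w, rg$centers[, 2], "-")^2
    states[idx] <- rg$labels[max.col(-d2, ties.method = "first")]
  }
  structure(list(states = states, bird_id = bird_id,
                 time_s = track$time_s[v]),
            class = "vocal_state_sequence")
}

#' Serialise a fitted partition to JSON
#' @param partition A \code{state_partition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "state_partition"))
  obj <- list(schema = "finchsong/state_partition/1",
              pitch_edges = partition$pitch_edges,
              states_per_region = partition$states_per_region,
              regions = lapply(partition$regions, function(r)
                list(centers = r$centers, scale = r$scale, labels = r$labels)),
              config = partition$config, n_windows = partition$n_windows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a partition from JSON
#'
#' Accepts files written by \code{\link{write_partition}} or hand-specified
#' partitions following the same schema, so published region boundaries can
#' be encoded directly.
#'
#' @param path JSON path.
#' @return A \code{state_partition}.
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "finchsong/state_partition/1"))
    stop("unrecognised partition schema")
  regions <- lapply(obj$regions, function(r)
    list(centers = do.call(rbind, lapply(r$centers, as.numeric)),
         scale = as.numeric(unlist(r$scale)),
         labels = as.integer(unlist(r$labels))))
  structure(list(pitch_edges = as.numeric(unlist(obj$pitch_edges)),
                 regions = regions,
                 states_per_region = as.integer(unlist(obj$states_per_region)),
                 config = obj$config, n_windows = obj$n_windows[[1]]),
            class = "state_partition")
}
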