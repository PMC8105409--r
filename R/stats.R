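p_cols <- function(role) paste0(role, "_p", 1:10)

pair_matrix <- function(pairs, role) {
  cols <- p_cols(role)
  if (!all(cols %in% names(pairs)))
    stop("pairs table lacks ", role, " abundance columns ",
         paste(setdiff(cols, names(pairs)), collapse = ", "))
  as.matrix(pairs[, cols])
}

#' Quartile labels by song similarity
#'
#' Pairs are ranked by \code{similarity_pct}; Q1 is the highest-similarity
#' quartile. Ties keep the stable input order; group sizes differ by at
#' most one.
#'
#' @param pairs A pairs table with a \code{similarity_pct} column.
#' @param by Column to rank on.
#' @return Factor of labels Q1-Q4, one per row.
#' @export
quartile_partition <- function(pairs, by = "similarity_pct") {
  n <- nrow(pairs)
  if (n < 4L) stop("need at least 4 pairs for quartiles")
  ord <- order(-pairs[[by]])                 # stable; highest first
  bounds <- floor(seq(0, n, length.out = 5L))
  sizes <- diff(bounds)
  lab <- integer(n)
  lab[ord] <- rep(1:4, times = sizes)
  factor(paste0("Q", lab), levels = paste0("Q", 1:4))
}

#' Remove population trends in vocal-state abundances
#'
#' Centres each state's abundance on its population mean (tutor and pupil
#' columns each centred on their own column means), making every vocal
#' state equally abundant in the population. This guarantees zero expected
#' correlation between tutor and pupil abundances when the pairing is
#' shuffled, which is the reference point for the residual regressions.
#'
#' @param pairs A pairs table.
#' @return The table with \code{tutor_p*}/\code{pupil_p*} columns replaced
#'   by centred values (which may be negative).
#' @export
detrend_abundances <- function(pairs) {
  if (nrow(pairs) < 2L) stop("need at least 2 pairs to detrend")
  for (role in c("tutor", "pupil")) {
    M <- pair_matrix(pairs, role)
    pairs[, p_cols(role)] <- sweep(M, 2, colMeans(M))
  }
  pairs
}

#' Regression of detrended pupil abundances on tutor abundances
#'
#' Each pair contributes ten (tutor, pupil) abundance points, detrended
#' with \code{\link{detrend_abundances}}. The default is ordinary least
#' squares with an optional cluster bootstrap by tutor for the slope's
#' standard error; \code{method = "lmer"} fits random intercepts for tutor
#' and pupil identity instead (requires lme4).
#'
#' @param pairs A pairs table (raw abundances; detrending is applied here).
#' @param group Optional logical/integer index selecting a subset of pairs
#'   (e.g. one similarity quartile).
#' @param method "ols" or "lmer".
#' @param cluster_boot Number of cluster-bootstrap resamples by tutor for
#'   the slope standard error (0 to skip; OLS only).
#' @param seed Seed for the bootstrap.
#' @return List with \code{slope}, \code{residual_R2}, \code{n_pairs} and,
#'   when bootstrapped, \code{slope_se_boot}.
#' @export
abundance_regression <- function(pairs, group = NULL, method = c("ols", "lmer"),
                                 cluster_boot = 0, seed = 1) {
  method <- match.arg(method)
  if (!is.null(group)) pairs <- pairs[group, , drop = FALSE]
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  pairs <- detrend_abundances(pairs)
  Tm <- pair_matrix(pairs, "tutor"); Pm <- pair_matrix(pairs, "pupil")
  long <- data.frame(t = as.vector(t(Tm)), p = as.vector(t(Pm)),
                     tutor_id = rep(pairs$tutor_id, each = 10L),
                     pupil_id = rep(pairs$pupil_id, each = 10L))
  if (stats::var(long$t) == 0 || stats::var(long$p) == 0)
    stop("degenerate abundances: zero variance")
  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("lme4 not available for method = 'lmer'")
    fit <- lme4::lmer(p ~ t + (1 | tutor_id) + (1 | pupil_id), data = long,
                      REML = FALSE)
    slope <- unname(lme4::fixef(fit)["t"])
    res <- stats::residuals(fit)
    r2 <- 1 - sum(res^2) / sum((long$p - mean(long$p))^2)
    return(list(slope = slope, residual_R2 = r2, n_pairs = nrow(pairs),
                method = "lmer"))
  }
  fit <- stats::lm(p ~ t, data = long)
  res <- stats::residuals(fit)
  out <- list(slope = unname(stats::coef(fit)["t"]),
              residual_R2 = 1 - sum(res^2) / sum((long$p - mean(long$p))^2),
              n_pairs = nrow(pairs), method = "ols")
  if (cluster_boot > 0) {
    ids <- unique(long$tutor_id)
    out$slope_se_boot <- with_seed(seed, {
      sl <- vapply(seq_len(cluster_boot), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        d <- do.call(rbind, lapply(take, function(i)
          long[long$tutor_id == i, , drop = FALSE]))
        unname(stats::coef(stats::lm(p ~ t, data = d))["t"])
      }, 0)
      stats::sd(sl)
    })
  }
  out
}

#' Diagonal bias of tutor vs pupil vocal-state abundances
#'
#' Among vocal states whose tutor abundance exceeds \code{threshold}, the
#' observed bias is the fraction whose pupil abundance falls below the
#' diagonal (pupil < tutor); the reverse bias swaps the roles. The test
#' statistic is their difference: positive when high-abundance tutor states
#' are preferentially attenuated by pupils (balancing), zero for exact
#' imitation.
#'
#' @param pairs A pairs table (raw abundances).
#' @param threshold Abundance threshold (default 0.2).
#' @return Object of class \code{bias_result} (no p-value; see
#'   \code{\link{direction_shuffle_test}}).
#' @export
diagonal_bias <- function(pairs, threshold = 0.2) {
  Tm <- pair_matrix(pairs, "tutor"); Pm <- pair_matrix(pairs, "pupil")
  st <- bias_statistic(Tm, Pm, threshold)
  if (st$n_obs + st$n_rev == 0L)
    stop("bias undefined: no abundance above threshold")
  structure(list(observed_bias = st$obs, reverse_bias = st$rev,
                 statistic = st$obs - st$rev,
                 n_above_tutor = st$n_obs, n_above_pupil = st$n_rev,
                 threshold = threshold),
            class = "bias_result")
}

bias_statistic <- function(Tm, Pm, threshold) {
  hi_t <- Tm > threshold
  hi_p <- Pm > threshold
  n_obs <- sum(hi_t); n_rev <- sum(hi_p)
  obs <- if (n_obs > 0) sum(Pm[hi_t] < Tm[hi_t]) / n_obs else 0
  rev <- if (n_rev > 0) sum(Tm[hi_p] < Pm[hi_p]) / n_rev else 0
  list(obs = obs, rev = rev, n_obs = n_obs, n_rev = n_rev)
}

#' Direction-shuffle test for the diagonal bias
#'
#' Null distribution obtained by randomly shuffling the direction
#' tutor-to-pupil vs pupil-to-tutor without breaking the pairs: each
#' shuffle independently swaps the two roles within each pair with
#' probability one half and recomputes the bias statistic. The direct
#' p-value is \code{(1 + #(shuffled >= observed)) / (1 + n_shuffles)}.
#'
#' @param pairs A pairs table.
#' @param threshold Abundance threshold.
#' @param n_shuffles Number of direction shuffles (at least 100).
#' @param seed Integer seed.
#' @return A \code{bias_result} with \code{p_value}, \code{n_shuffles} and
#'   \code{seed} filled in.
#' @export
direction_shuffle_test <- function(pairs, threshold = 0.2,
                                   n_shuffles = 1000, seed = 1) {
  if (n_shuffles < 100) stop("n_shuffles must be at least 100")
  base <- diagonal_bias(pairs, threshold)
  Tm <- pair_matrix(pairs, "tutor"); Pm <- pair_matrix(pairs, "pupil")
  n <- nrow(Tm)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      swap <- stats::runif(n) < 0.5
      T2 <- Tm; P2 <- Pm
      T2[swap, ] <- Pm[swap, ]; P2[swap, ] <- Tm[swap, ]
      st <- bias_statistic(T2, P2, threshold)
      st$obs - st$rev
    }, 0)
  })
  base$p_value <- (1 + sum(null_stats >= base$statistic)) / (1 + n_shuffles)
  base$n_shuffles <- n_shuffles
  base$seed <- seed
  base$null_statistics <- null_stats
  base
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result: observed %.3f, reverse %.3f, statistic %.3f%s>\n",
              x$observed_bias, x$reverse_bias, x$statistic,
              if (!is.null(x$p_value))
                sprintf(", p = %.4g (%d shuffles)", x$p_value, x$n_shuffles)
              else ""))
  invisible(x)
}

#' Abundance gain curve
#'
#' Tutor abundances are divided into bins of width \code{bin_width} centred
#' at 0.1, 0.2, ... (bin k covers [centre - w/2, centre + w/2)). For each
#' populated bin the median pupil abundance of the corresponding states is
#' computed, and the gain is that median divided by the bin centre: gain 1
#' means abundances are copied faithfully, 2 doubling, 0.5 halving.
#'
#' @param pairs A pairs table.
#' @param bin_width Bin width (and centre spacing).
#' @return A \code{gain_curve} data frame: \code{bin_center},
#'   \code{median_pupil}, \code{gain}, \code{n}.
#' @export
gain_curve <- function(pairs, bin_width = 0.1) {
  if (nrow(pairs) < 1L) stop("need at least 1 pair")
  tv <- as.vector(pair_matrix(pairs, "tutor"))
  pv <- as.vector(pair_matrix(pairs, "pupil"))
  centers <- seq(bin_width, 1, by = bin_width)
  rows <- lapply(centers, function(ct) {
    inb <- tv >= ct - bin_width / 2 & tv < ct + bin_width / 2
    if (!any(inb)) return(NULL)
    med <- stats::median(pv[inb])
    data.frame(bin_center = ct, median_pupil = med, gain = med / ct,
               n = sum(inb))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gain_curve", "data.frame")
  out
}

#' Pooled-song diversity of diversity (or influence) quartiles
#'
#' Tutors are split into quartiles of \code{by}; the bottom and top
#' quartiles' abundance vectors are pooled (equal weights) and the entropy
#' of each pooled song is reported alongside the per-bird mean diversities.
#'
#' @param pairs A pairs table.
#' @param by "tutor_diversity" or "influence".
#' @return List with \code{bottom_pooled_bits}, \code{top_pooled_bits},
#'   \code{bottom_mean_bits}, \code{top_mean_bits}, \code{n_per_quartile}.
#' @export
pooled_quartile_diversity <- function(pairs,
                                      by = c("tutor_diversity", "influence")) {
  by <- match.arg(by)
  if (nrow(pairs) < 8L) stop("need at least 8 pairs")
  key <- if (by == "tutor_diversity") pairs$tutor_diversity_bits else
    pairs$influence_pct
  q <- quartile_partition(within(pairs, similarity_pct <- key))
  Tm <- pair_matrix(pairs, "tutor")
  top <- q == "Q1"; bottom <- q == "Q4"
  pool_bits <- function(sel)
    shannon_diversity(normalize_p(colMeans(Tm[sel, , drop = FALSE])))
  list(bottom_pooled_bits = pool_bits(bottom),
       top_pooled_bits = pool_bits(top),
       bottom_mean_bits = mean(pairs$tutor_diversity_bits[bottom]),
       top_mean_bits = mean(pairs$tutor_diversity_bits[top]),
       n_per_quartile = sum(top))
}

#' Voiced-window mean song features
#'
#' @param track A \code{feature_track} with at least one voiced window.
#' @return Named vector: \code{mean_pitch}, \code{mean_fm},
#'   \code{mean_entropy}.
#' @export
mean_song_features <- function(track) {
  stopifnot(inherits(track, "feature_track"))
  v <- track$voiced
  if (!any(v)) stop("silent recording")
  c(mean_pitch = mean(track$pitch_hz[v]),
    mean_fm = mean(track$fm_deg[v]),
    mean_entropy = mean(track$wiener_entropy[v]))
}

#' Tutor mean-feature ranges for top vs bottom influence quartiles
#'
#' @param pairs A pairs table with \code{influence_pct}.
#' @param tutor_features Data frame with \code{bird_id} and feature columns
#'   \code{mean_pitch}, \code{mean_fm}, \code{mean_entropy} for each tutor.
#' @return Data frame: one row per (feature, quartile) with \code{lo},
#'   \code{hi}.
#' @export
influence_feature_ranges <- function(pairs, tutor_features) {
  q <- quartile_partition(within(pairs, similarity_pct <- influence_pct))
  feats <- c("mean_pitch", "mean_fm", "mean_entropy")
  rows <- list()
  for (which_q in c(top = "Q1", bottom = "Q4")) {
    ids <- pairs$tutor_id[q == which_q]
    fv <- tutor_features[tutor_features$bird_id %in% ids, , drop = FALSE]
    for (f in feats) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f,
        quartile = names(which(c(top = "Q1", bottom = "Q4") == which_q)),
        lo = min(fv[[f]]), hi = max(fv[[f]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-tutor diversity reversal table
#'
#' One row per tutor comparing his song diversity to the mean diversity of
#' all his pupils' songs; \code{direction} is "increase" when pupils are
#' more diverse, "decrease" when less, "tie" on exact equality.
#'
#' @param pairs A pairs table.
#' @return Data frame: \code{tutor_id}, \code{tutor_diversity_bits},
#'   \code{mean_pupil_diversity_bits}, \code{direction}.
#' @export
reversal_table <- function(pairs) {
  rows <- lapply(split(pairs, pairs$tutor_id), function(d) {
    mp <- mean(d$pupil_diversity_bits)
    delta <- mp - d$tutor_diversity_bits[1L]
    data.frame(tutor_id = d$tutor_id[1L],
               tutor_diversity_bits = d$tutor_diversity_bits[1L],
               mean_pupil_diversity_bits = mp,
               direction = if (delta > 0) "increase" else
                 if (delta < 0) "decrease" else "tie")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family-level coefficient-of-variance analysis of similarity
#'
#' Similarity scores are averaged within clutch; for each family (lineage)
#' with at least two clutches, the coefficient of variance of the clutch
#' means is computed; the across-family CV is the CV of the family means of
#' those clutch means.
#'
#' @param pairs A pairs table with \code{clutch_id} and \code{lineage_id}.
#' @return List with \code{within} (data frame: family, cv, n_clutches) and
#'   \code{across_cv}.
#' @export
family_cv_analysis <- function(pairs) {
  cv <- function(x) if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
  clutch_means <- stats::aggregate(
    similarity_pct ~ lineage_id + clutch_id, data = pairs, FUN = mean)
  fam <- split(clutch_means, clutch_means$lineage_id)
  multi <- Filter(function(d) nrow(d) >= 2L, fam)
  if (length(multi) == 0L) stop("no family with at least two clutches")
  within <- do.call(rbind, lapply(multi, function(d)
    data.frame(family = d$lineage_id[1L],
               cv = cv(d$similarity_pct), n_clutches = nrow(d))))
  rownames(within) <- NULL
  fam_means <- vapply(fam, function(d) mean(d$similarity_pct), 0)
  list(within = within, across_cv = cv(fam_means))
}

#' Bonferroni adjustment utility
#'
#' @param p Vector of p-values.
#' @param alpha Family-wise level (reporting threshold 0.01 by default).
#' @return Data frame with adjusted p-values and significance flags.
#' @export
bonferroni_adjust <- function(p, alpha = 0.01) {
  adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(p = p, p_adj = adj, significant = adj < alpha)
}
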