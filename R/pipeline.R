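#' Pipeline configuration
#'
#' Bundles the stage configurations and seeds for
#' \code{\link{run_pipeline}}. Serialises to JSON and back unchanged, so a
#' report directory fully records how it was produced.
#'
#' @param feature A \code{\link{feature_config}}.
#' @param partition A \code{\link{partition_config}}.
#' @param alpha Similarity section significance level.
#' @param repeats Similarity jitter repeats.
#' @param null_samples Null-model window pairs.
#' @param threshold Diagonal-bias abundance threshold.
#' @param bin_width Gain-curve bin width.
#' @param n_shuffles Direction shuffles.
#' @param seed Master seed for all randomised stages.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(feature = feature_config(),
                            partition = partition_config(),
                            alpha = 0.05, repeats = 5, null_samples = 5000,
                            threshold = 0.2, bin_width = 0.1,
                            n_shuffles = 1000, seed = 1) {
  stopifnot(alpha > 0, repeats > 0, null_samples > 0, threshold > 0,
            bin_width > 0, n_shuffles > 0)
  structure(list(feature = unclass(feature), partition = unclass(partition),
                 alpha = alpha, repeats = repeats,
                 null_samples = null_samples, threshold = threshold,
                 bin_width = bin_width, n_shuffles = n_shuffles, seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param config A \code{pipeline_config}.
#' @param path JSON path.
#' @return \code{path} / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    feature = do.call(feature_config, obj$feature),
    partition = do.call(partition_config, obj$partition),
    alpha = obj$alpha, repeats = obj$repeats,
    null_samples = obj$null_samples, threshold = obj$threshold,
    bin_width = obj$bin_width, n_shuffles = obj$n_shuffles, seed = obj$seed)
  cfg
}

#' Read a tutor-pupil pairs table
#'
#' CSV or TSV (by extension) with a header. Columns \code{tutor_id} and
#' \code{pupil_id} are required; \code{relation}, \code{clutch_id} and
#' \code{lineage_id} are optional, and unknown columns pass through.
#'
#' @param path File path.
#' @return Data frame of pair records.
#' @export
read_pairs_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("tutor_id", "pupil_id"))
    if (!col %in% names(df)) stop("pairs table missing required column: ", col)
  if (any(df$tutor_id == "" | df$pupil_id == ""))
    stop("empty bird id in pairs table")
  key <- paste(df$tutor_id, df$pupil_id)
  if (anyDuplicated(key))
    stop("duplicate tutor-pupil rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df
}

read_feature_track <- function(path) {
  tr <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(tr, "meta") <- meta
  class(tr) <- c("feature_track", "data.frame")
  tr
}

#' Run the full analysis pipeline on a corpus of song recordings
#'
#' Stages: per-bird feature extraction (cached as CSV under
#' \code{out_dir/cache} and reused when the configuration is unchanged);
#' population partition fit; state assignment, abundances and song
#' diversity per bird; empirical null; similarity and influence per pair;
#' balanced-imitation statistics. Reports are written as CSV/JSON under
#' \code{out_dir} and the filled pairs table is returned.
#'
#' @param corpus_dir Directory containing one \code{<bird_id>.wav} per bird.
#' @param pairs A pairs table (data frame) or path to one.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with \code{pairs} (filled table),
#'   \code{partition}, \code{null}, \code{abundances}.
#' @export
run_pipeline <- function(corpus_dir, pairs, config = pipeline_config(),
                         out_dir) {
  if (is.character(pairs)) pairs <- read_pairs_table(pairs)
  ids <- unique(c(pairs$tutor_id, pairs$pupil_id))
  wavs <- file.path(corpus_dir, paste0(ids, ".wav"))
  missing <- ids[!file.exists(wavs)]
  if (length(missing))
    stop("missing audio for ids: ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(cache_dir, "config.json")
  cache_ok <- file.exists(cfg_path) &&
    identical(as.character(cfg_json), paste(readLines(cfg_path, warn = FALSE),
                                            collapse = ""))
  writeLines(as.character(cfg_json), cfg_path)

  fcfg <- do.call(feature_config, config$feature)
  tracks <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    cpath <- file.path(cache_dir, paste0("features_", ids[i], ".csv"))
    if (cache_ok && file.exists(cpath)) {
      tracks[[i]] <- read_feature_track(cpath)
    } else {
      tracks[[i]] <- compute_features(read_wav(wavs[i]), fcfg)
      write_feature_track(tracks[[i]], cpath)
    }
    attr(tracks[[i]], "bird_id") <- ids[i]
  }

  partition <- fit_partition(tracks, do.call(partition_config,
                                             config$partition))
  write_partition(partition, file.path(out_dir, "partition.json"))

  ab <- lapply(ids, function(id) {
    av <- state_abundances(assign_states(tracks[[id]], partition,
                                         bird_id = id))
    c(list(bird_id = id), stats::setNames(as.list(av$p), paste0("p", 1:10)),
      list(n_windows = av$n_windows, diversity_bits = shannon_diversity(av)))
  })
  abundances <- do.call(rbind, lapply(ab, as.data.frame))
  utils::write.csv(abundances, file.path(out_dir, "abundances.csv"),
                   row.names = FALSE)

  null <- build_null(tracks, seed = config$seed,
                     n_samples = config$null_samples)
  write_null(null, file.path(out_dir, "null.json"))

  rowsf <- lapply(seq_len(nrow(pairs)), function(k) {
    tid <- pairs$tutor_id[k]; pid <- pairs$pupil_id[k]
    s <- similarity_score(tracks[[tid]], tracks[[pid]], null,
                          alpha = config$alpha, repeats = config$repeats,
                          seed = config$seed + k)
    infl <- influence_score(tracks[[tid]], tracks[[pid]], null,
                            alpha = config$alpha, repeats = config$repeats,
                            seed = config$seed + k)
    r <- pairs[k, , drop = FALSE]
    r$similarity_pct <- s$similarity_pct
    r$influence_pct <- infl$similarity_pct
    r$tutor_diversity_bits <-
      abundances$diversity_bits[abundances$bird_id == tid]
    r$pupil_diversity_bits <-
      abundances$diversity_bits[abundances$bird_id == pid]
    r[, p_cols("tutor")] <-
      as.list(unlist(abundances[abundances$bird_id == tid, paste0("p", 1:10)]))
    r[, p_cols("pupil")] <-
      as.list(unlist(abundances[abundances$bird_id == pid, paste0("p", 1:10)]))
    r
  })
  filled <- do.call(rbind, rowsf)
  rownames(filled) <- NULL
  utils::write.csv(filled, file.path(out_dir, "pairs_report.csv"),
                   row.names = FALSE)

  gc_tab <- gain_curve(filled, config$bin_width)
  utils::write.csv(gc_tab, file.path(out_dir, "gain_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(reversal_table(filled),
                   file.path(out_dir, "reversals.csv"), row.names = FALSE)
  summary <- list(n_pairs = nrow(filled),
                  mean_similarity_pct = mean(filled$similarity_pct),
                  mean_influence_pct = mean(filled$influence_pct),
                  pooled_diversity_bits = shannon_diversity(
                    normalize_p(colMeans(pair_matrix(filled, "tutor")))),
                  seed = config$seed)
  bias <- tryCatch(direction_shuffle_test(filled, config$threshold,
                                          config$n_shuffles, config$seed),
                   error = function(e) NULL)
  if (!is.null(bias)) {
    summary$bias_statistic <- bias$statistic
    summary$bias_p_value <- bias$p_value
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pairs = filled, partition = partition, null = null,
                 abundances = abundances))
}
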