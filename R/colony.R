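#' Colony simulation parameters
#'
#' Describes a synthetic tutor-pupil colony. The defaults emulate the
#' structure of the study corpus: 160 pairs whose tutors carry a left-tailed
#' song-diversity distribution (median ~3.1 bits, truncated at 2.3 bits),
#' copy fidelity varying across pairs around the colony mean with a
#' family-level component (so similarity spans roughly 20-100% and varies
#' more across families than within), about one pair in five fostered, and a
#' balancing exponent below 1 so pupils flatten their tutors' abundance
#' vectors toward uniform.
#'
#' @param n_pairs Number of tutor-pupil pairs.
#' @param balancing_exponent Exponent beta of the abundance power transform:
#'   pupil target = normalise(tutor^beta). 1 = faithful copying of
#'   abundances; smaller values flatten high abundances and boost rare ones.
#' @param copy_fidelity Colony-mean fraction of tutor material copied.
#' @param fidelity_concentration Beta-distribution concentration of per-pair
#'   fidelity around the (family-adjusted) mean.
#' @param family_sd Standard deviation of the family effect on logit
#'   fidelity.
#' @param n_families Number of families (lineages).
#' @param max_clutches Maximum clutches per family.
#' @param lineage_depth Number of generations (2 = grand-pupils whose tutors
#'   are generation-1 pupils).
#' @param n_windows Voiced windows per bird used to realise abundance
#'   vectors.
#' @param improv_base,improv_slope Improvised share of the pupil song:
#'   base rate plus slope times the tutor's diversity deficit (3.32 -
#'   tutor bits), so low-diversity tutors exert less influence.
#' @param foster_fraction Fraction of fostered pairs.
#' @param seed Integer seed.
#' @return List of class \code{colony_spec}.
#' @export
colony_spec <- function(n_pairs = 160, balancing_exponent = 0.8,
                        copy_fidelity = 0.7, fidelity_concentration = 20,
                        family_sd = 0.8, n_families = 24, max_clutches = 3,
                        lineage_depth = 1, n_windows = 2500,
                        improv_base = 0.12, improv_slope = 0.35,
                        foster_fraction = 0.19, seed = 1) {
  if (balancing_exponent <= 0 || balancing_exponent > 1)
    stop("balancing_exponent must be in (0, 1]")
  if (copy_fidelity < 0 || copy_fidelity > 1)
    stop("copy_fidelity must be in [0, 1]")
  structure(as.list(environment()), class = "colony_spec")
}

#' Derive a pupil song specification from its tutor's
#'
#' Copies a \code{copy_fidelity} fraction of the tutor's syllable elements
#' (parameters jittered by at most 5%) and adds improvised elements drawn
#' from the archetype pool so the pupil's target state-abundance vector is
#' the renormalised power transform \code{tutor_p^beta}. Improvisation
#' therefore concentrates on states the tutor rarely uses, keeping
#' improvised material largely disjoint from the copied material in feature
#' space. Ground truth (copied flags, targets) is attached as attributes.
#'
#' @param tutor_spec A \code{\link{song_spec}} with state-labelled elements.
#' @param colony A \code{\link{colony_spec}} (beta and fidelity are read
#'   from it).
#' @param seed Integer seed.
#' @param copy_fidelity Optional per-pair override of the colony fidelity.
#' @return A \code{song_spec} with attributes \code{"p_target"} and
#'   \code{"copied"}.
#' @export
simulate_pupil <- function(tutor_spec, colony = colony_spec(), seed = 1,
                           copy_fidelity = NULL) {
  stopifnot(inherits(tutor_spec, "song_spec"))
  fid <- if (is.null(copy_fidelity)) colony$copy_fidelity else copy_fidelity
  beta <- colony$balancing_exponent
  tutor_p <- spec_abundance(tutor_spec)
  target <- normalize_p((tutor_p + 1e-9)^beta)
  with_seed(seed, {
    m <- length(tutor_spec$motif)
    n_copy <- round(fid * m)
    copy_idx <- if (n_copy > 0) sort(sample.int(m, n_copy)) else integer(0)
    jit <- function(x, lo, hi) min(hi, max(lo, x * stats::runif(1, 0.96, 1.04)))
    copied <- lapply(tutor_spec$motif[copy_idx], function(sp)
      syllable_spec(max(24, jit(sp$duration_ms, 24, 4000)),
                    jit(sp$f0_start_hz, 300, 3000),
                    jit(sp$f0_end_hz, 300, 3000),
                    sp$n_harmonics, sp$noise_fraction, sp$amplitude_db,
                    state = sp$state))
    total_ms <- sum(vapply(tutor_spec$motif, `[[`, 0, "duration_ms"))
    copied_ms <- numeric(10)
    for (sp in copied) copied_ms[sp$state] <- copied_ms[sp$state] + sp$duration_ms
    deficit <- pmax(0, target * total_ms - copied_ms)
    arch <- state_archetypes()
    improvised <- list()
    for (st in order(deficit, decreasing = TRUE)) {
      if (deficit[st] < 24) next
      a <- arch[[st]]
      n_el <- max(1L, round(deficit[st] / 80))
      for (e in seq_len(n_el)) {
        j <- 1 + 0.08 * stats::runif(2, -1, 1)
        improvised[[length(improvised) + 1L]] <-
          syllable_spec(max(24, deficit[st] / n_el),
                        min(3000, max(300, a$f0_start_hz * j[1])),
                        min(3000, max(300, a$f0_end_hz * j[2])),
                        a$n_harmonics, a$noise_fraction, state = a$state)
      }
    }
    motif <- c(copied, improvised)
    if (length(motif) == 0L) motif <- tutor_spec$motif
    mlen <- length(motif)
    n_syl <- max(2L, min(6L, ceiling(mlen / 2)))
    syl_of <- sort(rep_len(seq_len(n_syl), mlen))
    gaps <- if (mlen > 1)
      ifelse(diff(syl_of) == 0, 0, round(stats::runif(mlen - 1, 35, 55)))
    else numeric(0)
    sp <- song_spec(motif, gap_ms = 45, gaps_ms = gaps,
                    n_repeats = tutor_spec$n_repeats,
                    seed = stats::runif(1, 1, 2^30))
    attr(sp, "p_target") <- target
    attr(sp, "copied") <- seq_along(copied)
    sp
  })
}

#' Simulate a tutor-pupil colony with known ground truth
#'
#' Draws tutors with the colony's left-tailed diversity distribution,
#' derives each pupil's target abundance vector by the balancing power
#' transform plus fidelity-dependent imitation noise, realises abundance
#' vectors as multinomial window counts, and fills in similarity/influence
#' scores from the generative parameters (similarity tracks copy fidelity;
#' influence is similarity discounted by the improvised share, which grows
#' as tutor diversity falls). With \code{render_audio = TRUE} (intended for
#' small colonies) each bird also receives a rendered \code{song_spec} so
#' the full audio pipeline can be run against the same truth.
#'
#' @param colony A \code{\link{colony_spec}}.
#' @param render_audio Also build song specifications and audio clips.
#' @return List of class \code{colony}: \code{pairs} (the pairs table:
#'   ids, relation, clutch/lineage, similarity, influence, diversities and
#'   abundance columns \code{tutor_p1..10}, \code{pupil_p1..10},
#'   \code{generation}), \code{truth} (targets, fidelities, improvised
#'   shares), and optionally \code{specs}/\code{clips} keyed by bird id.
#' @export
simulate_colony <- function(colony = colony_spec(), render_audio = FALSE) {
  stopifnot(inherits(colony, "colony_spec"))
  n <- colony$n_pairs
  empty <- function() data.frame(tutor_id = character(0),
                                 pupil_id = character(0))
  if (n == 0L) return(structure(list(pairs = empty(), truth = list()),
                                class = "colony"))
  with_seed(colony$seed, {
    n_gen1 <- if (colony$lineage_depth > 1) ceiling(n / 2) else n
    fam_effect <- stats::rnorm(colony$n_families, 0, colony$family_sd)
    fam_clutches <- sample.int(colony$max_clutches, colony$n_families,
                               replace = TRUE)
    rows <- list(); truth <- list()
    specs <- list(); clips <- list()
    gen1_pupils <- list()

    make_bird <- function(target_p) {
      counts <- stats::rmultinom(1, colony$n_windows, target_p)[, 1]
      normalize_p(counts)
    }

    pair_row <- function(k, gen, tutor_id, pupil_id, tutor_target,
                         fam, clutch) {
      fid_mean <- stats::plogis(stats::qlogis(colony$copy_fidelity) +
                                  fam_effect[fam])
      a <- fid_mean * colony$fidelity_concentration
      b <- (1 - fid_mean) * colony$fidelity_concentration
      fid <- stats::rbeta(1, a, b)
      tutor_p <- make_bird(tutor_target)
      h_tutor <- shannon_diversity(tutor_p)
      pupil_target <- normalize_p((tutor_target + 1e-9)^
                                    colony$balancing_exponent)
      noise_sd <- 0.10 + 0.60 * (1 - fid)
      pupil_target <- normalize_p(pupil_target *
                                    exp(stats::rnorm(10, 0, noise_sd)))
      pupil_p <- make_bird(pupil_target)
      similarity <- 100 * min(1, max(0.15, fid + stats::rnorm(1, 0, 0.04)))
      improv <- min(0.8, max(0.02, colony$improv_base +
                               colony$improv_slope * (3.3219 - h_tutor) +
                               stats::rnorm(1, 0, 0.05)))
      influence <- similarity * (1 - improv)
      rec <- data.frame(tutor_id = tutor_id, pupil_id = pupil_id,
                        relation = if (stats::runif(1) < colony$foster_fraction)
                          "foster" else "biological",
                        clutch_id = sprintf("F%02d_C%d", fam, clutch),
                        lineage_id = sprintf("F%02d", fam),
                        similarity_pct = similarity,
                        influence_pct = influence,
                        tutor_diversity_bits = h_tutor,
                        pupil_diversity_bits = shannon_diversity(pupil_p),
                        generation = gen)
      rec[, p_cols("tutor")] <- as.list(tutor_p)
      rec[, p_cols("pupil")] <- as.list(pupil_p)
      list(rec = rec, pupil_target = pupil_target, tutor_target = tutor_target,
           fidelity = fid, improvised_share = improv, tutor_p = tutor_p,
           pupil_p = pupil_p)
    }

    for (k in seq_len(n_gen1)) {
      fam <- sample.int(colony$n_families, 1L)
      clutch <- sample.int(fam_clutches[fam], 1L)
      h <- sample_tutor_diversity(1)
      tutor_target <- abundance_for_diversity(h)
      tid <- sprintf("T%03d", k); pid <- sprintf("P%03d", k)
      pr <- pair_row(k, 1L, tid, pid, tutor_target, fam, clutch)
      rows[[length(rows) + 1L]] <- pr$rec
      truth[[pid]] <- pr
      gen1_pupils[[length(gen1_pupils) + 1L]] <-
        list(id = pid, target = pr$pupil_target, fam = fam)
      if (render_audio) {
        t_spec <- song_spec_for_abundance(tutor_target,
                                          seed = round(stats::runif(1, 1, 2^30)))
        p_spec <- simulate_pupil(t_spec, colony,
                                 seed = round(stats::runif(1, 1, 2^30)),
                                 copy_fidelity = pr$fidelity)
        specs[[tid]] <- t_spec; specs[[pid]] <- p_spec
        clips[[tid]] <- synth_song(t_spec)
        clips[[pid]] <- synth_song(p_spec)
      }
    }

    if (colony$lineage_depth > 1 && n > n_gen1) {
      for (k in seq_len(n - n_gen1)) {
        src <- gen1_pupils[[sample.int(length(gen1_pupils), 1L)]]
        fam <- src$fam
        clutch <- sample.int(fam_clutches[fam], 1L)
        gid <- sprintf("G%03d", k)
        pr <- pair_row(n_gen1 + k, 2L, src$id, gid, src$target, fam, clutch)
        rows[[length(rows) + 1L]] <- pr$rec
        truth[[gid]] <- pr
      }
    }

    pairs <- do.call(rbind, rows)
    rownames(pairs) <- NULL
    out <- list(pairs = pairs, truth = truth, colony = colony)
    if (render_audio) { out$specs <- specs; out$clips <- clips }
    structure(out, class = "colony")
  })
}
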