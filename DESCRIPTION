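Package: finchsong
Title: Vocal-State Diversity and Balanced Imitation in Zebra Finch Song
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how zebra finch pupils imitate tutor songs at
    the sub-syllabic level. Extracts sliding-window acoustic features (pitch,
    frequency modulation, Wiener entropy, spectral continuity) from song
    recordings, fits a population-level partition of acoustic space into ten
    vocal states, and measures song diversity as the Shannon entropy of
    vocal-state abundances. Provides asymmetric similarity scoring between
    songs (tutor-referenced similarity and pupil-referenced influence) against
    an empirical null, amplitude-threshold syllable segmentation with
    type clustering and merge/split recombination detection, and the
    balanced-imitation statistics: detrended abundance regressions, abundance
    gain curves, a diagonal-bias test with a pair-preserving direction-shuffle
    null, pooled-diversity contrasts and family-level variance analyses. A
    synthetic-song module generates tutor-pupil colonies with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
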