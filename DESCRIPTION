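Package: villustrack
Title: Motility Analysis of Intravital Lymphocyte Tracks in the Intestinal Villus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-track and cohort motility statistics for intravital two-photon
    cell tracks of intestinal lymphocytes: instantaneous speed, arrest
    coefficient, straightness ratio and overlapping-interval mean squared
    displacement, with the preprocessing used on such movies (2D projection of
    3D positions, robust XY tissue-drift correction, gap splitting and
    minimum-duration filtering), a spot/wavy migration-pattern classifier, and
    cohort comparisons (Mann-Whitney U, one-way ANOVA). Includes a two-state
    (arrested/patrolling) persistent-random-walk simulator of villus
    lymphocytes under imaging-like acquisition, with named regime presets
    calibrated to published cohort statistics, so analyses can be exercised
    and validated without raw movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
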