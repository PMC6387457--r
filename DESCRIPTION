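Package: swardscan
Title: On-Ground 3D Sward Characterization from Fused Depth Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs grassland sward plots from sequences of depth
    frames by hashed truncated-signed-distance (TSDF) fusion with ray-cast
    model prediction and iterative-closest-point pose tracking, filters the
    resulting point clouds with a 64-nearest-neighbour statistical outlier
    rule, and extracts canopy traits: plant height by pre/post-harvest model
    differencing, cover area, 3D alpha-shape volume and digital-surface-model
    solid volume. A synthetic canopy generator emulates ryegrass-dominant
    (dense tillering, leaves bent to a common height) and timothy-dominant
    (taller, sparser, height-driven biomass) swards together with tape,
    rising-plate-meter and dry-biomass ground truth, so the full
    simulate-reconstruct-filter-traits-statistics pipeline is testable
    end to end. A validation layer provides simple linear regression with
    Pearson/R-squared summaries, replicate-based lack-of-fit tests and
    between-field equality-of-lines ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
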