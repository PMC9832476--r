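Package: sfstate
Title: Selectivity-Filter State Analysis for Potassium-Channel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of potassium-channel selectivity-filter (SF) states in
    molecular-dynamics trajectories. Estimates K+ occupancy of binding sites
    S0-S4 and oxygen coordination with a rational 6/12 switching function,
    profiles ion presence and hydration along the pore axis of the
    intracellular cavity, detects cavity ion dwell events, measures
    opposite-subunit (diagonal) distances and SF backbone RMSD against
    reference structures, and clusters frames by ion configuration using
    Ward-linkage agglomerative clustering with silhouette-based selection of
    the number of clusters. Includes a synthetic tetrameric-SF ensemble
    generator with planted geometry states, ion schedules and thermal noise
    so every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
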