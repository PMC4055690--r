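Package: ampdyn
Title: Temporal Dynamics of Amplicon-Surveyed Microbial Communities Under Primer Bias
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of monthly 16S rRNA amplicon time series from activated
    sludge and similar engineered ecosystems, built around the question of
    whether region-specific PCR primer bias distorts community dynamics as
    opposed to community composition. Provides subsampling normalization,
    rarefaction, Shannon diversity, Bray-Curtis and (un)weighted UniFrac
    distances, PCoA/NMDS ordination, Mantel, Procrustes/PROTEST and
    constrained-ordination (CAP) permutation inference, temporal-core
    detection, moving-window analysis, similarity-decay regression, the
    taxa-time relationship power law S = c*T^w, FISH biovolume quantification
    from probe/DAPI masks, and a synthetic community time-series generator
    with region-specific multiplicative primer bias for property-based
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
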