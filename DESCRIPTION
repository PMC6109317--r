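Package: phylosym
Title: Phylosymbiosis and Phylogenetic Diversity Analysis of Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing host-associated microbial
    communities against host phylogeny and ecology: phylogenetic entropy
    (Allen's index) and abundance-weighted UniFrac computed from a microbial
    chronogram, permutation tests of phylogenetic signal (Moran's I, Pagel's
    lambda) and of community drivers (Mantel, PERMANOVA with sequential sums
    of squares), Sloan's neutral community model fit, beta-diversity-through-
    time tree slicing, and core-microbiome extraction. Intraspecific
    variability is handled by two species-level strategies: repeated
    subsampling of one individual per species (Method A) and averaging of
    relative abundances within species (Method B). A synthetic-data module
    generates host trees, microbial chronograms and OTU tables with
    controllable phylosymbiosis strength and intraspecific variability so the
    whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
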