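Package: arealink
Title: Spatial Interoperability of Misaligned Aggregated Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for making two spatially misaligned aggregated databases
    (for example a hospital-discharge database and a census-style ecological
    database) interoperable without spatial disaggregation. A mapping table is
    built from one or more transition matrices (ID crosswalks), spatial units
    that share a source unit are merged into analysis units, variables are
    aggregated to the analysis scale, and the result is validated with
    relative-difference statistics on a shared variable plus spatial quality
    indices (fragmentation of discontinuous units, centroid containment and a
    spatial-resolution decline index). Includes a seeded synthetic-geography
    generator with planted equivalence situations, fragmentation and
    undercount, used as the test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
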