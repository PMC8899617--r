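Package: refugia
Title: Mapping Persistent Precipitation Refugia from Gridded Palaeoclimate Time Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying persistent climate refugia from gridded
    mean-annual-precipitation time slices spanning the Late Pleistocene
    (130-10 ka). Habitability envelopes are derived from ethnographic
    hunter-gatherer precipitation niches, persistence masks are computed
    across all time slices, and refugial zones are characterized through
    temporal precipitation statistics, biome richness and alternation
    dynamics, open/forest ecotone persistence in moving 3x3 neighbourhoods,
    and the relationship of dated archaeological occupations to the
    refugial zones. Includes a seeded synthetic-data generator with planted
    ground truth and an end-to-end pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
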