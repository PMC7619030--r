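Package: lingmap
Title: Retrieving Spatial Layouts of Transit Networks from Distributional Semantics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to test whether the spatial layout of medium-scale
    environments (networks of underground stations) is recoverable from
    word embeddings. Reads fastText-style '.vec' embedding files with
    subword n-gram composition for out-of-vocabulary multi-word station
    labels, computes cosine-based linguistic distances between station
    pairs and anchor-word linguistic latitude/longitude coordinates,
    pairs them with great-circle geographic distances, calibrates
    digitized schematic-map coordinates by affine least squares, and
    fits the corresponding crossed random-intercept mixed models and
    interaction linear models with per-city simple slopes. A synthetic
    generator produces cities and embedding spaces in which cosine
    similarity partially encodes planar position, so the whole pipeline
    and its recovery properties are testable without pretrained
    embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    car,
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
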