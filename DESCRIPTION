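Package: tetrakey
Title: Morphometric Indices, Dichotomous Keys and Checklist Analytics for
    Indian Tetramorium Ants
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for identification of Indian Tetramorium (Hymenoptera,
    Formicidae) worker ants. Computes the 13 standard morphometric ratio
    indices from 14 linear measurements, applies the reporting-precision
    rounding convention used in taxonomic descriptions, and checks printed
    index values against measurement data under rounding uncertainty using
    interval arithmetic. Ships data-encoded dichotomous identification keys
    (species-group key for India, and species keys for the T. inglebyi and
    T. tonganum groups) with a deterministic traversal engine that also
    supports partial knowledge (set-valued identification), the updated
    species checklist with endemic/exotic flags and species-group
    diagnoses, specimen-to-species matching against type-series measurement
    ranges, and seeded synthetic-specimen generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
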