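Package: persistLSD
Title: Persistence Modelling for Declining Populations by Latent Selection
    Difference with Imperfect Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models population persistence across a set of historically
    occupied sites as a latent selection difference (LSD): an exponential
    (logistic-discriminant) contrast between sites where a population
    persisted and sites where it was extirpated.  Extends the LSD with a
    single-season site-occupancy likelihood so that imperfect detection over
    repeat surveys is modelled explicitly, ranks candidate models by AICc
    with Akaike weights, assesses fit by parametric-bootstrap goodness of
    fit (c-hat), and ships a detection-history simulator emulating a
    43-lake, three-visit waterbird survey design so every component is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
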