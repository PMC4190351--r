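Package: conqual
Title: Confidence Ratings for Synthesised Qualitative Evidence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rates confidence in the synthesised findings of meta-aggregative
    qualitative systematic reviews using the ConQual approach. Each synthesised
    finding starts at a 'High' rating on the ordinal scale High, Moderate, Low,
    Very Low and is downgraded for dependability (assessed from five critical
    appraisal questions per study) and credibility (the Unequivocal, Equivocal,
    Unsupported rating of each constituent finding). Provides a JSON/YAML review
    document schema with validation, a Summary of Findings table renderer
    (Markdown, HTML, CSV), a seeded generator of synthetic review documents for
    testing and exploration, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
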