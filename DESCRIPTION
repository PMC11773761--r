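Package: householdseg
Title: Household-Level Segmentation of Linked Health and Social Care Records
Version: 0.1.0
Authors@R:
    person("CIPHA", "Analytics", email = "analytics@example.org", role = c("aut", "cre"))
Description: Derives analysis households from pseudonymised address
    identifiers in linked health and social care records, classifies
    households with children against a four-criterion definition of complex
    cross-sectoral need (adult physical-mental comorbidity, child health or
    social problems, social vulnerability, top-quartile per-capita
    cost-weighted utilisation), and profiles the resulting segment:
    criteria and prevalence tables, sector cost shares, service co-use
    intersections, and stratified odds ratios contrasting emergency
    mental-health attendance by prior service contact. Ships a synthetic
    linked-data generator with planted ground truth so every pipeline stage
    can be exercised without access to restricted records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
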