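Package: habbank
Title: Ecological Accounting for Aquatic Habitat Banking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ledger engine for aquatic habitat banking within a bounded
    service area. Habitat parcels are valued in productivity-weighted
    suitable area (PWSA) units: parcel area times habitat suitability,
    scaled by an ecotype-level potential productivity index (PPI).
    Deposits (habitat creation or enhancement), withdrawals (development
    impacts), equivalency trades with an inverse offset-area solver,
    natural-capital reserves, maturation holds on new deposits, and
    inter-area transfers are recorded in an append-only transaction
    journal that can be replayed deterministically. Balance sheets,
    quality-class summaries and progress-toward-objective reports are
    rendered from the journal; parcel inventories are read from CSV or
    GeoJSON and journals persist as JSON lines. Includes a packaged
    Toronto-nearshore worked example and a synthetic service-area
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
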