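Package: dutchpt
Title: Dynamic Prospect-Theory Modelling of Competitive Dutch-Auction Bidding
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying competitive bidding in descending-price (Dutch)
    auctions with a dynamic extension of cumulative prospect theory. Three
    concurrent agents repeatedly choose between bidding now at the current
    clock price and waiting for a lower price at the risk of losing to a
    competitor; per-step choice probabilities combine a reference-dependent
    power utility, inverse-S probability weighting, a competitor-bid hazard
    derived from a believed bid-time distribution, and a softmax choice rule.
    Includes a Monte-Carlo group-auction simulator, a synthetic trial-log
    generator emulating a three-player laboratory auction platform, the
    accompanying analysis pipeline (Pearson correlations, start-price binning,
    pooled and paired comparisons, default Jeffreys-Zellner-Siow Bayes
    factors computed by numerical integration), and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
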