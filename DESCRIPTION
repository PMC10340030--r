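Package: bullval
Title: Economic Valuation and Replacement Ranking of Dairy AI Bulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision support for bull replacement at artificial-insemination
    (AI) studs. Models a bull herd as an age-binned Markov chain with
    involuntary culling and constant-herd regeneration, aggregates a
    discounted net present value from semen income, maintenance, culling
    cost with linear depreciation and salvage income, smooths blended
    order-level semen prices by empirical Bayes shrinkage, and values every
    bull against a reference young replacement, flagging bulls whose
    relative value is negative for culling. Includes seeded synthetic-data
    generators for herds, collection histories and blended sales orders so
    the full pipeline can be exercised without proprietary company data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
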