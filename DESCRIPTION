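Package: grazenet
Title: Costing Net-Zero Transitions for Grazing Livestock Farms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Farm-systems analysis for grazing livestock enterprises moving
    toward net-zero greenhouse gas emissions. Provides delta-scaled climate
    projections, a seasonal synthetic pasture and livestock production
    generator, a monthly five-pool RothC soil organic carbon model over two
    depth layers, a saturating tree-stand carbon sequestration curve, a
    Tier-2 style farm greenhouse gas inventory with GWP100 accounting and
    protein-mass allocation, a composable intervention algebra for stacking
    adaptation and mitigation bundles, correlated-price Monte Carlo
    economics with a hybrid carbon tax and credit mechanism, marginal
    abatement cost curves, and a normalised multidimensional impact score.
    All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
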