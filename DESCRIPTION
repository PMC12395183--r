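Package: ecostoich
Title: Community Leaf Stoichiometry, Nutrient Resorption and Homeostasis Along Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community-level ecological stoichiometry along environmental
    gradients: community-weighted mean leaf C, N and P with Shannon and Pielou
    alpha-diversity; mass-loss-corrected nitrogen and phosphorus resorption
    efficiency; classification of the community resorption control strategy from
    a power-law fit of the resorbed N:P ratio against green-leaf N:P; the
    stoichiometric homeostasis index H with Persson's state classification;
    N:P nutrient-limitation calls under the Koerselman-Meuleman and Guesewell
    threshold schemes; polynomial elevation-trend fitting with AICc model
    selection; and a synthetic-community generator with known ground truth for
    end-to-end verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
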