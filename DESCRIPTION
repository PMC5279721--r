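Package: phosym
Title: Kinase-Phosphatase Impact Hierarchies and Writer-Eraser Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the asymmetric organization of opposing
    post-translational modification enzymes (writers such as kinases versus
    erasers such as phosphatases). Builds directed impact networks from
    perturbation screens, partitions enzymes into hierarchy layers under a
    simple and a stringent scheme, profiles each layer against annotation
    metrics, runs the class-asymmetry statistical battery (exact rank-sum and
    Fisher tests, Spearman correlation), and evaluates the first-order
    phosphorylation-dynamics model relating steady-state level and response
    time to kinase and phosphatase activity rates. Includes a synthetic-data
    generator producing annotation tables and planted-hierarchy networks with
    the statistical structure of the yeast kinome screens, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
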