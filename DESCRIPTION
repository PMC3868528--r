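Package: tetradkit
Title: Tetrad Analysis of Meiotic Crossover Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classical tetrad genetics for budding yeast: classification of
    four-spore tetrads into parental ditype, non-parental ditype and
    tetratype for pairs of linked markers; Perkins map distances with
    delta-method standard errors; crossover interference via NPD ratios
    (Papazian expectation) and adjacent-interval coincidence, including
    purging of non-exchange (E0) tetrads; crossover assurance tests against
    a Poisson null; spore viability, meiosis I nondisjunction (disome) and
    gene-conversion phenotyping; ratio arithmetic for quantified molecular
    species (interhomolog versus intersister double Holliday junctions,
    crossover/non-crossover fractions, crossover-bias compensation); and a
    forward meiosis simulator with controllable crossover number,
    interference, assurance failure, conversion, nondisjunction and spore
    viability for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
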