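Package: creolegame
Title: Naming-Game Dynamics of Creole Emergence in Structured Colonial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Naming-Game dynamics for the emergence of contact
    languages (creoles) in a three-group colonial population of Europeans,
    Mulattos (Free Colored) and Bozal slaves. Agents hold repertoires drawn
    from a European lexifier E, a coarse-grained African substrate A and an
    emergent creole C; interactions follow speaker/hearer Naming-Game rules
    with a segregation parameter (Europe-Bozal contact probability), an
    African mutual-intelligibility probability, and a creolization
    probability by which bilingual A+E hearers adopt C. The package provides
    a fast simulation engine, an exact Markov-chain oracle for tiny
    populations, phase-diagram sweeps over the demographic plane with
    extraction of the creole/no-creole transition stripe, and a classifier
    that projects census-style tables of Whites, Free Colored and Slaves
    onto the plane and predicts creole emergence, together with a synthetic
    census-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2,
    rlang,
    scales,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
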