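Package: brauerphylo
Title: Brauer and Partition Diagram Algebra for Phylogenetic Trees and Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rooted phylogenetic trees and forests as elements of Brauer and
    partition diagram monoids.  Implements the correspondence between leaf-
    labelled trees and perfect matchings, its extension to non-binary trees
    and forests via set partitions, diagram composition with loop removal,
    the flip involution, restricted Green's relations and eggbox censuses on
    tree space, the sandwich product relative to a fixed tree together with
    regularity tests, the regular-subsemigroup counting formula and
    idempotent enumeration, and exhaustive/random generation of trees,
    forests, diagrams and restricted set partitions.  Trees are read and
    written in Newick; diagrams and partitions use a compact block-list text
    and JSON dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
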