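Package: digestmap
Title: Genetic-Algorithm Reconstruction of Restriction Maps from Double
    Digest Fragment Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves the double digest problem (DDP) of restriction-site
    physical mapping: given the fragment-length multisets produced by
    digesting a DNA molecule with enzyme A alone, enzyme B alone, and both
    enzymes together, reconstruct orderings of the A- and B-fragments whose
    implied double digest agrees with the observed one. The solver is a
    permutation-encoded genetic algorithm with roulette-wheel selection,
    two order-based crossover operators, three permutation mutation
    operators, elitism, and a cyclic linearly adaptive mutation
    probability. The package also provides exact digest-map arithmetic
    (prefix-sum/step-difference vectors, double digest sequences, multiset
    mismatch fitness), preprocessing for coincident cut sites, a
    scaling-rounding-adjusting transform for numerically hard instances, a
    random instance generator with ground truth, a brute-force enumeration
    oracle for small instances, JSON/text instance I/O, nested pie-chart
    SVG rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
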