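Package: latticeanon
Title: Hierarchy-Based Microdata Anonymization via Generalization Lattice Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anonymizes tabular biomedical microdata by full-domain
    generalization over user-supplied value hierarchies combined with record
    suppression. The space of generalization schemes forms a lattice that is
    searched with an exhaustive oracle, greedy best-first bottom-up and
    top-down heuristics, or a two-subpopulation genetic algorithm, optimizing
    a granularity-based data-quality score under k-anonymity or a threshold on
    estimated population uniqueness (Pitman two-parameter Poisson-Dirichlet
    model fitted by method of moments). Supports global recoding (one scheme
    for all records) and local recoding (an iterative partition loop applying
    different schemes to different record subsets), a synthetic categorical
    data generator with balanced hierarchies, a quality-versus-budget
    benchmark harness, and a YAML-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
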