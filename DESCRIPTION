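Package: scatterkit
Title: Symbolic Small-Angle Scattering Equations for Composite Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds acyclic composite structures (block copolymers,
    micelles, stars, dendrimers, decorated solids and hierarchical
    assemblies) by linking sub-units at reference points, and symbolically
    derives the orientationally averaged form factor, form factor
    amplitudes and phase factors of the composite, together with
    Guinier-expansion size measures (radius of gyration and sigma
    mean-square distances).  Expressions can be exported as LaTeX, C,
    Python or plain text, or evaluated on a q grid and written to curve
    files.  A seeded Monte Carlo Debye-sum oracle samples explicit
    bead-model conformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
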