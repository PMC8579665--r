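Package: fluxmodes
Title: Exact Enumeration of Elementary Flux Modes and Elementary Flux Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exact-arithmetic toolkit for enumerating elementary flux modes
    (EFMs) and elementary flux vectors (EFVs) of metabolic networks. Reads SBML
    models, performs loss-free stoichiometric compression, transforms among the
    general-polyhedron, polyhedral-cone and flux-cone formulations of the
    enumeration problem, enumerates extreme rays and vertices with built-in
    double-description and lexicographic reverse-search engines over exact
    rational arithmetic, interoperates with lrs and efmtool input/output file
    dialects, and post-processes raw enumerator output into decompressed,
    deduplicated mode sets with yield and support-similarity analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
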