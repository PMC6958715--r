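Package: pathcons
Title: Sign-Consistency Modeling of Signed Regulatory Networks from KEGG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, directed causal interaction graphs from KEGG KGML
    pathway files (distinguishing gene, protein and protein-complex nodes),
    extracts the upstream regulatory subgraph of a gene list, discretizes
    differential-expression tables into qualitative observations, and
    confronts observations with the graph under sign-consistency
    constraints. Inconsistencies are repaired with minimal correction sets,
    and signs of unmeasured biomolecules are predicted whenever all
    consistent total labelings agree. Includes subsampling experiments
    that quantify prediction precision against fold-changes and prediction
    stability against the full-observation run, plus a synthetic-data
    generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
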