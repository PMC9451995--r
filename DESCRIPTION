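Package: qtspdna
Title: Adleman-Lipton DNA-Computing Simulator for the Quota Traveling
    Salesman Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, desk-scale simulator of a DNA-computing
    algorithm for the Quota Traveling Salesman Problem (QTSP). Implements a
    Watson-Crick code-word encoding of routes, a virtual test tube with the
    eleven Adleman-Lipton biological operations (merge, annealing,
    denaturation, separation, discard, append-head, append-tail,
    length selection, cutting, sort, read), the five composed strand-filtering
    algorithms that solve the QTSP by massive parallel filtering, an exact
    enumeration oracle (permutation and subset dynamic-programming modes) that
    certifies every answer, operation-count accounting against the stated
    complexity bounds, instance generation and conversion from prize-collecting
    TSP instances, and plain-text instance formats with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
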