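Package: eukbench
Title: Designer Metatranscriptome Simulation and Assembly Recovery Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "designer" eukaryotic mock-community metatranscriptomes with
    controlled diversity and ortholog structure, simulates error-bearing
    paired-end reads from them, and evaluates how faithfully de novo assemblies
    recover the designed sequence content. Includes MinHash sketch similarity
    and ANI estimation, abundance-weighted community diversity metrics,
    OrthoFinder-style orthogroup ingestion and inference, greedy
    identity/coverage sequence clustering with a multi-assembler merge
    hierarchy, a sliding-window quality trimmer, a k-mer pseudo-mapper, and
    taxonomic/functional recovery classification with concordance statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
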