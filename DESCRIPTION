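Package: unitigphaser
Title: Strand-Seq Phasing of Diploid Assembly Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases diploid genome assembly graphs using single-cell
    template-strand (Strand-seq) sequencing signal. Unitigs are clustered
    by homologous-chromosome pair with a batched agglomerative clustering
    on absolute cosine similarity of strand-state-frequency vectors,
    misoriented unitigs are detected and corrected by flip-augmented
    two-group hierarchical clustering, per-cluster phase vectors are
    inferred from an uncentered principal-component plane, and
    haplotype-informative libraries are pooled into per-unitig haplotype
    marker counts and calls. Includes a synthetic Strand-seq simulator
    with full ground truth and a truth-based evaluation utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
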