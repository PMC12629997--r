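Package: inductr
Title: Prophage Induction Detection from Coverage, K-mer and Alignment Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects induced prophages from shotgun-sequencing evidence and
    compares induced to non-induced (putatively cryptic) prophages. Implements
    binned-coverage outlier statistics (modified z-score, Cohen's d, coverage
    fold change) with boundary refinement and interval merging; ANI/AF
    computation and greedy dereplication of viral genomes from alignment
    blocks; community-scale induction calling from read-mapping and unique
    k-mer reports; virome fractional abundance and prevalence profiling;
    gene-category enrichment and HGT/indel gap-event calling between
    high-similarity prophage pairs; and study-level induction summaries.
    A synthetic-data module generates lysogen genomes, negative-binomial
    coverage tracks, community reports and alignment fixtures with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
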