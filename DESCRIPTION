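Package: subspecscan
Title: Subspecies Divergence Scanning in Multi-Strain Sequence Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and characterising gene-level divergence
    between two parapatric subspecies sampled as panels of wild-derived
    inbred (haploid) strains. Screens strain SNP genotype tables for genes
    where two focal strains carry differing genotypes, classifies variable
    alignment columns into fixed inter-group differences versus private or
    shared polymorphisms with per-codon synonymous/nonsynonymous annotation,
    computes nucleotide diversity (pi) and Watterson's theta, builds
    neighbor-joining gene trees from F84 distances with column-bootstrap
    support, reconstructs ancestral states (Fitch parsimony and joint
    maximum likelihood under HKY) to census homoplasies under alternative
    guide trees, and quantifies inter-gene linkage disequilibrium (r^2)
    across concatenated variable sites. A synthetic-data generator produces
    two-group alignments, tree-evolved sequences and SNP genotype tables
    with recorded ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
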