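Package: akashi
Title: Translational Accuracy Analysis of Codon Usage at Conserved Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting selection on synonymous codon choice at
    evolutionarily conserved amino-acid sites in protein-coding genes.
    Builds codon alignments from protein alignments of orthologs,
    classifies sites as conserved or variable (pairwise, phylogeny-based
    with an outgroup, and optimality-tied variants), and measures
    synonymous-codon enrichment with gene-stratified Mantel-Haenszel
    odds ratios (the Akashi test), optionally stratified by protein
    domain membership, mRNA stem/loop state, expression class and
    position along the transcript. Includes codon-usage summary
    statistics (GC3, effective number of codons, fraction of optimal
    codons, tRNA-RSCU), optimal-codon identification from expression
    data, and a synthetic ortholog-trio generator with known effect
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
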