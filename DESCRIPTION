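Package: rpclustermap
Title: Mapping Ribosomal Protein Gene Clusters in Prokaryotic Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates canonical ribosomal-protein (r-protein) gene clusters in
    annotated archaeal and bacterial genomes, rescues cluster members hidden
    behind "hypothetical protein" labels by local protein alignment against a
    reference panel, classifies cluster contiguity, splits and insertions, and
    compares cluster organization across genomes. Reads NCBI assembly feature
    tables, GFF3 and GenBank flat files; ships a registry of cluster models
    covering the S10-spc, str-L30e, alpha-L18e, L7ae-S24e and L31e-L11
    families, and a synthetic-genome generator with planted truth for
    end-to-end validation, including the annotation pathologies seen in
    metagenome-assembled genomes (mislabels, pseudogenes, partial genes,
    contig fragmentation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    rtracklayer,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
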