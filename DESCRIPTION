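Package: panepi
Title: Pan-Epigenome Analysis of Multipartite Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps strand-specific DNA methylation calls (6mA, 4mC, 5mC) onto
    IUPAC degenerate motif occurrences and genomic feature classes across
    multi-replicon bacterial genomes. Computes per-motif methylation
    frequencies, classifies the pan-epigenome into core and shell motif sets
    across a strain panel, and provides the comparative statistics used in
    multi-strain methylome studies: normalized root-mean-square deviation of
    frequencies, principal-component variable contributions, Kruskal-Wallis
    with Dunn's post hoc test, complete-linkage clustering with cophenetic
    correlation between dendrograms, and donor-by-recipient log10 fold-change
    matrices of plasmid-transfer ratios. Includes a seeded synthetic-panel
    generator emitting FASTA, annotation GFF3 and methylation GFF3 with
    planted ground truth, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
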