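Package: nearhgt
Title: Detection of Horizontal Gene Transfer Between Closely Related
    Bacterial Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects horizontal gene transfer (HGT) between closely related
    bacterial genomes, where phylogenetic and compositional signals are weak.
    A synteny-index screen flags genes sitting in anomalous genomic
    neighbourhoods, and flagged candidates are validated with a
    constant-relative-mutability chi-square test that compares the observed
    inter-strain distance of a candidate gene with the distance expected from
    a witness gene and a pair of reference organisms, under the Jukes-Cantor
    model. Includes a sequence-evolution simulator (Yule species trees, HGT
    grafting, Jukes-Cantor evolution) for power and false-positive studies, a
    genomic-signature sliding-window composition scan, and readers for gene
    orders (TSV, GFF3, GenBank feature tables) and per-gene FASTA alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
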