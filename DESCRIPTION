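Package: baculannot
Title: Annotation and Comparative Analysis of Baculovirus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for annotating circular double-stranded DNA virus
    genomes in the style of published baculovirus genome reports: six-frame
    open reading frame discovery with origin wrap-around, early (TATA/CAKT)
    and late (DTAAG) promoter motif classification of upstream windows,
    detection of homologous regions as clustered arrays of imperfect
    palindromic repeats, gene-parity plots with collinear-run detection,
    conservation-tier classification against packaged core-gene lists, and
    a synthetic-genome simulator with planted ground truth for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
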