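Package: mirtrons
Title: Annotation and Characterization of Splicing-Derived microRNAs
    (Mirtrons) from Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and characterizing mirtrons, the
    intronic microRNA precursors whose hairpin ends are defined by the
    splicing machinery rather than by Drosha cleavage.  Collapsed small RNA
    reads are placed on a genome with an iterative 3'-trimming exact-match
    mapper, assigned to annotated introns, folded, and classified into the
    four splicing-mediated biogenesis subtypes (conventional, 5'-tailed,
    3'-tailed, two-tailed) under tiered read-evidence criteria that combine
    miRNA/star duplex counts with Argonaute immunoprecipitation support.
    Downstream analyses quantify terminal heterogeneity of the derived
    small RNAs, untemplated 3' uridylation and adenylation called against
    splice-site-anchored references, 5'-guanine decapitation ("xU" reads),
    sequence, length and folding-energy features of host introns, host-gene
    intron-count statistics, mirtron-host mRNA expression correlation with
    shuffled-label confidence envelopes, and Ago-IP enrichment.  A bundled
    synthetic-data generator plants ground-truth loci of every subtype so
    that each stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
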