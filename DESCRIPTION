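Package: ampevo
Title: Molecular Evolution of Amphibian Antimicrobial Peptide Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for families of antimicrobial peptide (AMP)
    precursor cDNAs from frog skin. Precursors are translated and segmented
    into signal peptide, acidic propiece and mature peptide at dibasic
    processing motifs (KR/ER/RR); physicochemical descriptors (molecular
    weight, theoretical pI, net charge, GRAVY, instability index) are
    computed per segment; per-family nucleotide diversity (pi with Nei's
    sampling variance), pooled transition/transversion ratios and
    Nei-Gojobori dN/dS selection summaries are produced per region;
    neighbor-joining trees with Felsenstein and transfer-bootstrap (TBE)
    supports test family monophyly; and Pearson correlations between
    propiece and mature-peptide lengths and net charges test the Net Charge
    Balance and Cut Point Sliding hypotheses. A seeded simulator generates
    precursor families with known segmentation, omega, transition bias and
    inter-segment couplings so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
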