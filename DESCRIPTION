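Package: CypMine
Type: Package
Title: Cytochrome P450 Genome Mining: Motif Triage, Family Assignment
    and Biosynthetic Gene Cluster Linkage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mining of cytochrome P450
    monooxygenases (CYPs) in bacterial proteomes. Candidate hit
    proteins are triaged on the conserved EXXR (K-helix) and CXG
    (heme-loop) motifs into complete P450s, pseudo-P450s and
    fragments; complete P450s are assigned to CYP families and
    subfamilies by percent identity to named reference P450s under
    the standard nomenclature thresholds (same family above 40
    percent, same subfamily above 55 percent, new family below 40
    percent); P450 genes are intersected with secondary-metabolite
    biosynthetic gene cluster (BGC) intervals and family-to-cluster-type
    linkage is tabulated; and per-genus cohort statistics (totals,
    modal counts, rounded averages, truncated percentages,
    presence/absence matrices) are computed. A synthetic-cohort
    generator plants proteomes, reference databases and BGC layouts
    with known truth so that every stage of the pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: Classification, Annotation, SequenceMatching, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
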