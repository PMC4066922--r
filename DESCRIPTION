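Package: polykaryon
Title: Detecting Polykaryotic Basidiomata from Cloned Amplicon Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether mushroom fruit bodies (basidiomata)
    carry more than two parental nuclear haplotypes, from plasmid-cloned
    single-locus amplicon sequences. Collapses per-basidioma clone sequences
    into supported haplotypes with singleton exclusion, classifies the
    transition/transversion/indel polymorphism spectrum of exon and intron
    regions, tests whether minor haplotypes are explainable as PCR or meiotic
    recombinants of the dominant pair by minimal template-switch counting,
    computes birthday-paradox probabilities that recurrent mutations arise by
    chance, runs the pairwise homoplasy index (PHI) recombination test, and
    summarises population structure via haploid gene diversity, Fst and
    haplotype networks. Includes a seeded simulator of cloned-amplicon data
    sets with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
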