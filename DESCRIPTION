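Package: codingIR
Title: Inverted Repeats Embedded in Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of perfect and imperfect inverted repeats
    (hairpin stems) embedded within protein-coding sequences, with an emphasis
    on mitochondrial genomes. Provides a maximal perfect inverted-repeat
    detector and a scored (alignment-based) detector for imperfect repeats;
    classification of in-frame repeats into the three codon-pairing phases;
    genetic-code constraint metrics (permitted amino acids and their entropy
    on the complementary arm, given a fixed amino-acid sequence); codon- and
    nucleotide-shuffling null models for repeat abundance and phase
    proportions; codon-usage statistics by repeat region (effective number of
    codons, amino-acid composition comparison with Fisher's exact test);
    cross-species midpoint sharing from codon-aware alignments; and a
    synthetic-data generator that embeds repeats of controlled phase, arm and
    loop length into AT-rich coding sequences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
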