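# codingIR

Detection and analysis of perfect inverted repeats embedded in
protein-coding sequences, built for the extreme case presented by
mitochondrial genomes of horsehair worms (Nematomorpha), whose
protein-coding genes carry perfect hairpin stems with arms up to 142 bp —
while both arms still encode conserved, functional protein.

The package is aimed at researchers in molecular evolution and organellar
genomics who need to (a) catalogue perfect and imperfect inverted repeats
per coding sequence, (b) resolve them by reading-frame *phase*, (c)
quantify the coding constraints each phase imposes, and (d) test repeat
abundance against shuffling null models.

## The core quantities

**Maximal perfect inverted repeats.** Two arms on the same strand with
`arm5 = reverse_complement(arm3)`, extendable neither outward nor inward
(loop shrinking) without breaking complementarity or overlapping the
arms. Each arm pair is reported once with 0-based half-open coordinates;
"repeat length" means arm length.

**Phase.** For an in-frame repeat, the codon position k ∈ {1,2,3} that
pairs with itself between the arms. With `cA` the codon position of the
first base of the 5′ arm and `cB` that of the last base of the 3′ arm,

    s = (cA + cB) mod 3;   s = 2 → phase 1,  s = 1 → phase 2,  s = 0 → phase 3.

Phase 1 pairs codon positions (1,1), (2,3), (3,2); phase 2 pairs (2,2),
(1,3), (3,1); phase 3 pairs (3,3), (1,2), (2,1) — so phase 3 ties both
functionally critical first and second codon positions and is the most
constrained.

**Permitted amino acids.** For a dipeptide on the focal arm, the number
of distinct amino acids the complementary arm's frame can encode over all
synonymous dicodon choices (stop outcomes excluded); the entropy variant
weights dicodons by within-family codon frequencies and reports the
Shannon entropy (bits) of the induced amino-acid distribution. Under the
invertebrate mitochondrial code, for a Met–Met dipeptide, phase 3 permits
1 amino acid, phases 1 and 2 permit 2 each.

**Null models.** Per-CDS codon shuffling (uniform permutation of the
codon array — preserving codon usage and the amino-acid multiset) or
nucleotide shuffling, 10 replicates by default, with observed/expected
repeat counts per minimal arm length.

**Effective number of codons (Nc).** Wright's estimator with the code's
actual degeneracy census (for NCBI table 5: 12 two-fold, 6 four-fold,
six-fold Leu, eight-fold Ser; 62 sense codons), used to compare synonymous
codon-usage uniformity between repeat-phase regions and non-repeat
regions.

## Worked example

```r
library(codingIR)

# a synthetic coding sequence with one embedded phase-2 repeat
cds <- generate_cds(60, seed = 42, ir_free_min_arm = 12)
rec <- embed_repeat(cds, phase = 2, arm_len = 18, loop_len = 9, seed = 43)
hits <- phase_repeats(cds_set(list(rec)), min_arm = 15)
hits[, c("arm5_start", "arm3_end", "arm_len", "loop_len", "phase", "midpoint")]
#>   arm5_start arm3_end arm_len loop_len phase midpoint
#> 1         45       90      18        9     2     67.5
```

The detector recovered the embedded stem exactly: arms of 18 bp at
0-based positions [45,63) and [72,90), a 9 bp loop, classified as phase 2
(second codon positions pair between the arms), midpoint at 67.5.

```r
# the per-phase characteristics table for a synthetic genome
gs <- generate_genome_set(n_genomes = 1, seed = 7)
round(ir_table1(gs$cds), 2)
#>                          phase1 phase2 phase3
#> mean_permitted_aa          3.43   2.97   1.48
#> mean_entropy_actual_bits   1.41   1.24   0.44
#> mean_entropy_equal_bits    1.54   1.39   0.44
#> n_repeats_gt15             7.00   7.00  12.00
#> cumulative_length_gt15   329.00 299.00 581.00
#> n_repeats_gt30             7.00   4.00   8.00
#> cumulative_length_gt30   329.00 226.00 486.00
```

Reading the table: a phase-1 repeat lets the complementary arm choose
among 3.4 amino acids on average for each fixed dipeptide, phase 2 among
3.0, phase 3 only 1.5 — phase 3 repeats impose much the strongest coding
constraint. The census rows count the repeats of each phase above the
arm-length cutoffs and their cumulative arm lengths.

For real data, load annotated genomes with `read_cds_genbank()` (GenBank
flat files) or `read_cds_table()` (FASTA plus a gene-coordinate TSV), then
run the same functions; `ir_nullrun()` adds the codon-shuffling null,
`enc_by_region()` the per-region Nc, `composition_compare()` the
amino-acid enrichment tests, and `shared_midpoints()` the cross-species
hairpin-position analysis from per-gene alignments.

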