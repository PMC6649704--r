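---
title: "Inverted repeats embedded in protein-coding sequences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverted repeats embedded in protein-coding sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codingIR)
```

## The problem

Inverted repeats — two DNA segments on the same strand where one is the
reverse complement of the other — fold into hairpins and are ordinarily
rare inside protein-coding sequences, because perfect complementarity
between two stretches of the same reading frame severely constrains the
protein both arms can encode. Mitochondrial genomes of horsehair worms
(Nematomorpha) are a striking exception: their protein-coding genes carry
dozens of long *perfect* inverted repeats, with both arms encoding
conserved protein regions. `codingIR` implements the analysis pipeline
such data call for:

* detection of maximal perfect inverted repeats per coding sequence, and a
  scored detector for imperfect repeats;
* classification of in-frame repeats into the three codon-pairing
  *phases*, and all phase-resolved summaries (censuses, proportion curves,
  per-codon region masks, cross-species midpoint sharing);
* the genetic-code *constraint calculus*: how many amino acids, and with
  what entropy, the complementary arm can encode when the focal arm's
  amino acids are fixed;
* codon- and nucleotide-shuffling null models for repeat abundance;
* codon-usage statistics by repeat region (Wright's effective number of
  codons, amino-acid composition comparison by Fisher's exact test);
* a synthetic-data generator that embeds repeats of controlled geometry
  into AT-rich coding sequences, providing exact truth sets.

## Detection model

A *maximal* perfect inverted repeat is one whose arms can be extended
neither outward (both arms growing away from the loop) nor inward
(shrinking the loop) without breaking complementarity or making the arms
overlap. All base pairs of one hairpin stem share the same index sum, so
maximal repeats are maximal runs of complementary base pairs along
anti-diagonals of the sequence-versus-reverse-complement match structure,
truncated at the arm-overlap boundary. This yields an exact enumeration,
reporting each arm pair once; nested and overlapping maximal repeats are
all kept (no greedy masking), since overlapping stems — competing
hairpins and attenuator-like arrangements — are themselves of interest.
The unit tests verify the detector against an independent brute-force
oracle (innermost-pair enumeration with outward extension) on a thousand
random sequences, and check the maximality predicate on every reported
repeat.

"Repeat length" always means arm length; a zero-loop repeat of arm
length L is a perfect palindrome of length 2L. Detection runs per coding
sequence, never across gene boundaries, and the loop length is by default
unbounded within a sequence (a per-CDS scan bounds the spacer
implicitly); `max_loop` is available for genome-scale scans.

The scored detector (`find_scored_irs`) treats imperfect repeats as local
alignments of the sequence against its own reverse complement, with the
classical hairpin-finding scoring scheme: match +3, mismatch −4, gap −12
per base, score threshold 15. We define the dynamic programme concretely:
cells are restricted so that each aligned pair has its 5′ partner
strictly before its 3′ partner (which also makes every stem unique in the
output), stems are extracted greedily in score order with their covered
positions masked, and `max_extent` bounds the stem span. The scoring
parameters are conventional; the extraction order and masking are this
package's own choices, so agreement with any particular external
implementation is not guaranteed beyond the scoring scheme itself. The
number of matching columns (`n_match`) is reported per stem to support
length-versus-identity summaries of imperfect repeats.

## Phases

For a repeat lying inside a coding sequence, the *phase* is the codon
position (1, 2 or 3) that pairs with itself between the arms. The full
pairing pattern follows from the geometry: phase 1 pairs codon positions
(1,1), (2,3), (3,2); phase 2 pairs (2,2), (1,3), (3,1); phase 3 pairs
(3,3), (1,2), (2,1). With `cA` the codon position of the first base of
the 5′ arm and `cB` that of the last base of the 3′ arm,
`s = (cA + cB) mod 3` determines the phase (s = 2 → phase 1, s = 1 →
phase 2, s = 0 → phase 3); phases cycle 1 → 2 → 3 under single-base
downstream shifts. Because outward and inward extensions move both
defining bases symmetrically, a repeat's phase is invariant under
maximal extension — which is why the classifier can be applied to
detector output directly. Repeats only partially inside a CDS are
excluded from phase analysis; their pairing geometry is undefined across
gene boundaries.

Censuses (`phase_census`) use strict cutoffs (`arm_len > 15`) by default
and sum one arm length per repeat; both choices are configurable.
Proportion curves re-use a single detection run filtered at each minimal
length, which is equivalent to re-running detection because maximality
does not depend on the reporting threshold.

### Midpoint sharing across species

Homologous hairpins in different species are identified by mapping each
repeat's midpoint — the centre coordinate between the arms, half-integral
when the span is even — into the column space of a per-gene codon-aware
alignment supplied by the user. A midpoint's column is the mean of the
columns of its two flanking bases (or the single central base), making
the mapping deterministic and insensitive to gaps inside the loop.
Repeats are grouped by single linkage at a tolerance of 3 columns (one
codon) by default; the tolerance is a free parameter because "same
location" has no canonical column-level definition, and it is recorded in
the output.

## The constraint calculus

The unit of analysis is the dipeptide: two adjacent amino acids on the
focal arm. For each synonymous dicodon choice, the reverse complement of
the 6-mer is read in the complementary arm's frame. In phase 2 the frame
offset is 0 and both complementary codons are complete; in phases 3 and 1
the offsets are 1 and 2, and the single junction-spanning complementary
codon is the informative one. `permitted_aa_count` enumerates all
synonymous dicodons and counts the distinct amino acids reachable on the
complementary arm; `permitted_aa_entropy` weights each dicodon by the
product of within-family codon probabilities (observed usage renormalised
per synonymous family, or uniform) and returns the Shannon entropy (bits)
of the induced amino-acid distribution. Dataset-level summaries weight
dipeptides by their observed frequencies in the pooled coding sequences.

Two conventions required a decision:

* **Phase 2.** The complement of each phase-2 codon depends on that codon
  alone, so the per-dipeptide accounting reduces to a single-codon
  calculation. The default (`phase2_variant = "second"`) varies the
  second codon's synonymous choice, keeping the "one complementary codon
  per dipeptide" accounting uniform across phases; the `"union"` variant
  (amino acids reachable through either complementary codon) is
  implemented and can be emitted side by side (`ir_table1(...,
  phase2_variant = "both")`), since the aggregation is the one genuinely
  underdetermined step of the procedure.
* **Stops.** A complementary codon that is a stop cannot be "permitted"
  inside a coding region: stops are excluded from the count (tallied in
  the `n_stop` attribute) and the entropy distribution is renormalised
  without them.

Dipeptide weights are pooled over all records in the input set — the
constraint table describes a single coding-sequence population — and the
same observed weights are used in both entropy modes ("equal" refers to
codon frequencies within families, not to dipeptide weighting). Entropies
are in bits (log base 2) throughout.

## Null models

Codon shuffling is a uniform Fisher–Yates permutation of the codon array
(exactly the k = 1 shuffle of the sequence after recoding each codon as
one symbol), preserving codon frequencies and the encoded amino-acid
multiset; nucleotide shuffling permutes bases and preserves only base
composition. Shuffling is always per CDS. The default ensemble size is 10
replicates; per-replicate, per-record seeds derive deterministically from
the top-level seed and are recorded in the output. Over-representation
ratios (observed / mean null count at each minimal arm length) are
reported as missing where the null mean is zero — at long arm lengths the
null is empty and the meaningful statement is the observed count against
a null of zero, not a ratio.

## Codon-usage statistics

Wright's effective number of codons is computed from the code's actual
degeneracy census (for the invertebrate mitochondrial code: 12 two-fold
families, 6 four-fold, six-fold leucine and eight-fold serine; 62 sense
codons). Family homozygosity F̂ = (nΣp̂² − 1)/(n − 1) is averaged within
degeneracy classes; families with fewer than two observations (or a
non-positive estimate) are imputed by their class mean, and a wholly
missing class by the mean of its nearest estimable neighbours. Nc is
reported as computed even when small-sample noise pushes it above the
sense-codon count — capping would hide exactly the uniform-usage signal
the statistic is meant to show in repeat regions. Closed forms anchor the
tests: one codon per amino acid gives Nc = 20; asymptotically uniform
usage over the mitochondrial code gives Nc → 62.

Composition comparison builds, per amino acid, the 2×2 table (this amino
acid vs all others, region vs background) and applies the two-sided
Fisher exact test (p as the sum of probabilities of tables no more likely
than the observed one), with Bonferroni correction over the 20 amino
acids: significance at p < 0.05/20 = 0.0025. Repeat regions are defined
by the per-codon mask: a codon belongs to a phase region if any of its
bases lies in either arm of a repeat of that phase, with overlaps
resolved by longest-repeat precedence (ties to the lower phase number);
both arms contribute. Conservation profiles, when supplied as a numeric
per-site column, are smoothed with a central moving average of window 5,
the window shrinking symmetrically at the edges.

## Synthetic data: what it emulates and what it does not

The generator draws i.i.d. codons from an AT-rich usage (independent
per-base probabilities at a target A+T of 0.72 by default, inside the
0.65–0.78 range of the mitochondrial genomes this emulates, stop codons
removed), rejection-resamples each gene until it is free of perfect
repeats at the background threshold (default arm ≥ 15), and then writes
perfect repeats of requested phase, arm and loop into the genes. The
default genome set mirrors the study conditions: four genomes of the 13
standard mitochondrial protein-coding genes (realistic lengths, ~11 kb
coding per genome), about 27 embedded repeats per genome with phases in
proportion 47:22:41, arm lengths 15 + Exp(mean 28) capped at 142 bp
(mean ≈ 43), and loops |N(37, 18)| bp. These values are the observed
repeat load of the nematomorph genomes and are fixed once as the
generator's defaults.

Embedding preserves perfect complementarity unconditionally: the 3′ arm
is always the reverse complement of the 5′ arm. Stops arising on codons
overlapping the 3′ arm are repaired by re-drawing the paired focal-arm
codon synonymously; junction geometries that admit no synonymous fix
(e.g. a TA-prefix tyrosine codon meeting a two-fold family ending T/C)
fall back to mutating a free non-arm base of the offending codon, then to
replacing the paired focal-arm codon outright — the 5′ arm keeps host
codons only where possible. The requested phase is obtained by shifting
the arm start by 0–2 bases, keeping arm and loop lengths exact. Chance
complementary flanks can extend an embedded repeat beyond the requested
arm length, so truth-set assertions are "arm ≥ requested, phase exact".

What the generator does **not** emulate: real codon usage (draws are
i.i.d., so there is no amino-acid-level selection, no gene-specific
composition, no dinucleotide structure), repeat evolution (no gain/loss
or conversion dynamics), and no selective signature inside repeat regions
beyond the embedding itself. Consequently, passing round-trip tests shows
the machinery is correct — detection, phase classification, censuses and
null ratios recover exactly what was put in — but region-level contrasts
(e.g. Nc differences between repeat and non-repeat regions) are
attenuated on synthetic material relative to real genomes, where codon
usage in repeat regions is genuinely reshaped by the pairing constraint.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open internally; GenBank-style input/output
  converts from 1-based inclusive. Repeat tables carry 0-based half-open
  arm coordinates.
* Half-integral midpoints are kept as .5 values; no rounding.
* Repeat tables are sorted by 5′ arm start, then decreasing arm length —
  deterministic output everywhere.
* Empty inputs: detection returns an empty table; summaries report count
  0 with missing means; pooled usage of an empty set is an error.
* Ambiguity codes are rejected at the record level with a logged warning
  (repeat identity is defined on exact complementarity); terminal
  incomplete codons (mitochondrial truncated T/TA stops) are trimmed, not
  padded; records with internal stops are excluded with a warning naming
  the gene.
* A zero-frequency synonymous family under "actual" codon frequencies
  falls back to the uniform within-family distribution.
* All randomness flows through explicit integer seeds (base R RNG,
  Fisher–Yates via `sample`); identical seeds give identical ensembles.

## Problem sizes used in validation

The shipped validation runs at deliberately modest scale, chosen to
exercise every code path with exact expectations: the detector-vs-oracle
comparison uses 1000 random sequences of 50–500 bp across 20–80% GC; the
embedding round trip covers 100 seeded specs spanning all phases, arm
lengths 15–142 and loops 0–100; null ensembles use the study's 10
replicates on the default four-genome set (~44 kb coding). The
acceptance script regenerates the default synthetic genome set from a
single seed and recomputes the full census, constraint table, per-region
Nc and null-model ratios from scratch.

## Known limitations

* The scored detector's stem extraction is greedy and non-overlapping; in
  strongly self-complementary (very AT-rich) stretches a long-range
  chance stem can outscore and mask a local hairpin unless `max_extent`
  bounds the span.
* The constraint calculus is strictly dipeptide-based; longer-range
  dependencies between neighbouring junction codons are not modelled.
* Nc is undefined (reported missing) when no synonymous family of any
  class has two or more observations.
* The GenBank reader covers the location grammar needed for organellar
  CDS features (`complement`, `join`, partial markers); it is not a
  general-purpose GenBank parser.
* Analyses of the deposited nematomorph genomes require the user to fetch
  the four accessions (MG257764–MG257767); the package does not download
  or redistribute them.
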