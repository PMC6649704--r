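# The constraint calculus: how many amino acids, and with what entropy, the
# complementary arm of an in-frame inverted repeat can encode while the
# focal arm's amino acids stay fixed. The unit of enumeration is the
# dicodon: two adjacent codons on the focal arm, whose reverse complement is
# a 6-mer read by the complementary arm's frame.

#' Complementary-strand codons of a dicodon, by phase
#'
#' Let R be the reverse complement of the 6-mer X.Y. The complementary
#' arm's reading frame depends on the repeat phase: phase 2 reads R in
#' frame offset 0 (two complete codons, the reverse complements of Y and X,
#' in that order); phase 3 reads frame offset 1, whose single
#' junction-spanning codon is R[2..4]; phase 1 reads frame offset 2, with
#' junction codon R[3..5].
#'
#' @param x,y Sense codons (3-character strings).
#' @param phase 1, 2 or 3.
#' @param code A \code{\link{genetic_code}} (used to reject stop inputs).
#' @return Character vector of codons: length 2 for phase 2, length 1 for
#'   phases 1 and 3.
#' @export
complementary_codons <- function(x, y, phase, code = genetic_code(5L)) {
  stopifnot(nchar(x) == 3L, nchar(y) == 3L, phase %in% 1:3)
  if (code$codon_to_aa[[x]] == "*" || code$codon_to_aa[[y]] == "*") {
    stop("stop codon in dicodon input")
  }
  R <- reverse_complement(paste0(x, y))
  switch(phase,
         `1` = substr(R, 3L, 5L),
         `2` = c(substr(R, 1L, 3L), substr(R, 4L, 6L)),
         `3` = substr(R, 2L, 4L))
}

# Enumerate, for a dipeptide and phase, the complementary codon reached by
# every synonymous dicodon choice, with its probability under within-family
# codon frequencies. Phase 2 uses one of two conventions (see
# permitted_aa_count). Returns data.frame(codon, prob).
complement_distribution <- function(aa1, aa2, phase, code, freqs1, freqs2,
                                    phase2_variant = "second") {
  c1 <- code$families[[aa1]]
  c2 <- code$families[[aa2]]
  if (is.null(c1)) stop("amino acid not encodable in this code: ", aa1)
  if (is.null(c2)) stop("amino acid not encodable in this code: ", aa2)
  p1 <- family_probs(c1, freqs1)
  p2 <- family_probs(c2, freqs2)
  if (phase == 2L) {
    rc2 <- vapply(c2, function(cod) reverse_complement(cod), character(1))
    if (phase2_variant == "second") {
      return(data.frame(codon = rc2, prob = p2, stringsAsFactors = FALSE))
    }
    # union variant: both complementary codons contribute, equal weight
    rc1 <- vapply(c1, function(cod) reverse_complement(cod), character(1))
    return(data.frame(codon = c(rc2, rc1), prob = c(p2, p1) / 2,
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(i = seq_along(c1), j = seq_along(c2),
                      KEEP.OUT.ATTRS = FALSE)
  codons <- vapply(seq_len(nrow(grid)), function(r) {
    complementary_codons(c1[grid$i[r]], c2[grid$j[r]], phase, code)
  }, character(1))
  data.frame(codon = codons, prob = p1[grid$i] * p2[grid$j],
             stringsAsFactors = FALSE)
}

# Within-family codon probabilities from a codon_usage (renormalised per
# family); "equal" or an all-zero family falls back to uniform.
family_probs <- function(codons, freqs) {
  if (identical(freqs, "equal")) {
    return(rep(1 / length(codons), length(codons)))
  }
  p <- freqs$counts[codons]
  p[is.na(p)] <- 0
  tot <- sum(p)
  if (tot == 0) return(rep(1 / length(codons), length(codons)))
  as.numeric(p / tot)
}

#' Number of permitted amino acids on the complementary arm
#'
#' For a fixed dipeptide on one arm of an in-frame inverted repeat,
#' enumerates all synonymous dicodon choices and counts the distinct amino
#' acids that the complementary arm's junction-spanning codon (phases 1
#' and 3) can encode. For phase 2 both complementary codons are complete;
#' by default the count varies the second codon's synonymous choice (the
#' complement of each codon depends on that codon alone, so phase 2 reduces
#' to a single-codon calculation); \code{phase2_variant = "union"} instead
#' counts the amino acids reachable through either complementary codon.
#' Complementary codons that are stops cannot be permitted in a coding
#' region: they are excluded from the count and tallied in the
#' \code{"n_stop"} attribute.
#'
#' @param aa1,aa2 Single-letter amino acids (first and second of the
#'   dipeptide, in translation order).
#' @param phase 1, 2 or 3.
#' @param code A \code{\link{genetic_code}}.
#' @param phase2_variant \code{"second"} (default) or \code{"union"}.
#' @return Integer count of distinct permitted amino acids, with attribute
#'   \code{n_stop} (number of distinct complementary codons that were
#'   stops).
#' @export
permitted_aa_count <- function(aa1, aa2, phase, code = genetic_code(5L),
                               phase2_variant = c("second", "union")) {
  phase2_variant <- match.arg(phase2_variant)
  dist <- complement_distribution(aa1, aa2, phase, code, "equal", "equal",
                                  phase2_variant)
  aa <- unname(code$codon_to_aa[dist$codon])
  n_stop <- length(unique(dist$codon[aa == "*"]))
  structure(length(unique(aa[aa != "*"])), n_stop = n_stop)
}

#' Entropy of the permitted amino-acid distribution
#'
#' Same enumeration as \code{\link{permitted_aa_count}}, but each synonymous
#' dicodon is weighted by the product of within-family codon probabilities
#' (actual usage renormalised per synonymous family, or uniform for
#' \code{"equal"}), inducing a probability distribution over the
#' complementary amino acids; returns its Shannon entropy in bits. Stop
#' outcomes are excluded and the distribution renormalised.
#'
#' @inheritParams permitted_aa_count
#' @param codon_freqs A \code{\link{codon_usage}} or the string
#'   \code{"equal"}.
#' @return Entropy in bits.
#' @export
permitted_aa_entropy <- function(aa1, aa2, phase, code = genetic_code(5L),
                                 codon_freqs = "equal",
                                 phase2_variant = c("second", "union")) {
  phase2_variant <- match.arg(phase2_variant)
  dist <- complement_distribution(aa1, aa2, phase, code,
                                  codon_freqs, codon_freqs, phase2_variant)
  aa <- unname(code$codon_to_aa[dist$codon])
  keep <- aa != "*"
  if (!any(keep)) return(0)
  p <- tapply(dist$prob[keep], aa[keep], sum)
  p <- p / sum(p)
  shannon_bits(as.numeric(p))
}

#' Dipeptide-weighted mean constraint metrics for one phase
#'
#' Frequency-weighted mean of the permitted-amino-acid count and of both
#' entropy variants (actual and equal codon frequencies) over all
#' dipeptides with non-zero frequency.
#'
#' @param dipeptides A \code{\link{dipeptide_frequencies}} table.
#' @param phase 1, 2 or 3.
#' @param code A \code{\link{genetic_code}}.
#' @param codon_freqs A \code{\link{codon_usage}} for the "actual" entropy
#'   (e.g. pooled usage of the input CDS set).
#' @param phase2_variant See \code{\link{permitted_aa_count}}.
#' @return One-row data frame: \code{phase}, \code{mean_permitted_aa},
#'   \code{mean_entropy_actual}, \code{mean_entropy_equal}.
#' @export
mean_constraints <- function(dipeptides, phase, code = genetic_code(5L),
                             codon_freqs = NULL,
                             phase2_variant = c("second", "union")) {
  phase2_variant <- match.arg(phase2_variant)
  w <- dipeptides[dipeptides > 0]
  if (abs(sum(w) - 1) > 1e-6) stop("dipeptide table must be normalised")
  pairs <- names(w)
  counts <- numeric(length(w))
  h_act <- numeric(length(w))
  h_eq <- numeric(length(w))
  for (i in seq_along(w)) {
    a1 <- substr(pairs[i], 1L, 1L)
    a2 <- substr(pairs[i], 2L, 2L)
    counts[i] <- permitted_aa_count(a1, a2, phase, code, phase2_variant)
    h_eq[i] <- permitted_aa_entropy(a1, a2, phase, code, "equal",
                                    phase2_variant)
    h_act[i] <- if (is.null(codon_freqs)) NA_real_ else
      permitted_aa_entropy(a1, a2, phase, code, codon_freqs, phase2_variant)
  }
  data.frame(phase = phase,
             mean_permitted_aa = sum(w * counts),
             mean_entropy_actual = sum(w * h_act),
             mean_entropy_equal = sum(w * h_eq))
}

#' Full constraint table over the three phases
#'
#' Assembles the per-phase mean permitted amino acids and mean entropies
#' (actual and equal codon frequencies) from a CDS set: dipeptide weights
#' and codon usage are pooled over all records.
#'
#' @param x A \code{\link{cds_set}}.
#' @param code A \code{\link{genetic_code}}.
#' @param phase2_variant See \code{\link{permitted_aa_count}}.
#' @return Data frame with one row per phase.
#' @export
constraint_table <- function(x, code = genetic_code(5L),
                             phase2_variant = c("second", "union")) {
  phase2_variant <- match.arg(phase2_variant)
  dip <- dipeptide_frequencies(x, code)
  usage <- codon_usage(x, code)
  do.call(rbind, lapply(1:3, function(p) {
    mean_constraints(dip, p, code, usage, phase2_variant)
  }))
}
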