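# Shuffle-based null models for repeat abundance and phase proportions.
#
# Codon shuffling (a uniform Fisher-Yates permutation of the codon array)
# preserves codon frequencies and the encoded amino-acid multiset while
# destroying positional structure; nucleotide shuffling preserves only base
# composition. Shuffling is always per CDS, never across genes, matching
# per-CDS repeat detection.

#' Shuffle the codons of a CDS
#'
#' Uniformly random permutation of the codon sequence (the k = 1 shuffle of
#' the codon alphabet after recoding each codon as a single symbol). The
#' codon multiset is preserved exactly; deterministic under a fixed seed.
#'
#' @param x A \code{\link{cds_record}} or in-frame DNA string.
#' @param seed Integer seed (NULL uses the ambient RNG stream).
#' @return Same type as the input, with shuffled codons.
#' @export
shuffle_codons <- function(x, seed = NULL) {
  seq <- if (inherits(x, "cds_record")) x$seq else x
  codons <- split_codons(seq)
  shuffled <- with_seed(seed, paste(sample(codons), collapse = ""))
  if (inherits(x, "cds_record")) { x$seq <- shuffled; x } else shuffled
}

#' Shuffle the nucleotides of a sequence
#'
#' Uniform permutation of the bases (k = 1 nucleotide shuffle); base
#' composition is preserved, codon frequencies in general are not.
#'
#' @inheritParams shuffle_codons
#' @export
shuffle_nucleotides <- function(x, seed = NULL) {
  seq <- if (inherits(x, "cds_record")) x$seq else x
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  shuffled <- with_seed(seed, paste(sample(chars), collapse = ""))
  if (inherits(x, "cds_record")) { x$seq <- shuffled; x } else shuffled
}

#' Expected repeat counts under a shuffling null
#'
#' Builds \code{n_replicates} shuffled copies of every CDS, re-runs perfect
#' repeat detection with the same parameters as the observed scan, and
#' tabulates per-replicate repeat counts at each minimal arm length,
#' together with observed/expected over-representation ratios.
#'
#' @param x A \code{\link{cds_set}}.
#' @param mode \code{"codon"} or \code{"nucleotide"}.
#' @param n_replicates Number of shuffled replicates (default 10).
#' @param min_lengths Minimal arm lengths at which counts are tabulated.
#' @param seed Top-level seed; per-replicate, per-record seeds derive from
#'   it deterministically.
#' @param max_loop Passed to the detector.
#' @return An object of class \code{null_ensemble}: list with \code{mode},
#'   \code{seeds}, \code{min_lengths}, \code{null_counts} (replicates x
#'   lengths matrix), \code{observed}, \code{null_mean}, \code{null_sd} and
#'   \code{ratio} (observed / null mean; NA where the null mean is 0).
#' @export
expected_counts <- function(x, mode = c("codon", "nucleotide"),
                            n_replicates = 10L,
                            min_lengths = seq(10L, 30L, 2L), seed = 1L,
                            max_loop = Inf) {
  mode <- match.arg(mode)
  min_arm <- min(min_lengths)
  shuffler <- if (mode == "codon") shuffle_codons else shuffle_nucleotides
  count_at <- function(reps) {
    vapply(min_lengths, function(L) sum(reps$arm_len >= L), integer(1))
  }
  observed <- count_at(find_perfect_irs_set(x, min_arm = min_arm,
                                            max_loop = max_loop))
  seeds <- seed + seq_len(n_replicates)
  null_counts <- t(vapply(seq_len(n_replicates), function(r) {
    shuffled <- cds_set(lapply(seq_along(x), function(i) {
      shuffler(x[[i]], seed = seeds[r] * 10000L + i)
    }))
    count_at(find_perfect_irs_set(shuffled, min_arm = min_arm,
                                  max_loop = max_loop))
  }, integer(length(min_lengths))))
  null_mean <- colMeans(null_counts)
  ratio <- ifelse(null_mean > 0, observed / null_mean, NA_real_)
  structure(list(mode = mode, seeds = seeds, min_lengths = min_lengths,
                 null_counts = null_counts, observed = observed,
                 null_mean = null_mean,
                 null_sd = apply(null_counts, 2, stats::sd),
                 ratio = ratio),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s shuffle, %d replicates\n",
              x$mode, nrow(x$null_counts)))
  print(data.frame(min_length = x$min_lengths, observed = x$observed,
                   null_mean = x$null_mean, ratio = x$ratio))
  invisible(x)
}

#' Phase-proportion curve under a shuffling null
#'
#' Shuffles every CDS once (per replicate semantics of the phase analysis)
#' and recomputes the phase-proportion curve on the shuffled material.
#'
#' @inheritParams expected_counts
#' @param thresholds Minimal arm lengths for the curve.
#' @return A \code{phase_curve} (see \code{\link{phase_proportion_curve}}).
#' @export
null_phase_proportions <- function(x, mode = c("codon", "nucleotide"),
                                   thresholds = 5:50, seed = 1L) {
  mode <- match.arg(mode)
  shuffler <- if (mode == "codon") shuffle_codons else shuffle_nucleotides
  shuffled <- cds_set(lapply(seq_along(x), function(i) {
    shuffler(x[[i]], seed = seed * 10000L + i)
  }))
  phased <- phase_repeats(shuffled, min_arm = max(2L, min(thresholds)))
  phase_proportion_curve(phased, thresholds)
}
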