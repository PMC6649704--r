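#' Classify the codon-pairing phase of an in-frame inverted repeat
#'
#' The phase of a repeat embedded in a coding sequence is the codon position
#' k (1, 2 or 3) that pairs with itself between the two arms. The full
#' pairing pattern follows: phase 1 pairs codon positions (1,1), (2,3) and
#' (3,2); phase 2 pairs (2,2), (1,3), (3,1); phase 3 pairs (3,3), (1,2),
#' (2,1). With \code{cA} the codon position of the first base of the 5' arm
#' and \code{cB} the codon position of the last base of the 3' arm (the two
#' outermost paired bases), \code{s = (cA + cB) mod 3} determines the phase:
#' s = 2 is phase 1, s = 1 phase 2, s = 0 phase 3 (the unique k with
#' 2k = s mod 3). Phases cycle 2 -> 3 -> 1 when the repeat shifts one base
#' downstream.
#'
#' @param arm5_start 0-based start of the 5' arm within the CDS (frame
#'   offset 0, so codon position of base i is \code{(i mod 3) + 1}).
#' @param arm3_end 0-based exclusive end of the 3' arm.
#' @param cds_length Length of the CDS in bases; both arms must lie inside.
#' @return Integer vector of phases in \code{1:3} (vectorised).
#' @export
classify_phase <- function(arm5_start, arm3_end, cds_length = Inf) {
  if (any(arm5_start < 0L) || any(arm3_end > cds_length)) {
    stop("repeat arm lies outside the CDS; phase undefined")
  }
  cA <- (arm5_start %% 3L) + 1L
  cB <- ((arm3_end - 1L) %% 3L) + 1L
  s <- (cA + cB) %% 3L
  ifelse(s == 2L, 1L, ifelse(s == 1L, 2L, 3L))
}

#' Detect and phase-classify repeats across a CDS set
#'
#' Convenience wrapper: runs the perfect detector per record and attaches
#' the phase of each repeat. Repeats always lie within their CDS here
#' because detection is per record.
#'
#' @param x A \code{\link{cds_set}}.
#' @inheritParams find_perfect_irs
#' @return Repeat data frame with a \code{phase} column.
#' @export
phase_repeats <- function(x, min_arm = 2L, max_loop = Inf) {
  reps <- find_perfect_irs_set(x, min_arm = min_arm, max_loop = max_loop)
  if (nrow(reps) == 0L) {
    reps$phase <- integer(0)
    return(reps)
  }
  reps$phase <- classify_phase(reps$arm5_start, reps$arm3_end)
  reps
}

#' Per-phase census of repeat counts and cumulative arm lengths
#'
#' For each minimal-arm-length cutoff, counts the repeats of each phase and
#' sums their arm lengths (one arm per repeat). Cutoffs are strict
#' (\code{arm_len > cutoff}) by default, matching the ">15 bp" convention
#' of per-phase repeat tables; set \code{strict = FALSE} for inclusive.
#'
#' @param phased Repeat data frame with a \code{phase} column.
#' @param cutoffs Arm-length cutoffs (bp).
#' @param strict Strict (\code{>}) or inclusive (\code{>=}) comparison.
#' @return Data frame: \code{cutoff}, \code{phase}, \code{n},
#'   \code{cumulative_length}.
#' @export
phase_census <- function(phased, cutoffs = c(15L, 30L), strict = TRUE) {
  out <- expand.grid(cutoff = cutoffs, phase = 1:3, KEEP.OUT.ATTRS = FALSE)
  out$n <- 0L
  out$cumulative_length <- 0L
  for (r in seq_len(nrow(out))) {
    keep <- if (strict) phased$arm_len > out$cutoff[r]
            else phased$arm_len >= out$cutoff[r]
    keep <- keep & phased$phase == out$phase[r]
    out$n[r] <- sum(keep)
    out$cumulative_length[r] <- sum(phased$arm_len[keep])
  }
  out[order(out$cutoff, out$phase), , drop = FALSE]
}

#' Phase proportions as a function of minimal repeat length
#'
#' The relative amounts of phase 1/2/3 repeats at each minimal arm length.
#' Because maximality does not depend on the detection threshold, filtering
#' one detection run at \code{min(thresholds)} is equivalent to re-running
#' detection at each threshold.
#'
#' @param phased Repeat data frame with \code{phase}.
#' @param thresholds Minimal arm lengths (inclusive).
#' @return An object of class \code{phase_curve}: data frame with
#'   \code{threshold}, \code{n_total}, \code{n1}, \code{n2}, \code{n3},
#'   \code{p1}, \code{p2}, \code{p3} (proportions sum to 1 where
#'   \code{n_total > 0}, NA otherwise).
#' @export
phase_proportion_curve <- function(phased, thresholds = 5:50) {
  rows <- lapply(thresholds, function(t) {
    keep <- phased$arm_len >= t
    n <- sum(keep)
    np <- vapply(1:3, function(p) sum(keep & phased$phase == p), integer(1))
    data.frame(threshold = t, n_total = n,
               n1 = np[1], n2 = np[2], n3 = np[3],
               p1 = if (n > 0) np[1] / n else NA_real_,
               p2 = if (n > 0) np[2] / n else NA_real_,
               p3 = if (n > 0) np[3] / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_curve", "data.frame")
  out
}

#' Assign each codon of a CDS to a phase region
#'
#' A codon belongs to the region of a phase if at least one of its bases
#' lies in either arm of a repeat of that phase. Overlaps between phases are
#' resolved by longest-repeat precedence (ties: lower phase number); codons
#' covered by no repeat are the non-repeat region (0).
#'
#' @param cds A \code{\link{cds_record}}.
#' @param phased Phase-classified repeats of this CDS (0-based coordinates
#'   within the CDS).
#' @return Integer vector, one entry per codon: 0 (non-repeat) or 1/2/3.
#' @export
phase_region_mask <- function(cds, phased) {
  n_codons <- nchar(cds$seq) %/% 3L
  mask <- integer(n_codons)
  if (nrow(phased) == 0L) return(mask)
  ord <- order(-phased$arm_len, phased$phase)
  for (r in ord) {
    covered <- c(codons_touched(phased$arm5_start[r], phased$arm5_end[r]),
                 codons_touched(phased$arm3_start[r], phased$arm3_end[r]))
    covered <- covered[covered >= 1L & covered <= n_codons]
    unset <- covered[mask[covered] == 0L]
    mask[unset] <- phased$phase[r]
  }
  mask
}

# 1-based codon indices touched by a 0-based half-open base interval.
codons_touched <- function(start0, end0) {
  if (end0 <= start0) return(integer(0))
  (start0 %/% 3L + 1L):((end0 - 1L) %/% 3L + 1L)
}
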