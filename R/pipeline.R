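# End-to-end orchestration: scan, constraint table, null run. These
# functions compose the module surfaces and are the programmatic interface
# for whole-analysis reproduction; each returns plain data structures ready
# for TSV/JSON serialisation.

#' Scan a CDS set for inverted repeats and summarise
#'
#' Runs perfect-repeat detection per gene, classifies phases, and computes
#' the census summary (count, mean/max arm length, mean loop length, mean
#' repeat AT content).
#'
#' @param x A \code{\link{cds_set}}.
#' @param min_arm Minimal arm length (bp) for the scan.
#' @param max_loop Maximal loop length.
#' @return List: \code{repeats} (phase-classified repeat table),
#'   \code{summary} (see \code{\link{repeat_summary}}).
#' @export
ir_scan <- function(x, min_arm = 15L, max_loop = Inf) {
  phased <- phase_repeats(x, min_arm = min_arm, max_loop = max_loop)
  list(repeats = phased, summary = repeat_summary(phased))
}

#' Assemble the full per-phase characteristics table
#'
#' The constraint rows (dipeptide-weighted mean permitted amino acids and
#' mean entropies under actual and equal codon frequencies) and the census
#' rows (observed repeat counts and cumulative arm lengths above each
#' cutoff) for the three phases, in one table.
#'
#' @param x A \code{\link{cds_set}}.
#' @param code A \code{\link{genetic_code}}.
#' @param cutoffs Census arm-length cutoffs (strict \code{>}).
#' @param min_arm Detection threshold feeding the census.
#' @param phase2_variant Phase-2 counting convention; \code{"both"} emits
#'   the two variants side by side (see \code{\link{permitted_aa_count}}).
#' @return A data frame with metrics as rows and phases as columns.
#' @export
ir_table1 <- function(x, code = genetic_code(5L), cutoffs = c(15L, 30L),
                      min_arm = 15L,
                      phase2_variant = c("second", "union", "both")) {
  phase2_variant <- match.arg(phase2_variant)
  variants <- if (phase2_variant == "both") c("second", "union")
              else phase2_variant
  rows <- list()
  for (v in variants) {
    ct <- constraint_table(x, code, phase2_variant = v)
    tag <- if (length(variants) > 1L) paste0(" [phase2:", v, "]") else ""
    rows[[paste0("mean_permitted_aa", tag)]] <- ct$mean_permitted_aa
    rows[[paste0("mean_entropy_actual_bits", tag)]] <- ct$mean_entropy_actual
    rows[[paste0("mean_entropy_equal_bits", tag)]] <- ct$mean_entropy_equal
  }
  phased <- phase_repeats(x, min_arm = min_arm)
  census <- phase_census(phased, cutoffs = cutoffs, strict = TRUE)
  for (co in cutoffs) {
    sub <- census[census$cutoff == co, ]
    rows[[paste0("n_repeats_gt", co)]] <- sub$n[order(sub$phase)]
    rows[[paste0("cumulative_length_gt", co)]] <-
      sub$cumulative_length[order(sub$phase)]
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("phase", 1:3)
  out
}

#' Null-model run: expected counts and over-representation
#'
#' @param x A \code{\link{cds_set}}.
#' @param mode \code{"codon"} or \code{"nucleotide"} shuffling.
#' @param n_replicates Replicates (default 10).
#' @param min_lengths Minimal arm lengths tabulated.
#' @param seed Top-level seed.
#' @return A \code{\link{expected_counts}} ensemble.
#' @export
ir_nullrun <- function(x, mode = "codon", n_replicates = 10L,
                       min_lengths = seq(10L, 30L, 2L), seed = 1L) {
  expected_counts(x, mode = mode, n_replicates = n_replicates,
                  min_lengths = min_lengths, seed = seed)
}
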