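#' Find scored (possibly imperfect) inverted repeats
#'
#' Local-alignment dynamic programming of the sequence against its own
#' reverse complement, reporting non-overlapping locally optimal hairpin
#' stems with score at or above \code{threshold}. The default scoring
#' scheme is match +3, mismatch -4, gap -12 per gapped base, with score
#' threshold 15. Alignment cells are restricted so that every aligned base
#' pair has its 5' partner strictly before its 3' partner, which also makes
#' each stem unique in the output; stems are extracted greedily in score
#' order, masking the sequence positions they cover.
#'
#' \code{n_match} counts the matching (complementary) columns of the stem
#' alignment, supporting arm-length-versus-matching-sites summaries of
#' imperfect repeats.
#'
#' @param seq DNA string.
#' @param match,mismatch,gap Column scores (gap per base; \code{-Inf}
#'   disables gaps or mismatches entirely).
#' @param threshold Minimal reported score.
#' @param max_extent Maximal total span (outermost base to outermost base)
#'   of a reported stem; default unbounded.
#' @param seq_id Optional label.
#' @param max_stems Safety cap on the number of extracted stems.
#' @return A repeat data frame as in \code{\link{find_perfect_irs}}, with
#'   \code{score} filled in and \code{n_match} possibly smaller than
#'   \code{arm_len} (arm length here is the aligned extent on the 5' arm).
#' @export
find_scored_irs <- function(seq, match = 3, mismatch = -4, gap = -12,
                            threshold = 15, max_extent = Inf,
                            seq_id = NA_character_, max_stems = 100L) {
  s <- dna_to_int(seq)
  n <- length(s)
  if (n < 2L) return(empty_repeat_table()[, -(2:3)])
  r <- rev(5L - s)                      # reverse complement, encoded
  use_gap <- is.finite(gap)
  masked <- rep(FALSE, n)
  rows <- list()

  repeat {
    H <- scored_dp(s, r, match, mismatch, gap, use_gap, max_extent, masked)
    best <- max(H)
    if (best < threshold || length(rows) >= max_stems) break
    cell <- which(H == best, arr.ind = TRUE)[1L, ]
    tb <- scored_traceback(H, s, r, match, mismatch, gap, use_gap,
                           cell[1L], cell[2L], n)
    # arm intervals (0-based half-open) in original coordinates
    arm5 <- c(tb$i0 - 1L, tb$i1)
    arm3 <- c(n - tb$j1, n - tb$j0 + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id,
      arm5_start = arm5[1], arm5_end = arm5[2],
      arm3_start = arm3[1], arm3_end = arm3[2],
      arm_len = arm5[2] - arm5[1], loop_len = arm3[1] - arm5[2],
      n_match = tb$n_match, score = best,
      midpoint = (arm5[2] + arm3[1]) / 2,
      at_content = at_content(paste0(
        substr(seq, arm5[1] + 1L, arm5[2]),
        substr(seq, arm3[1] + 1L, arm3[2]))),
      stringsAsFactors = FALSE
    )
    masked[c(seq.int(arm5[1] + 1L, arm5[2]),
             seq.int(arm3[1] + 1L, arm3[2]))] <- TRUE
  }
  if (length(rows) == 0L) return(empty_repeat_table()[, -(2:3)])
  out <- do.call(rbind, rows)
  out <- out[order(out$arm5_start, -out$arm_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Smith-Waterman of s against r (its reverse complement) with linear gaps.
# Row i aligns s[i]; column j aligns r[j], i.e. original position n+1-j.
# Cells with i + j > n (5' partner not strictly before 3' partner) and cells
# whose stem extent would exceed max_extent are forced to zero, as are rows
# and columns touching masked positions.
scored_dp <- function(s, r, match, mismatch, gap, use_gap, max_extent, masked) {
  n <- length(s)
  H <- matrix(0, n + 1L, n + 1L)
  rmasked <- rev(masked)                # masked status of r positions
  for (i in seq_len(n)) {
    jmax <- n - i                       # enforce i + j <= n
    if (jmax < 1L) break
    js <- seq_len(jmax)
    sub <- ifelse(r[js] == s[i], match, mismatch)
    sub[rmasked[js]] <- -Inf
    if (masked[i]) sub[] <- -Inf
    if (is.finite(max_extent)) {
      # extent = (n + 1 - j) - i + 1; ban pairs spanning too far
      sub[(n + 2L - js - i) > max_extent] <- -Inf
    }
    d <- H[i, js] + sub                 # diagonal: H[i-1, j-1] + sub
    t <- pmax(0, d)
    if (use_gap) {
      u <- H[i, js + 1L] + gap          # up: H[i-1, j]
      t <- pmax(t, u)
      # left gaps within the row: g[j] = max(t[j], g[j-1] + gap)
      aux <- t - gap * js
      t <- cummax(aux) + gap * js
    }
    H[i + 1L, js + 1L] <- t
  }
  H
}

scored_traceback <- function(H, s, r, match, mismatch, gap, use_gap,
                             ci, cj, n) {
  i <- ci - 1L; j <- cj - 1L            # sequence indices of the end cell
  i1 <- i; j1 <- j
  n_match <- 0L
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    sub <- if (r[j] == s[i]) match else mismatch
    here <- H[i + 1L, j + 1L]
    if (here == H[i, j] + sub) {
      if (r[j] == s[i]) n_match <- n_match + 1L
      i <- i - 1L; j <- j - 1L
    } else if (use_gap && here == H[i, j + 1L] + gap) {
      i <- i - 1L
    } else if (use_gap && here == H[i + 1L, j] + gap) {
      j <- j - 1L
    } else {
      break
    }
  }
  list(i0 = i + 1L, i1 = i1, j0 = j + 1L, j1 = j1, n_match = n_match)
}
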