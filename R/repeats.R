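#' Find maximal perfect inverted repeats
#'
#' Reports every perfect inverted repeat (hairpin stem) in \code{seq} whose
#' arms cannot be extended: extending both arms outward by one base, or
#' inward by one base (shrinking the loop), either breaks complementarity or
#' would make the arms overlap. Nested and overlapping maximal repeats are
#' all reported; each arm pair is reported once, with the 5' arm first.
#'
#' The detector scans anti-diagonals of the (sequence x reverse-complement)
#' match structure: all base pairs of a hairpin stem share the same index
#' sum, so maximal stems are maximal runs of complementary pairs along one
#' anti-diagonal, truncated at the arm-overlap boundary.
#'
#' Coordinates in the output are 0-based half-open, the package-wide
#' convention for interval arithmetic.
#'
#' @param seq DNA string (A/C/G/T only).
#' @param min_arm Minimal arm length to report (>= 2).
#' @param max_loop Maximal loop (spacer) length; default unbounded, which is
#'   the natural setting when detection runs per CDS.
#' @param seq_id Optional label copied into the output.
#' @return A data frame with one row per repeat: \code{seq_id},
#'   \code{arm5_start}, \code{arm5_end}, \code{arm3_start}, \code{arm3_end}
#'   (0-based half-open), \code{arm_len}, \code{loop_len}, \code{n_match}
#'   (= \code{arm_len} for perfect repeats), \code{score} (NA here),
#'   \code{midpoint} (possibly half-integral) and \code{at_content} over
#'   both arms. Sorted by \code{arm5_start}, then decreasing \code{arm_len}.
#' @examples
#' find_perfect_irs("AAAGAATTCAAA", min_arm = 3)
#' @export
find_perfect_irs <- function(seq, min_arm = 2L, max_loop = Inf,
                             seq_id = NA_character_) {
  if (min_arm < 2L) stop("min_arm must be >= 2")
  s <- dna_to_int(seq)
  n <- length(s)
  a5 <- integer(0); arm <- integer(0); loop <- integer(0)
  if (n >= 2L * min_arm) {
    for (cc in seq_len(2L * n - 3L)) {
      x_hi <- (cc - 1L) %/% 2L
      x_lo <- max(0L, cc - n + 1L)
      if (x_hi < x_lo) next
      xs <- x_lo:x_hi
      b <- (s[xs + 1L] + s[cc - xs + 1L]) == 5L
      r <- rle(b)
      hit <- which(r$values & r$lengths >= min_arm)
      if (length(hit) == 0L) next
      ends <- cumsum(r$lengths)
      for (k in hit) {
        m <- xs[ends[k]]
        L <- r$lengths[k]
        lp <- cc - 2L * m - 1L
        if (lp > max_loop) next
        a5 <- c(a5, m - L + 1L); arm <- c(arm, L); loop <- c(loop, lp)
      }
    }
  }
  if (length(a5) == 0L) return(empty_repeat_table()[, -(2:3)])
  arm3_start <- a5 + arm + loop
  res <- data.frame(
    seq_id = seq_id,
    arm5_start = a5, arm5_end = a5 + arm,
    arm3_start = arm3_start, arm3_end = arm3_start + arm,
    arm_len = arm, loop_len = loop,
    n_match = arm, score = NA_real_,
    midpoint = (a5 + arm + arm3_start) / 2,
    stringsAsFactors = FALSE
  )
  res$at_content <- vapply(seq_len(nrow(res)), function(i) {
    arms <- paste0(substr(seq, res$arm5_start[i] + 1L, res$arm5_end[i]),
                   substr(seq, res$arm3_start[i] + 1L, res$arm3_end[i]))
    at_content(arms)
  }, numeric(1))
  res <- res[order(res$arm5_start, -res$arm_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect maximal perfect inverted repeats across a CDS set
#'
#' Runs \code{\link{find_perfect_irs}} on each record individually (never
#' across gene boundaries) and binds the results, carrying species and gene
#' labels.
#'
#' @param x A \code{\link{cds_set}}.
#' @inheritParams find_perfect_irs
#' @return Combined repeat data frame with \code{species} and \code{gene}
#'   columns.
#' @export
find_perfect_irs_set <- function(x, min_arm = 2L, max_loop = Inf) {
  stopifnot(inherits(x, "cds_set") || is.list(x))
  parts <- lapply(x, function(rec) {
    df <- find_perfect_irs(rec$seq, min_arm = min_arm, max_loop = max_loop,
                           seq_id = paste(rec$species, rec$gene, sep = "|"))
    if (nrow(df) > 0L) {
      df$species <- rec$species
      df$gene <- rec$gene
    }
    df
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  if (length(parts) == 0L) {
    out <- empty_repeat_table()
    return(out)
  }
  out <- do.call(rbind, parts)
  out <- out[, names(empty_repeat_table())]
  rownames(out) <- NULL
  out
}

#' Summarise a repeat table
#'
#' @param repeats A repeat data frame.
#' @return A list: \code{count}, \code{mean_arm_len}, \code{max_arm_len},
#'   \code{mean_loop_len}, \code{mean_at_content} (all means arithmetic;
#'   NA when the table is empty).
#' @export
repeat_summary <- function(repeats) {
  if (nrow(repeats) == 0L) {
    return(list(count = 0L, mean_arm_len = NA_real_, max_arm_len = NA_real_,
                mean_loop_len = NA_real_, mean_at_content = NA_real_))
  }
  list(count = nrow(repeats),
       mean_arm_len = mean(repeats$arm_len),
       max_arm_len = max(repeats$arm_len),
       mean_loop_len = mean(repeats$loop_len),
       mean_at_content = mean(repeats$at_content))
}
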