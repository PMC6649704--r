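# Codon-usage uniformity and composition statistics by repeat region.

#' Wright's effective number of codons (Nc)
#'
#' Measures how uniformly a gene (or region) uses its synonymous codons:
#' Nc equals the number of amino acids under maximal bias and the number of
#' sense codons under uniform usage. Per synonymous family the codon
#' homozygosity is estimated as F = (n * sum(p_i^2) - 1) / (n - 1) with n
#' the family's codon count and p_i the within-family frequencies; family
#' estimates are averaged within degeneracy classes (families of equal
#' size), and Nc sums (number of amino acids in class) / (class mean F)
#' over the classes of the code's actual census (for the invertebrate
#' mitochondrial code: 12 two-fold, 6 four-fold, 1 six-fold, 1 eight-fold
#' family). Single-codon families contribute their count directly (F = 1).
#' Families with fewer than 2 observed codons (or a non-positive F
#' estimate) are imputed by their class mean; a class with no estimable
#' family is imputed by the mean of the nearest estimable classes on either
#' side, mirroring the conventional treatment of the missing isoleucine
#' class. Small samples can push F below 1/familysize, so Nc may exceed
#' the sense-codon count; values are reported as computed.
#'
#' @param usage A \code{\link{codon_usage}} (its \code{counts} are used).
#' @param code A \code{\link{genetic_code}}.
#' @return Nc as a single number (NA when no class is estimable).
#' @export
effective_number_of_codons <- function(usage, code = genetic_code(5L)) {
  fam_F <- vapply(code$families, function(codons) {
    if (length(codons) == 1L) return(1)
    cnt <- as.numeric(usage$counts[codons])
    cnt[is.na(cnt)] <- 0
    n <- sum(cnt)
    if (n < 2) return(NA_real_)
    p <- cnt / n
    Fhat <- (n * sum(p^2) - 1) / (n - 1)
    if (Fhat <= 0) NA_real_ else Fhat
  }, numeric(1))
  sizes <- code$family_sizes
  classes <- sort(unique(sizes))
  class_mean <- vapply(classes, function(k) {
    mean(fam_F[sizes == k], na.rm = TRUE)
  }, numeric(1))
  # impute classes with no estimable family from neighbouring classes
  for (i in seq_along(classes)) {
    if (is.nan(class_mean[i]) || is.na(class_mean[i])) {
      lo <- rev(which(!is.na(class_mean[seq_len(i - 1L)])))
      hi <- which(!is.na(class_mean[-seq_len(i)])) + i
      neigh <- c(if (length(lo)) class_mean[lo[1]],
                 if (length(hi)) class_mean[hi[1]])
      class_mean[i] <- if (length(neigh)) mean(neigh) else NA_real_
    }
  }
  if (anyNA(class_mean)) return(NA_real_)
  n_aa <- vapply(classes, function(k) sum(sizes == k), numeric(1))
  sum(n_aa / class_mean)
}

#' Pool codon and amino-acid counts by repeat phase region
#'
#' Applies \code{\link{phase_region_mask}} to every CDS and pools codon
#' counts into four regions: phase 1, phase 2, phase 3 and non-repeat.
#' Both arms of a repeat contribute to its phase region.
#'
#' @param x A \code{\link{cds_set}}.
#' @param phased Phase-classified repeat data frame for the set (with
#'   \code{species} and \code{gene} columns).
#' @param code A \code{\link{genetic_code}}.
#' @return Named list of regions (\code{"phase1"}, \code{"phase2"},
#'   \code{"phase3"}, \code{"nonrepeat"}), each with \code{codon_counts}
#'   (named integer over 64 codons) and \code{aa_counts}.
#' @export
region_usage <- function(x, phased, code = genetic_code(5L)) {
  all64 <- names(code$codon_to_aa)
  tallies <- lapply(0:3, function(p) stats::setNames(integer(64L), all64))
  names(tallies) <- c("nonrepeat", "phase1", "phase2", "phase3")
  for (rec in x) {
    sub <- phased[phased$species == rec$species & phased$gene == rec$gene, ,
                  drop = FALSE]
    mask <- phase_region_mask(rec, sub)
    codons <- split_codons(rec$seq)
    for (p in 0:3) {
      sel <- codons[mask == p]
      if (length(sel) == 0L) next
      tab <- table(factor(sel, levels = all64))
      key <- names(tallies)[p + 1L]
      tallies[[key]] <- tallies[[key]] + as.integer(tab)
    }
  }
  lapply(tallies, function(cnt) {
    aa <- tapply(cnt, code$codon_to_aa[names(cnt)], sum)
    list(codon_counts = cnt,
         aa_counts = aa[names(aa) != "*"])
  })
}

#' Nc per repeat-phase region
#'
#' @inheritParams region_usage
#' @return Named numeric vector: Nc for phase1, phase2, phase3 and
#'   non-repeat regions.
#' @export
enc_by_region <- function(x, phased, code = genetic_code(5L)) {
  ru <- region_usage(x, phased, code)
  vapply(ru, function(region) {
    usage <- structure(list(counts = region$codon_counts), class = "codon_usage")
    effective_number_of_codons(usage, code)
  }, numeric(1))
}

#' Compare amino-acid composition of a region against a background
#'
#' For each amino acid, builds the 2x2 table (this amino acid vs all
#' others, region vs background) and applies the two-sided Fisher exact
#' test; significance uses a Bonferroni correction over the 20 amino acids
#' (alpha 0.05, i.e. p < 0.0025).
#'
#' @param region,background Named amino-acid count vectors (as produced by
#'   \code{\link{region_usage}}).
#' @param alpha Family-wise significance level before correction.
#' @param code A \code{\link{genetic_code}} (supplies the amino-acid
#'   alphabet and the Bonferroni m).
#' @return Data frame: \code{aa}, \code{region_count}, \code{background_count},
#'   \code{region_freq}, \code{background_freq}, \code{odds_ratio} (sample
#'   odds ratio), \code{p}, \code{significant}.
#' @export
composition_compare <- function(region, background, alpha = 0.05,
                                code = genetic_code(5L)) {
  aas <- code$amino_acids
  r <- stats::setNames(numeric(length(aas)), aas)
  b <- r
  r[names(region)] <- region
  b[names(background)] <- background
  nr <- sum(r); nb <- sum(b)
  if (nr == 0 || nb == 0) stop("zero total counts in region or background")
  m <- length(aas)
  rows <- lapply(aas, function(a) {
    tab <- matrix(c(r[[a]], nr - r[[a]], b[[a]], nb - b[[a]]), nrow = 2,
                  byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    orr <- (r[[a]] * (nb - b[[a]])) / (b[[a]] * (nr - r[[a]]))
    data.frame(aa = a, region_count = r[[a]], background_count = b[[a]],
               region_freq = r[[a]] / nr, background_freq = b[[a]] / nb,
               odds_ratio = orr, p = p,
               significant = p < alpha / m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Central moving average with shrinking edges
#'
#' Smooths a per-site series with a centred window of odd size; near the
#' edges the window shrinks symmetrically to the available sites, so a
#' length-1 series is returned unchanged.
#'
#' @param values Numeric series (e.g. per-site conservation rates).
#' @param window Odd window size (default 5).
#' @return Smoothed numeric series of the same length.
#' @export
smooth_profile <- function(values, window = 5L) {
  n <- length(values)
  if (n == 0L) stop("empty series")
  if (window %% 2L != 1L) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(values[(i - h):(i + h)])
  }, numeric(1))
}
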