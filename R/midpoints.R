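#' Group repeats that share midpoint positions across species
#'
#' Maps each repeat's hairpin midpoint into the column space of a per-gene
#' multiple alignment and groups repeats from different species whose mapped
#' midpoints lie within \code{tolerance} alignment columns of each other
#' (single linkage). Homologous hairpin positions across species show up as
#' groups covering several species.
#'
#' A midpoint at coordinate m (0-based, possibly half-integral) sits between
#' the two innermost loop-flanking bases, or on a central base when the
#' repeat span is odd; its column is the mean of the columns of the bases
#' floor(m - 1/2) and ceiling(m - 1/2). This keeps half-integral midpoints
#' half-integral and is insensitive to alignment gaps inside the loop.
#'
#' @param alignments Named list (gene -> aligned FASTA path or
#'   \code{Biostrings::DNAStringSet}); row names must be species labels.
#' @param phased Phase-classified repeat data frame with \code{species},
#'   \code{gene} and \code{midpoint} columns (CDS coordinates).
#' @param cds A \code{\link{cds_set}} used to verify that each ungapped
#'   alignment row reproduces the corresponding CDS.
#' @param tolerance Maximal column distance for grouping (default 3, one
#'   codon).
#' @return Data frame with one row per repeat in a multi-species group:
#'   \code{group}, \code{gene}, \code{species}, \code{midpoint},
#'   \code{column}, \code{group_size}, \code{n_species}.
#' @export
shared_midpoints <- function(alignments, phased, cds, tolerance = 3) {
  recs <- stats::setNames(
    unclass(cds),
    paste(vapply(cds, `[[`, character(1), "species"),
          vapply(cds, `[[`, character(1), "gene"), sep = "|"))
  out <- list()
  group_id <- 0L
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (is.character(aln)) aln <- Biostrings::readDNAStringSet(aln)
    rows <- stats::setNames(toupper(as.character(aln)), names(aln))
    sub <- phased[phased$gene == gene, , drop = FALSE]
    if (nrow(sub) == 0L) next
    cols <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      sp <- sub$species[i]
      if (!sp %in% names(rows)) {
        stop("species ", sp, " missing from alignment of gene ", gene)
      }
      row <- rows[[sp]]
      ungapped <- gsub("-", "", row, fixed = TRUE)
      key <- paste(sp, gene, sep = "|")
      if (!is.null(recs[[key]]) && ungapped != recs[[key]]$seq) {
        stop("alignment row does not reproduce the CDS for ", sp, "/", gene)
      }
      pos2col <- which(strsplit(row, "", fixed = TRUE)[[1]] != "-")
      m <- sub$midpoint[i]
      lb <- floor(m - 0.5) + 1  # 1-based flanking base indices
      rb <- ceiling(m - 0.5) + 1
      lb <- max(1, min(lb, length(pos2col)))
      rb <- max(1, min(rb, length(pos2col)))
      cols[i] <- (pos2col[lb] + pos2col[rb]) / 2
    }
    # single-linkage chaining along sorted columns
    ord <- order(cols)
    gaps <- diff(cols[ord])
    cluster <- cumsum(c(1, gaps > tolerance))
    for (cl in unique(cluster)) {
      members <- ord[cluster == cl]
      if (length(unique(sub$species[members])) < 2L) next
      group_id <- group_id + 1L
      out[[group_id]] <- data.frame(
        group = group_id, gene = gene,
        species = sub$species[members],
        midpoint = sub$midpoint[members],
        column = cols[members],
        group_size = length(members),
        n_species = length(unique(sub$species[members])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(group = integer(0), gene = character(0),
                      species = character(0), midpoint = numeric(0),
                      column = numeric(0), group_size = integer(0),
                      n_species = integer(0)))
  }
  do.call(rbind, out)
}
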