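#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement on the strict \code{A,C,G,T}
#' alphabet. Ambiguity codes are rejected: repeat identity throughout this
#' package is defined on exact complementarity, so inputs carrying IUPAC
#' ambiguity characters must be cleaned (or excluded) upstream.
#'
#' @param seq A single DNA string (uppercase A/C/G/T).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Genetic code with degeneracy-class partition
#'
#' Wraps an NCBI translation table (via \code{Biostrings::getGeneticCode})
#' together with the partition of its sense codons into synonymous families
#' and the census of family sizes. The default is NCBI table 5, the
#' invertebrate mitochondrial code (ATA = Met, AGA/AGG = Ser, TGA = Trp;
#' stops TAA/TAG), under which serine is an 8-fold family and the code has
#' 62 sense codons.
#'
#' @param table_id NCBI translation table number (1, 2, 4 and 5 are the
#'   intended range; any id known to Biostrings is accepted).
#' @return An object of class \code{genetic_code}: a list with elements
#'   \code{table_id}, \code{codon_to_aa} (named character of length 64, stop
#'   = \code{"*"}), \code{families} (list: amino acid -> synonymous codons),
#'   \code{family_sizes}, \code{stops}, \code{amino_acids}.
#' @export
genetic_code <- function(table_id = 5L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  sense <- map[map != "*"]
  families <- split(names(sense), sense)
  structure(list(
    table_id = as.integer(table_id),
    codon_to_aa = map,
    families = families,
    family_sizes = vapply(families, length, integer(1)),
    stops = names(map)[map == "*"],
    amino_acids = names(families)
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$table_id, "): ",
      length(x$codon_to_aa) - length(x$stops), " sense codons, stops ",
      paste(x$stops, collapse = "/"), "\n", sep = "")
  cat("Family-size census:\n")
  print(table(x$family_sizes))
  invisible(x)
}

#' Translate an in-frame coding sequence
#'
#' Codon-by-codon translation. An internal stop codon signals a mis-framed
#' or mis-annotated CDS and raises an error; a single terminal stop is
#' tolerated (and translated as \code{"*"}) unless
#' \code{allow_terminal_stop = FALSE}.
#'
#' @param seq In-frame DNA string, length divisible by 3.
#' @param code A \code{\link{genetic_code}}.
#' @param allow_terminal_stop Tolerate a stop codon in the final position.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq, code = genetic_code(5L), allow_terminal_stop = TRUE) {
  check_dna(seq)
  codons <- split_codons(seq)
  aa <- unname(code$codon_to_aa[codons])
  n <- length(aa)
  internal <- which(aa == "*")
  if (allow_terminal_stop && n > 0L) internal <- setdiff(internal, n)
  if (length(internal) > 0L) {
    stop("internal stop codon(s) at codon position(s) ",
         paste(internal, collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Construct a CDS record
#'
#' One protein-coding gene: the in-frame coding-strand sequence plus source
#' coordinates. Minus-strand genes must already be reverse-complemented so
#' that \code{seq} is always the coding strand with frame offset 0.
#'
#' @param species,gene Labels.
#' @param seq In-frame coding-strand DNA.
#' @param start,end 1-based inclusive coordinates on the source genome.
#' @param strand \code{"+"} or \code{"-"}.
#' @return An object of class \code{cds_record}.
#' @export
cds_record <- function(species, gene, seq, start = NA_integer_,
                       end = NA_integer_, strand = "+") {
  check_dna(seq, "CDS seq")
  if (nchar(seq) %% 3L != 0L) stop("CDS length not divisible by 3: ", gene)
  structure(list(species = species, gene = gene, seq = seq,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "cds_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s %s: %d bp (%s strand)\n",
              x$species, x$gene, nchar(x$seq), x$strand))
  invisible(x)
}

#' Bundle CDS records into a set
#' @param records List of \code{\link{cds_record}} objects.
#' @return An object of class \code{cds_set} (a list of records).
#' @export
cds_set <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "cds_record")))
  structure(records, class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("<cds_set> %d records, %d bp total, species: %s\n",
              length(x), sum(vapply(x, function(r) nchar(r$seq), integer(1))),
              paste(unique(vapply(x, `[[`, character(1), "species")),
                    collapse = ", ")))
  invisible(x)
}

# Validate a candidate CDS: ACGT alphabet, in frame after trimming terminal
# incomplete codons, no internal stops. Returns the record or NULL (with a
# warning) when the gene must be excluded.
validate_cds <- function(species, gene, seq, start, end, strand, code) {
  if (grepl("[^ACGT]", seq)) {
    warning("excluding ", species, "/", gene,
            ": sequence contains ambiguity codes", call. = FALSE)
    return(NULL)
  }
  # Mitochondrial CDS often end on an incomplete (T / TA) stop completed by
  # polyadenylation; trim to a codon multiple rather than pad.
  extra <- nchar(seq) %% 3L
  if (extra > 0L) seq <- substr(seq, 1L, nchar(seq) - extra)
  if (nchar(seq) < 3L) {
    warning("excluding ", species, "/", gene, ": no complete codon",
            call. = FALSE)
    return(NULL)
  }
  rec <- cds_record(species, gene, seq, start, end, strand)
  ok <- tryCatch({ translate_cds(seq, code); TRUE },
                 error = function(e) {
                   warning("excluding ", species, "/", gene, ": ",
                           conditionMessage(e), call. = FALSE)
                   FALSE })
  if (!ok) return(NULL)
  rec
}

#' Pooled codon usage of a CDS set
#'
#' Counts codons over all records (stop codons are counted but excluded from
#' the frequency normalisation, which runs over sense codons only).
#'
#' @param x A \code{cds_set}, a single \code{cds_record}, or a character
#'   vector of in-frame sequences.
#' @param code A \code{\link{genetic_code}}.
#' @return An object of class \code{codon_usage}: list with \code{counts}
#'   (named integer over all 64 codons) and \code{frequencies} (named
#'   numeric over sense codons, summing to 1).
#' @export
codon_usage <- function(x, code = genetic_code(5L)) {
  seqs <- cds_seqs(x)
  if (length(seqs) == 0L) stop("empty input")
  codons <- unlist(lapply(seqs, split_codons), use.names = FALSE)
  if (length(codons) == 0L) stop("empty input")
  all64 <- names(code$codon_to_aa)
  counts <- table(factor(codons, levels = all64))
  counts <- stats::setNames(as.integer(counts), all64)
  sense <- all64[code$codon_to_aa != "*"]
  tot <- sum(counts[sense])
  if (tot == 0L) stop("no sense codons in input")
  structure(list(counts = counts, frequencies = counts[sense] / tot,
                 table_id = code$table_id),
            class = "codon_usage")
}

#' Uniform codon usage over the sense codons of a code
#' @param code A \code{\link{genetic_code}}.
#' @return A \code{codon_usage} with equal sense-codon frequencies
#'   (counts are all 1).
#' @export
equal_codon_usage <- function(code = genetic_code(5L)) {
  all64 <- names(code$codon_to_aa)
  sense <- all64[code$codon_to_aa != "*"]
  counts <- stats::setNames(as.integer(all64 %in% sense), all64)
  structure(list(counts = counts,
                 frequencies = stats::setNames(rep(1 / length(sense),
                                                   length(sense)), sense),
                 table_id = code$table_id),
            class = "codon_usage")
}

#' Dipeptide frequencies of a CDS set
#'
#' Adjacent amino-acid pairs within each record (never across record
#' boundaries), pooled over the whole set and normalised. The full 400-cell
#' grid (20 x 20 ordered pairs) is returned, zero cells included; terminal
#' stops are dropped before pairing.
#'
#' @inheritParams codon_usage
#' @return An object of class \code{dipeptide_table}: named numeric vector
#'   over ordered pairs (names like \code{"MK"}), summing to 1.
#' @export
dipeptide_frequencies <- function(x, code = genetic_code(5L)) {
  seqs <- cds_seqs(x)
  if (length(seqs) == 0L) stop("empty input")
  aa <- code$amino_acids
  grid <- as.vector(outer(aa, aa, paste0))
  counts <- stats::setNames(numeric(length(grid)), grid)
  n_pairs <- 0L
  for (s in seqs) {
    prot <- translate_cds(s, code)
    prot <- sub("\\*$", "", prot)
    m <- nchar(prot)
    if (m < 2L) next
    pair <- paste0(substring(prot, 1:(m - 1L), 1:(m - 1L)),
                   substring(prot, 2:m, 2:m))
    tab <- table(pair)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    n_pairs <- n_pairs + (m - 1L)
  }
  if (n_pairs == 0L) stop("no dipeptides in input")
  structure(counts / n_pairs, class = "dipeptide_table",
            n_pairs = n_pairs)
}

# Coerce the accepted input types to a character vector of sequences.
cds_seqs <- function(x) {
  if (inherits(x, "cds_record")) return(x$seq)
  if (inherits(x, "cds_set")) {
    return(vapply(x, `[[`, character(1), "seq"))
  }
  if (is.character(x)) return(x)
  if (is.list(x)) return(vapply(x, `[[`, character(1), "seq"))
  stop("cannot interpret input as CDS sequences")
}
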