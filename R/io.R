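# Readers and writers for annotated genomes and derived tables.
#
# GenBank flat files are parsed with a purpose-built reader restricted to
# what CDS extraction needs (LOCUS/ORGANISM, CDS feature locations with
# complement()/join(), /gene and /product qualifiers, ORIGIN block): no
# installed R package parses GenBank feature tables from local files.

#' Read protein-coding genes from a GenBank flat file
#'
#' Extracts every CDS feature of every record in the file. Minus-strand
#' genes are reverse-complemented so the returned sequence is always the
#' coding strand in frame; terminal incomplete codons (the truncated T/TA
#' stops typical of mitochondrial annotation) are trimmed. Records that
#' contain ambiguity codes or internal stops are excluded with a warning.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param code A \code{\link{genetic_code}} used for validation.
#' @param species Optional label overriding the ORGANISM line.
#' @return A \code{\link{cds_set}}.
#' @export
read_cds_genbank <- function(path, code = genetic_code(5L), species = NULL) {
  lines <- readLines(path, warn = FALSE)
  breaks <- grep("^//", lines)
  starts <- c(1L, utils::head(breaks, -1L) + 1L)
  if (length(breaks) == 0L) { starts <- 1L; breaks <- length(lines) }
  records <- list()
  for (k in seq_along(starts)) {
    rec_lines <- lines[starts[k]:breaks[k]]
    records <- c(records, parse_genbank_record(rec_lines, code, species))
  }
  cds_set(records)
}

parse_genbank_record <- function(lines, code, species_override) {
  org <- grep("^ {0,12}ORGANISM", lines, value = TRUE)
  species <- if (!is.null(species_override)) species_override
             else if (length(org) > 0) trimws(sub("^ *ORGANISM *", "", org[1]))
             else trimws(sub("^LOCUS +(\\S+).*", "\\1", lines[1]))

  origin <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(origin) == 1L && origin < length(lines)) {
    body <- lines[(origin + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }

  # CDS features: a location (possibly wrapped over lines) + qualifiers.
  feat_idx <- grep("^ {5}CDS {2,}", lines)
  out <- list()
  for (i in feat_idx) {
    loc <- trimws(sub("^ {5}CDS +", "", lines[i]))
    j <- i + 1L
    while (j <= length(lines) && !grepl("^ {21}/", lines[j]) &&
           !grepl("^ {5}\\S", lines[j]) && grepl("^ {21}\\S", lines[j])) {
      loc <- paste0(loc, trimws(lines[j]))
      j <- j + 1L
    }
    gene <- NA_character_
    while (j <= length(lines) && !grepl("^ {5}\\S", lines[j]) &&
           !grepl("^(ORIGIN|CONTIG|BASE COUNT)", lines[j])) {
      if (grepl("^ {21}/gene=", lines[j])) {
        gene <- gsub("\"", "", sub("^ {21}/gene=", "", lines[j]))
      } else if (is.na(gene) && grepl("^ {21}/product=", lines[j])) {
        gene <- gsub("\"", "", sub("^ {21}/product=", "", lines[j]))
      }
      j <- j + 1L
    }
    parsed <- parse_gb_location(loc)
    if (is.null(parsed)) {
      warning("skipping CDS with unsupported location: ", loc, call. = FALSE)
      next
    }
    pieces <- vapply(seq_len(nrow(parsed$intervals)), function(r) {
      substr(seq, parsed$intervals[r, 1], parsed$intervals[r, 2])
    }, character(1))
    cds_seq <- paste(pieces, collapse = "")
    if (parsed$minus) cds_seq <- reverse_complement_lenient(cds_seq)
    rec <- validate_cds(species, gene, cds_seq,
                        min(parsed$intervals[, 1]), max(parsed$intervals[, 2]),
                        if (parsed$minus) "-" else "+", code)
    if (!is.null(rec)) out <- c(out, list(rec))
  }
  out
}

# Location grammar subset: [complement(] [join(] a..b[,c..d...] [)] [)],
# with <, > partial markers stripped.
parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub(" ", "", loc))
  minus <- grepl("^complement\\(", loc)
  if (minus) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!all(grepl("^[0-9]+\\.\\.[0-9]+$", parts))) return(NULL)
  iv <- t(vapply(strsplit(parts, "..", fixed = TRUE),
                 function(p) as.integer(p), integer(2)))
  list(intervals = iv, minus = minus)
}

# Reverse complement tolerating ambiguity codes (validation happens later,
# at the record level, so the offending gene is named rather than the file).
reverse_complement_lenient <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Read protein-coding genes from a FASTA genome plus a coordinate table
#'
#' Alternative to GenBank input: a plain FASTA genome and a tab-separated
#' gene table with columns \code{gene}, \code{start}, \code{end},
#' \code{strand} (1-based inclusive, as in GenBank annotation).
#'
#' @param fasta_path Single-sequence FASTA of the genome.
#' @param coords Path to the TSV, or an equivalent data frame.
#' @param code A \code{\link{genetic_code}}.
#' @param species Label for the records (default: the FASTA header word).
#' @return A \code{\link{cds_set}}.
#' @export
read_cds_table <- function(fasta_path, coords, code = genetic_code(5L),
                           species = NULL) {
  genome_set <- Biostrings::readDNAStringSet(fasta_path)
  genome <- toupper(as.character(genome_set[[1]]))
  if (is.null(species)) species <- strsplit(names(genome_set)[1], " ")[[1]][1]
  if (is.character(coords)) {
    coords <- utils::read.delim(coords, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(coords)))
  out <- list()
  for (r in seq_len(nrow(coords))) {
    sq <- substr(genome, coords$start[r], coords$end[r])
    if (coords$strand[r] == "-") sq <- reverse_complement_lenient(sq)
    rec <- validate_cds(species, coords$gene[r], sq,
                        coords$start[r], coords$end[r], coords$strand[r], code)
    if (!is.null(rec)) out <- c(out, list(rec))
  }
  cds_set(out)
}

#' Write a CDS set as FASTA
#' @param x A \code{\link{cds_set}}.
#' @param path Output file.
#' @export
write_cds_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(vapply(x, `[[`, character(1), "seq"))
  names(seqs) <- paste(vapply(x, `[[`, character(1), "species"),
                       vapply(x, `[[`, character(1), "gene"), sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a repeat table as TSV
#' @param repeats A repeat data frame (from the detectors or phase classifier).
#' @param path Output file.
#' @export
write_repeats_tsv <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Coding sequences of the four nematomorph mitochondrial genomes
#'
#' Loader for the deposited genomes of the four horsehair-worm species
#' (NCBI GenBank MG257764-MG257767). The sequences are not redistributed
#' with the package; fetch the four accessions (GenBank flat-file format)
#' into a directory and point this function at it.
#'
#' @param dir Directory containing the four GenBank files (any file names;
#'   every \code{.gb}/\code{.gbk}/\code{.genbank} file in it is read).
#' @param code A \code{\link{genetic_code}}; the invertebrate mitochondrial
#'   code (table 5) is the correct one for these genomes.
#' @return A \code{\link{cds_set}} pooling the protein-coding genes of the
#'   four genomes.
#' @export
nematomorph_cds <- function(dir, code = genetic_code(5L)) {
  if (missing(dir) || !dir.exists(dir)) {
    stop("The nematomorph mitochondrial genomes (GenBank accessions ",
         "MG257764-MG257767) are not bundled with the package. ",
         "Download the four accessions as GenBank flat files into a ",
         "directory and pass it as `dir`.")
  }
  files <- list.files(dir, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no GenBank files (*.gb, *.gbk, *.genbank) found in ", dir)
  }
  recs <- unlist(lapply(files, function(f) {
    unclass(read_cds_genbank(f, code = code))
  }), recursive = FALSE)
  cds_set(recs)
}
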