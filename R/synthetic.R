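# Synthetic coding sequences with embedded inverted repeats.
#
# The generator emulates the statistical regime of AT-rich invertebrate
# mitochondrial coding sequences: i.i.d. codons drawn from an AT-rich usage
# under the invertebrate mitochondrial code, with perfect inverted repeats
# of controlled phase, arm length and loop length written into chosen
# positions. Every embedded repeat is perfectly complementary by
# construction; stop codons that would arise on the complementary arm are
# repaired by re-drawing the corresponding focal-arm codon from synonymous
# alternatives, so the complementarity invariant is never relaxed.

#' AT-rich codon usage for sequence generation
#'
#' Codon frequencies from independent per-base probabilities with a target
#' A+T fraction, stop codons removed and the distribution renormalised.
#'
#' @param at Target A+T fraction (the mitochondrial genomes this emulates
#'   range from about 0.65 to 0.78; default 0.72).
#' @param code A \code{\link{genetic_code}}.
#' @return A \code{\link{codon_usage}}.
#' @export
synth_codon_usage <- function(at = 0.72, code = genetic_code(5L)) {
  stopifnot(at > 0, at < 1)
  pb <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  all64 <- names(code$codon_to_aa)
  pr <- vapply(all64, function(cod) {
    b <- strsplit(cod, "")[[1]]
    prod(pb[b])
  }, numeric(1))
  pr[code$codon_to_aa == "*"] <- 0
  pr <- pr / sum(pr)
  sense <- all64[code$codon_to_aa != "*"]
  structure(list(counts = stats::setNames(round(pr * 1e6), all64),
                 frequencies = pr[sense], table_id = code$table_id),
            class = "codon_usage")
}

#' Generate a repeat-free random coding sequence
#'
#' Draws codons i.i.d. from \code{usage} (sense codons only, so no internal
#' stops arise) and rejection-resamples the whole gene until it contains no
#' perfect inverted repeat with arm length at or above
#' \code{ir_free_min_arm}; embedded repeats added afterwards are then the
#' only long ones, giving an exact truth set.
#'
#' @param length_codons Gene length in codons.
#' @param usage A \code{\link{codon_usage}} to draw from.
#' @param code A \code{\link{genetic_code}}.
#' @param seed Integer seed (NULL for the ambient stream).
#' @param ir_free_min_arm Background repeat-freeness threshold (bp).
#' @param species,gene Labels for the record.
#' @param max_attempts Rejection bound; exceeding it raises an error
#'   advising a higher threshold.
#' @return A \code{\link{cds_record}}.
#' @export
generate_cds <- function(length_codons, usage = synth_codon_usage(),
                         code = genetic_code(5L), seed = NULL,
                         ir_free_min_arm = 15L, species = "synthetic",
                         gene = "gene1", max_attempts = 50L) {
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      codons <- sample(names(usage$frequencies), length_codons,
                       replace = TRUE, prob = usage$frequencies)
      seq <- paste(codons, collapse = "")
      hits <- find_perfect_irs(seq, min_arm = ir_free_min_arm)
      if (nrow(hits) == 0L) {
        return(cds_record(species, gene, seq))
      }
    }
    stop("could not generate a repeat-free sequence in ", max_attempts,
         " attempts; raise ir_free_min_arm")
  })
}

#' Embed a perfect inverted repeat of a given phase into a CDS
#'
#' Writes the reverse complement of the (host-derived) 5' arm into the 3'
#' arm interval. The requested phase is obtained by shifting the arm start
#' by 0, 1 or 2 bases (phases cycle 1 -> 2 -> 3 under unit downstream
#' shifts), keeping the requested arm and loop lengths exact. Any codon
#' overlapping the 3' arm that would become a stop is repaired by
#' re-drawing the synonymous choice of the focal-arm codon complementary to
#' the offending base, iterating until the record validates; junction
#' geometries that admit no synonymous fix fall back to mutating a free
#' (non-arm) base of the offending codon, then to replacing the paired
#' focal-arm codon outright (the 5' arm keeps host codons only where
#' possible).
#'
#' @param cds A \code{\link{cds_record}}.
#' @param phase Requested phase (1, 2 or 3).
#' @param arm_len Arm length in bp (>= 2).
#' @param loop_len Loop (spacer) length in bp (>= 0).
#' @param position 0-based start of the 5' arm; NULL picks a random
#'   position. The start actually used may differ by +1 or +2 to satisfy
#'   the phase.
#' @param seed Integer seed.
#' @param code A \code{\link{genetic_code}}.
#' @param max_repair Bound on stop-repair iterations.
#' @return The modified \code{cds_record}, with attribute
#'   \code{"embedded"}: a one-row data frame (\code{arm5_start},
#'   \code{arm_len}, \code{loop_len}, \code{phase}, \code{midpoint}).
#' @export
embed_repeat <- function(cds, phase, arm_len, loop_len, position = NULL,
                         seed = NULL, code = genetic_code(5L),
                         max_repair = 200L) {
  stopifnot(arm_len >= 2L, loop_len >= 0L, phase %in% 1:3)
  n <- nchar(cds$seq)
  span <- 2L * arm_len + loop_len
  if (span + 2L > n) stop("repeat does not fit in the gene")
  with_seed(seed, {
    a <- if (is.null(position)) sample.int(n - span - 2L, 1L) - 1L
         else as.integer(position)
    if (a + span + 2L > n) stop("position leaves no room for a phase shift")
    phase0 <- classify_phase(a, a + span, n)
    delta <- (phase - phase0) %% 3L
    a <- a + delta
    chars <- strsplit(cds$seq, "", fixed = TRUE)[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    arm3_start <- a + arm_len + loop_len
    for (iter in seq_len(max_repair)) {
      arm5 <- chars[(a + 1L):(a + arm_len)]
      chars[(arm3_start + 1L):(arm3_start + arm_len)] <-
        comp[rev(arm5)]
      touched <- codons_touched(arm3_start, arm3_start + arm_len)
      seq_now <- paste(chars, collapse = "")
      codons <- split_codons(seq_now)
      bad <- touched[code$codon_to_aa[codons[touched]] == "*"]
      if (length(bad) == 0L) {
        out <- cds_record(cds$species, cds$gene, seq_now,
                          cds$start, cds$end, cds$strand)
        attr(out, "embedded") <- data.frame(
          arm5_start = a, arm_len = arm_len, loop_len = loop_len,
          phase = phase, midpoint = (a + arm_len + arm3_start) / 2)
        return(out)
      }
      # repair the first offending codon: re-draw, synonymously, a focal-arm
      # codon paired to one of its 3' arm bases; each candidate is applied
      # to a scratch copy (re-writing the 3' arm) and accepted only if it
      # actually resolves this codon
      ci <- bad[1L]
      cod_lo <- (ci - 1L) * 3L       # 0-based codon interval [cod_lo, cod_lo+3)
      inside <- intersect(seq.int(cod_lo, cod_lo + 2L),
                          seq.int(arm3_start, arm3_start + arm_len - 1L))
      fixes_ci <- function(trial_chars) {
        arm5t <- trial_chars[(a + 1L):(a + arm_len)]
        trial_chars[(arm3_start + 1L):(arm3_start + arm_len)] <-
          comp[rev(arm5t)]
        cod <- paste(trial_chars[(cod_lo + 1L):(cod_lo + 3L)], collapse = "")
        if (code$codon_to_aa[[cod]] == "*") NULL else trial_chars
      }
      repaired <- NULL
      for (p in inside[sample.int(length(inside))]) {
        t <- p - arm3_start
        q <- a + (arm_len - 1L) - t          # paired 5' arm base
        qi <- q %/% 3L + 1L                  # its codon index
        current <- codons[qi]
        alts <- setdiff(code$families[[code$codon_to_aa[[current]]]], current)
        for (newc in alts[sample.int(length(alts))]) {
          trial <- chars
          trial[((qi - 1L) * 3L + 1L):(qi * 3L)] <- strsplit(newc, "")[[1]]
          repaired <- fixes_ci(trial)
          if (!is.null(repaired)) break
        }
        if (!is.null(repaired)) break
      }
      if (is.null(repaired)) {
        # fall back to mutating a base of this codon that is free (neither
        # in the 3' arm nor in the focal arm)
        outside <- setdiff(seq.int(cod_lo, cod_lo + 2L),
                           c(seq.int(arm3_start, arm3_start + arm_len - 1L),
                             seq.int(a, a + arm_len - 1L)))
        for (p in outside) {
          for (b in sample(DNA_BASES)) {
            if (b == chars[p + 1L]) next
            trial <- chars
            trial[p + 1L] <- b
            repaired <- fixes_ci(trial)
            if (!is.null(repaired)) break
          }
          if (!is.null(repaired)) break
        }
      }
      if (is.null(repaired)) {
        # last resort: replace a paired focal-arm codon outright (the 5'
        # arm keeps host codons only where possible; some junctions admit
        # no stop-free synonymous choice, e.g. a TA-prefix tyrosine codon
        # meeting a T/C-ending two-fold family)
        sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
        for (p in inside[sample.int(length(inside))]) {
          t <- p - arm3_start
          qi <- (a + (arm_len - 1L) - t) %/% 3L + 1L
          for (newc in sense[sample.int(length(sense))]) {
            trial <- chars
            trial[((qi - 1L) * 3L + 1L):(qi * 3L)] <- strsplit(newc, "")[[1]]
            repaired <- fixes_ci(trial)
            if (!is.null(repaired)) break
          }
          if (!is.null(repaired)) break
        }
      }
      if (is.null(repaired)) {
        stop("no stop-free assignment for codon ", ci, " of ", cds$gene)
      }
      chars <- repaired
    }
    stop("stop repair did not converge for ", cds$gene)
  })
}

#' Introduce mismatches into one arm of an embedded repeat
#'
#' Substitutes \code{n_mismatches} distinct 3' arm positions so that the
#' pairing with the 5' arm is broken there without creating stop codons.
#' The perfect detector then reports only sub-arms; the scored detector
#' still recovers the full stem with score
#' \code{match * (arm_len - n_mismatches) + mismatch * n_mismatches}.
#'
#' @param cds A \code{\link{cds_record}} containing the repeat.
#' @param rpt One-row repeat data frame (0-based \code{arm3_start},
#'   \code{arm3_end}).
#' @param n_mismatches Number of positions to break (< arm length).
#' @param seed Integer seed.
#' @param code A \code{\link{genetic_code}}.
#' @return The modified \code{cds_record}.
#' @export
decay_repeat <- function(cds, rpt, n_mismatches, seed = NULL,
                         code = genetic_code(5L)) {
  arm_len <- rpt$arm3_end - rpt$arm3_start
  stopifnot(n_mismatches < arm_len, n_mismatches >= 0L)
  if (n_mismatches == 0L) return(cds)
  with_seed(seed, {
    chars <- strsplit(cds$seq, "", fixed = TRUE)[[1]]
    pos <- sample(seq.int(rpt$arm3_start, rpt$arm3_end - 1L), n_mismatches)
    for (p in pos) {
      qi <- p %/% 3L + 1L
      cod <- chars[((qi - 1L) * 3L + 1L):(qi * 3L)]
      off <- p - (qi - 1L) * 3L + 1L         # position within codon (1..3)
      ok <- character(0)
      for (b in setdiff(DNA_BASES, chars[p + 1L])) {
        trial <- cod
        trial[off] <- b
        if (code$codon_to_aa[[paste(trial, collapse = "")]] != "*") {
          ok <- c(ok, b)
        }
      }
      if (length(ok) == 0L) stop("cannot break pairing at position ", p,
                                 " without creating a stop")
      chars[p + 1L] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    cds_record(cds$species, cds$gene, paste(chars, collapse = ""),
               cds$start, cds$end, cds$strand)
  })
}

# Default gene complement: the 13 protein-coding genes of a metazoan
# mitochondrial genome with realistic lengths (codons).
default_gene_lengths <- function() {
  c(atp6 = 225L, atp8 = 55L, cob = 370L, cox1 = 515L, cox2 = 230L,
    cox3 = 260L, nad1 = 320L, nad2 = 330L, nad3 = 115L, nad4 = 450L,
    nad4l = 95L, nad5 = 560L, nad6 = 165L)
}

#' Generate a set of synthetic mitochondrial-like genomes
#'
#' Builds \code{n_genomes} genomes of 13 protein-coding genes each from an
#' AT-rich codon usage, embeds perfect inverted repeats according to
#' \code{embedded} (or an automatically drawn complement emulating the
#' repeat load of nematomorph mitochondria: about 27 repeats per genome
#' above 15 bp, phases drawn in proportion 47:22:41, arm lengths 15-142 bp
#' with mean near 43, loops centred near 37 bp), and returns the records
#' together with an exact truth table of what was embedded.
#'
#' @param n_genomes Number of genomes.
#' @param gene_lengths Named integer vector of gene lengths in codons.
#' @param usage A \code{\link{codon_usage}} for background generation.
#' @param code A \code{\link{genetic_code}}.
#' @param embedded Data frame (\code{species}, \code{gene}, \code{phase},
#'   \code{arm_len}, \code{loop_len}, optional \code{position}) of repeats
#'   to embed; NULL draws the default complement.
#' @param n_repeats_per_genome Used when \code{embedded} is NULL.
#' @param ir_free_min_arm Background repeat-freeness threshold.
#' @param seed Integer seed driving all randomness.
#' @return A list: \code{cds} (a \code{\link{cds_set}} pooling all
#'   genomes), \code{truth} (data frame: species, gene, phase, arm_len,
#'   loop_len, arm5_start, midpoint), \code{genomes} (per-species list
#'   with the assembled genome string and its 1-based gene coordinate
#'   table, some genes placed on the minus strand).
#' @export
generate_genome_set <- function(n_genomes = 4L,
                                gene_lengths = default_gene_lengths(),
                                usage = synth_codon_usage(),
                                code = genetic_code(5L),
                                embedded = NULL,
                                n_repeats_per_genome = 27L,
                                ir_free_min_arm = 15L,
                                seed = 1L) {
  with_seed(seed, {
    species <- paste0("genome", seq_len(n_genomes))
    records <- list()
    truth <- list()
    for (sp in species) {
      free <- lapply(gene_lengths * 3L, function(n) {
        cbind(start = 0L, end = n)          # free intervals per gene
      })
      plan <- if (is.null(embedded)) {
        draw_repeat_plan(sp, names(gene_lengths), n_repeats_per_genome)
      } else {
        embedded[embedded$species == sp, , drop = FALSE]
      }
      genes <- list()
      for (g in names(gene_lengths)) {
        genes[[g]] <- generate_cds(gene_lengths[[g]], usage, code,
                                   seed = NULL,
                                   ir_free_min_arm = ir_free_min_arm,
                                   species = sp, gene = g)
      }
      if (nrow(plan) > 0L) for (r in seq_len(nrow(plan))) {
        g <- plan$gene[r]
        span <- 2L * plan$arm_len[r] + plan$loop_len[r]
        pos <- if ("position" %in% names(plan) && !is.na(plan$position[r])) {
          plan$position[r]
        } else {
          pick_free_position(free[[g]], span + 2L, margin = 12L)
        }
        if (is.na(pos)) {                   # gene full; try the others
          for (g2 in sample(names(gene_lengths))) {
            pos <- pick_free_position(free[[g2]], span + 2L, margin = 12L)
            if (!is.na(pos)) { g <- g2; break }
          }
        }
        if (is.na(pos)) next                # nowhere fits; repeat dropped
        rec <- tryCatch(
          embed_repeat(genes[[g]], plan$phase[r], plan$arm_len[r],
                       plan$loop_len[r], position = pos, seed = NULL,
                       code = code),
          error = function(e) NULL)
        if (is.null(rec)) next              # unrepairable geometry; dropped
        genes[[g]] <- rec
        emb <- attr(rec, "embedded")
        free[[g]] <- claim_interval(free[[g]], emb$arm5_start - 12L,
                                    emb$arm5_start + span + 14L)
        emb$species <- sp
        emb$gene <- g
        truth[[length(truth) + 1L]] <- emb
      }
      records <- c(records, unname(genes))
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(arm5_start = integer(0), arm_len = integer(0),
                 loop_len = integer(0), phase = integer(0),
                 midpoint = numeric(0), species = character(0),
                 gene = character(0))
    genomes <- assemble_genomes(records, species)
    list(cds = cds_set(fix_coords(records, genomes)),
         truth = truth[, c("species", "gene", "phase", "arm_len",
                           "loop_len", "arm5_start", "midpoint")],
         genomes = genomes)
  })
}

# Default embedded-repeat complement for one genome: phases in proportion
# 47:22:41, arm lengths 15 + Exp(mean 28) capped at 142, loops |N(37, 18)|.
draw_repeat_plan <- function(sp, genes, n) {
  data.frame(
    species = sp,
    gene = sample(genes, n, replace = TRUE,
                  prob = pmax(default_gene_lengths()[genes], 100)),
    phase = sample(1:3, n, replace = TRUE, prob = c(47, 22, 41)),
    arm_len = pmin(142L, 15L + as.integer(round(stats::rexp(n, 1 / 28)))),
    loop_len = as.integer(round(abs(stats::rnorm(n, 37, 18)))),
    position = NA_integer_,
    stringsAsFactors = FALSE)
}

# Pick a uniform random start for an interval of length `need` inside the
# free intervals, keeping `margin` bp away from previously claimed spans.
pick_free_position <- function(free, need, margin = 12L) {
  cand <- free[free[, "end"] - free[, "start"] >= need + margin, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_integer_)
  row <- cand[sample.int(nrow(cand), 1L), ]
  lo <- row[["start"]]
  hi <- row[["end"]] - need
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

claim_interval <- function(free, lo, hi) {
  out <- list()
  for (r in seq_len(nrow(free))) {
    s <- free[r, "start"]; e <- free[r, "end"]
    if (hi <= s || lo >= e) { out[[length(out) + 1L]] <- c(s, e); next }
    if (lo > s) out[[length(out) + 1L]] <- c(s, lo)
    if (hi < e) out[[length(out) + 1L]] <- c(hi, e)
  }
  if (length(out) == 0L) return(cbind(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Concatenate each genome's genes (some on the minus strand) with random
# spacers, recording 1-based inclusive coordinates.
assemble_genomes <- function(records, species) {
  out <- list()
  for (sp in species) {
    recs <- Filter(function(r) r$species == sp, records)
    genome <- ""
    coords <- list()
    for (i in seq_along(recs)) {
      spacer <- paste(sample(DNA_BASES, 20L, replace = TRUE), collapse = "")
      genome <- paste0(genome, spacer)
      start <- nchar(genome) + 1L
      minus <- i %% 5L == 0L                # a few minus-strand genes
      genome <- paste0(genome,
                       if (minus) reverse_complement(recs[[i]]$seq)
                       else recs[[i]]$seq)
      coords[[i]] <- data.frame(gene = recs[[i]]$gene, start = start,
                                end = nchar(genome),
                                strand = if (minus) "-" else "+",
                                stringsAsFactors = FALSE)
    }
    out[[sp]] <- list(seq = genome, coords = do.call(rbind, coords))
  }
  out
}

# Copy genome coordinates back onto the CDS records.
fix_coords <- function(records, genomes) {
  lapply(records, function(r) {
    co <- genomes[[r$species]]$coords
    row <- co[co$gene == r$gene, ]
    r$start <- row$start[1]; r$end <- row$end[1]; r$strand <- row$strand[1]
    r
  })
}

#' Write a synthetic genome set to disk
#'
#' One FASTA and one gene-coordinate TSV per genome (consumable by
#' \code{\link{read_cds_table}}), plus the truth table of embedded repeats.
#'
#' @param gs Result of \code{\link{generate_genome_set}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_genome_set <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(gs$genomes)) {
    g <- gs$genomes[[sp]]
    seqs <- Biostrings::DNAStringSet(g$seq)
    names(seqs) <- sp
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(sp, ".fasta")))
    utils::write.table(g$coords, file.path(dir, paste0(sp, ".genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(gs$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
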