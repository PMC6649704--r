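# Independent oracles and fixture builders. The oracles deliberately share
# no code with the package internals: the repeat oracle enumerates innermost
# base pairs and extends outward; the Fisher oracle sums hypergeometric
# probabilities over all tables with the observed margins.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

validate_cds_exported <- function(...) codingIR:::validate_cds(...)
split_codons_exported <- function(...) codingIR:::split_codons(...)
random_dna_seeded <- function(n, gc, seed) {
  set.seed(seed)
  random_dna(n, gc)
}
withr_tempfile <- function() tempfile(fileext = ".gb")
withr_tempdir <- function() { d <- tempfile("dir"); dir.create(d); d }

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Maximal perfect inverted repeats by innermost-pair enumeration:
# every maximal repeat has a unique innermost base pair (E, S) (1-based)
# that cannot be moved further inward; extend outward from each such seed.
oracle_find_irs <- function(seq, min_arm = 2L, max_loop = Inf) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  M <- outer(b, unname(COMP[b]), "==")    # M[i, j]: bases i and j pair
  cand <- which(M & upper.tri(M), arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    E <- cand[, 1]; S <- cand[, 2]
    # innermost: either the loop is already < 2 or the next inward pair fails
    inner_ok <- (S - E) < 3L | !M[cbind(E + 1L, S - 1L)]
    E <- E[inner_ok]; S <- S[inner_ok]
  } else {
    E <- integer(0); S <- integer(0)
  }
  L <- rep(1L, length(E))
  t <- 1L
  active <- seq_along(E)
  while (length(active) > 0L) {
    ok <- (E[active] - t) >= 1L & (S[active] + t) <= n
    ok[ok] <- M[cbind(E[active][ok] - t, S[active][ok] + t)]
    L[active[ok]] <- t + 1L
    active <- active[ok]
    t <- t + 1L
  }
  keep <- L >= min_arm & (S - E - 1L) <= max_loop
  out <- data.frame(arm5_start = E[keep] - L[keep],
                    arm5_end = E[keep],
                    arm3_start = S[keep] - 1L,
                    arm3_end = S[keep] - 1L + L[keep],
                    arm_len = L[keep],
                    loop_len = S[keep] - E[keep] - 1L)
  out <- out[order(out$arm5_start, -out$arm_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Definitional maximality check on a reported repeat (string level).
is_maximal_ir <- function(seq, a5, e5, a3, e3) {
  n <- nchar(seq)
  arm5 <- substr(seq, a5 + 1L, e5)
  arm3 <- substr(seq, a3 + 1L, e3)
  perfect <- identical(arm5, reverse_complement(arm3))
  outward <- a5 == 0L || e3 == n ||
    substr(seq, a5, a5) != COMP[[substr(seq, e3 + 1L, e3 + 1L)]]
  inward <- (a3 - e5) < 2L ||
    substr(seq, e5 + 1L, e5 + 1L) != COMP[[substr(seq, a3, a3)]]
  perfect && outward && inward
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= observed).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0L, r1 + c1 - N):min(r1, c1)
  pr <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# The codon-position pairing sets that define each phase.
phase_pairing_set <- function(phase) {
  switch(phase,
         `1` = list(c(1, 1), c(2, 3), c(3, 2)),
         `2` = list(c(2, 2), c(1, 3), c(3, 1)),
         `3` = list(c(3, 3), c(1, 2), c(2, 1)))
}

# Check that every base pair of a repeat respects its phase's pairing set.
phase_pairing_holds <- function(a5, arm_len, loop_len, phase) {
  a3 <- a5 + arm_len + loop_len
  allowed <- phase_pairing_set(phase)
  for (t in seq_len(arm_len) - 1L) {
    i <- a5 + t                      # 0-based base of the 5' arm
    j <- a3 + (arm_len - 1L) - t     # its partner on the 3' arm
    pr <- c(i %% 3L + 1L, j %% 3L + 1L)
    if (!any(vapply(allowed, function(x) all(x == pr), logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

# A small synthetic GenBank flat file exercising plus-strand, minus-strand
# and joined CDS locations; returns the path and the expected sequences.
write_genbank_fixture <- function(path) {
  g1 <- "ATGAAATTTCAT"                       # 5..16, plus strand
  g2 <- "ATGTTAGGATTT"                       # 21..32, minus strand
  g3a <- "ATGCAA"; g3b <- "TTCGGG"           # join(35..40,45..50)
  genome <- paste0("ACGT", g1, "ACGT", reverse_complement(g2), "AC",
                   g3a, "ACGT", g3b, "ACGTACGTAC")
  lines <- c(
    sprintf("LOCUS       SYNREC01  %d bp  DNA  circular  23-SEP-2026",
            nchar(genome)),
    "DEFINITION  synthetic fixture.",
    "  ORGANISM  Testus examplus",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..16",
    "                     /gene=\"g1\"",
    "     CDS             complement(21..32)",
    "                     /gene=\"g2\"",
    "     CDS             join(35..40,45..50)",
    "                     /gene=\"g3\"",
    "ORIGIN",
    paste("        1", tolower(genome)),
    "//")
  writeLines(lines, path)
  list(path = path, genome = genome,
       expected = c(g1 = g1, g2 = g2, g3 = paste0(g3a, g3b)))
}
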