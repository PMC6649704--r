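# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integers 1..4 (A,C,G,T); complement pairs sum to 5.
dna_to_int <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("non-ACGT character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  idx
}

int_to_dna <- function(x) paste(DNA_BASES[x], collapse = "")

check_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string")
  }
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(what, " contains non-ACGT character(s): ", paste(bad, collapse = ", "))
  }
  invisible(seq)
}

# Split an in-frame sequence into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Shannon entropy in bits of a probability vector (zeros ignored).
shannon_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

# Evaluate `code` with a local, restorable RNG state seeded by `seed`.
# NULL seed runs the code under the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fraction of A/T bases in a string.
at_content <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  at <- nchar(gsub("[^AT]", "", seq))
  at / n
}

empty_repeat_table <- function() {
  data.frame(
    seq_id = character(0), species = character(0), gene = character(0),
    arm5_start = integer(0), arm5_end = integer(0),
    arm3_start = integer(0), arm3_end = integer(0),
    arm_len = integer(0), loop_len = integer(0),
    n_match = integer(0), score = numeric(0),
    midpoint = numeric(0), at_content = numeric(0),
    stringsAsFactors = FALSE
  )
}
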