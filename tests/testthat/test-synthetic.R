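cd5 <- genetic_code(5L)

test_that("background generation is reproducible and follows the usage", {
  u <- structure(list(frequencies = stats::setNames(1.0, "ATG")),
                 class = "codon_usage")
  expect_identical(generate_cds(5, usage = u, seed = 1,
                                ir_free_min_arm = 15)$seq,
                   strrep("ATG", 5))
  a <- generate_cds(150, seed = 91)
  b <- generate_cds(150, seed = 91)
  expect_identical(a$seq, b$seq)
  # empirical codon frequencies track the target distribution
  usage <- synth_codon_usage(at = 0.72, code = cd5)
  big <- generate_cds(30000, usage = usage, seed = 92, ir_free_min_arm = 25)
  emp <- table(factor(split_codons_exported(big$seq),
                      levels = names(usage$frequencies)))
  chi <- stats::chisq.test(as.integer(emp), p = usage$frequencies)
  expect_gt(chi$p.value, 0.001)
  # repeat-freeness at the requested threshold
  expect_equal(nrow(find_perfect_irs(a$seq, min_arm = 15)), 0L)
})

test_that("generated material sits in the AT-rich mitochondrial regime", {
  for (at in c(0.65, 0.72, 0.78)) {
    cds <- generate_cds(2000, usage = synth_codon_usage(at = at),
                        seed = round(100 * at), ir_free_min_arm = 20)
    obs <- codingIR:::at_content(cds$seq)
    expect_equal(obs, at, tolerance = 0.03)
  }
})

test_that("embedding round-trips phase, arm length and loop", {
  set.seed(93)
  cases <- expand.grid(phase = 1:3, arm = c(15L, 55L, 142L),
                       loop = c(0L, 37L, 100L))
  for (r in seq_len(nrow(cases))) {
    cds <- generate_cds(180, seed = 900 + r, ir_free_min_arm = 14)
    rec <- embed_repeat(cds, cases$phase[r], cases$arm[r], cases$loop[r],
                        seed = 950 + r)
    emb <- attr(rec, "embedded")
    expect_equal(emb$loop_len, cases$loop[r])
    hits <- phase_repeats(cds_set(list(rec)), min_arm = 14)
    cover <- hits[hits$arm5_start <= emb$arm5_start &
                  hits$arm_len >= cases$arm[r], ]
    expect_gte(nrow(cover), 1L)
    expect_equal(cover$phase[1], cases$phase[r])
    # no stops anywhere; protein preserved for codons outside both arms
    prot <- translate_cds(rec$seq, cd5)
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
    orig <- strsplit(translate_cds(cds$seq, cd5), "")[[1]]
    new <- strsplit(prot, "")[[1]]
    arm_cod <- unique(c(
      codingIR:::codons_touched(emb$arm5_start,
                                emb$arm5_start + cases$arm[r]),
      codingIR:::codons_touched(emb$arm5_start + cases$arm[r] +
                                  cases$loop[r],
                                emb$arm5_start + 2 * cases$arm[r] +
                                  cases$loop[r])))
    outside <- setdiff(seq_along(orig), arm_cod)
    expect_equal(new[outside], orig[outside])
  }
})

test_that("the worked Met-Lys-Phe geometry reproduces the phase-2 example", {
  host <- cds_record("s", "g", "ATGAAATTTCAT")
  rec <- embed_repeat(host, phase = 2, arm_len = 3, loop_len = 0,
                      position = 3L, seed = 94)
  r <- find_perfect_irs(rec$seq, min_arm = 3)
  expect_true(any(r$arm5_start <= 3 & r$arm3_end >= 9))
  expect_equal(classify_phase(3L, 9L, 12L), 2L)
})

test_that("decayed repeats lose perfection but keep the scored stem", {
  cds <- generate_cds(150, seed = 95, ir_free_min_arm = 12)
  rec <- embed_repeat(cds, phase = 1, arm_len = 10, loop_len = 6,
                      seed = 96)
  emb <- attr(rec, "embedded")
  rpt <- data.frame(arm3_start = emb$arm5_start + 10L + 6L,
                    arm3_end = emb$arm5_start + 26L)
  expect_identical(decay_repeat(rec, rpt, 0)$seq, rec$seq)
  dec <- decay_repeat(rec, rpt, 1, seed = 97)
  expect_error(translate_cds(dec$seq, cd5), NA)
  # perfect detector: only sub-arms shorter than the original remain
  perf <- find_perfect_irs(dec$seq, min_arm = 2)
  inside <- perf[perf$arm5_start >= emb$arm5_start - 1 &
                 perf$arm3_end <= emb$arm5_start + 27, ]
  expect_true(all(inside$arm_len < 10))
  # scored detector (span-bounded, as for hairpin-scale stems) recovers the
  # full stem: 9 x 3 - 4 = 23
  sc <- find_scored_irs(dec$seq, threshold = 20, max_extent = 40)
  hit <- sc[abs(sc$midpoint - emb$midpoint) < 2, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$score[1], 23)
})

test_that("genome sets carry an exact truth table", {
  genes <- c(nad1 = 150L, nad2 = 160L, cox1 = 170L, nad5 = 180L)
  emb <- data.frame(species = "genome1",
                    gene = c("nad1", "nad2", "cox1", "nad5"),
                    phase = c(1L, 2L, 3L, 1L),
                    arm_len = c(20L, 25L, 18L, 40L),
                    loop_len = c(10L, 0L, 37L, 22L),
                    position = NA_integer_)
  gs <- generate_genome_set(n_genomes = 1L, gene_lengths = genes,
                            embedded = emb, seed = 98L)
  expect_equal(nrow(gs$truth), 4L)
  scan <- ir_scan(gs$cds, min_arm = 15)
  # recall: every truth repeat is recovered with its phase
  for (r in seq_len(nrow(gs$truth))) {
    tr <- gs$truth[r, ]
    hit <- scan$repeats[scan$repeats$gene == tr$gene &
                        scan$repeats$arm5_start <= tr$arm5_start &
                        scan$repeats$arm_len >= tr$arm_len, ]
    expect_gte(nrow(hit), 1L)
    expect_equal(hit$phase[1], tr$phase)
  }
  # a zero-repeat spec yields a repeat-free genome at the threshold
  gs0 <- generate_genome_set(n_genomes = 1L, gene_lengths = genes,
                             embedded = emb[0, ], ir_free_min_arm = 12L,
                             seed = 99L)
  expect_equal(nrow(gs0$truth), 0L)
  expect_equal(nrow(find_perfect_irs_set(gs0$cds, min_arm = 12)), 0L)
  # determinism of the full generator
  gs_a <- generate_genome_set(n_genomes = 2L, seed = 100L)
  gs_b <- generate_genome_set(n_genomes = 2L, seed = 100L)
  expect_identical(vapply(gs_a$cds, `[[`, character(1), "seq"),
                   vapply(gs_b$cds, `[[`, character(1), "seq"))
  expect_identical(gs_a$truth, gs_b$truth)
})
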