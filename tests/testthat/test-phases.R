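test_that("phase classification matches the worked example and cycles", {
  # CDS ATG AAA TTT CAT, repeat AAA/TTT at [3,6)/[6,9): base 5 (codon
  # position 2) pairs with base 8 (codon position 2) -> phase 2
  expect_equal(classify_phase(3L, 9L, 12L), 2L)
  # unit downstream shifts cycle the phase 2 -> 3 -> 1
  expect_equal(classify_phase(4L, 10L, 15L), 3L)
  expect_equal(classify_phase(5L, 11L, 15L), 1L)
  expect_error(classify_phase(3L, 13L, 12L), "outside")
})

test_that("the phase formula agrees with exhaustive per-base pairing", {
  set.seed(31)
  for (i in 1:80) {
    arm <- sample(6:60, 1)
    loop <- sample(0:50, 1)
    a5 <- sample(0:29, 1)
    span <- 2L * arm + loop
    ph <- classify_phase(a5, a5 + span)
    expect_true(phase_pairing_holds(a5, arm, loop, ph),
                label = sprintf("a5=%d arm=%d loop=%d", a5, arm, loop))
    # the other two phases must violate the pairing set
    for (other in setdiff(1:3, ph)) {
      expect_false(phase_pairing_holds(a5, arm, loop, other))
    }
  }
})

test_that("embedded repeats come back with the requested phase", {
  set.seed(32)
  for (ph in 1:3) for (loop in c(0L, 7L, 37L)) {
    cds <- generate_cds(120, seed = 100 + ph * 10 + loop, ir_free_min_arm = 12)
    rec <- embed_repeat(cds, phase = ph, arm_len = 20, loop_len = loop,
                        seed = 200 + ph + loop)
    hits <- phase_repeats(cds_set(list(rec)), min_arm = 15)
    emb <- attr(rec, "embedded")
    covering <- hits[hits$arm5_start <= emb$arm5_start &
                     hits$arm3_end >= emb$arm5_start + 2 * 20 + loop, ]
    expect_equal(nrow(covering), 1L)
    expect_equal(covering$phase, ph)
    expect_true(covering$arm_len >= 20L)
  }
})

test_that("phase census counts and cumulative lengths are correct", {
  phased <- data.frame(arm_len = c(20L, 31L, 40L, 16L, 33L),
                       phase = c(1L, 1L, 1L, 2L, 3L))
  cen <- phase_census(phased, cutoffs = c(15L, 30L))
  c30 <- cen[cen$cutoff == 30L, ]
  expect_equal(c30$n[c30$phase == 1L], 2L)
  expect_equal(c30$cumulative_length[c30$phase == 1L], 71L)
  c15 <- cen[cen$cutoff == 15L, ]
  expect_equal(sum(c15$n), 5L)
  # strictness: arm of exactly the cutoff is excluded by default
  border <- data.frame(arm_len = 30L, phase = 2L)
  expect_equal(sum(phase_census(border, 30L)$n), 0L)
  expect_equal(sum(phase_census(border, 30L, strict = FALSE)$n), 1L)
  # empty input gives zeros
  expect_equal(sum(phase_census(phased[0, ], c(15L, 30L))$n), 0L)
})

test_that("phase proportion curve is monotone and proportions sum to 1", {
  gs <- generate_genome_set(n_genomes = 1L, n_repeats_per_genome = 8L,
                            seed = 33L)
  phased <- phase_repeats(gs$cds, min_arm = 5)
  curve <- phase_proportion_curve(phased, 5:40)
  expect_true(all(diff(curve$n_total) <= 0))
  nz <- curve$n_total > 0
  expect_equal(curve$p1[nz] + curve$p2[nz] + curve$p3[nz],
               rep(1, sum(nz)))
  # a set with only long phase-1 repeats has proportions (1, 0, 0)
  only1 <- phased[phased$phase == 1L & phased$arm_len >= 25, ]
  c25 <- phase_proportion_curve(only1, 25)
  expect_equal(c(c25$p1, c25$p2, c25$p3), c(1, 0, 0))
})

test_that("phase region mask follows coverage and precedence rules", {
  rec <- cds_record("s", "g", strrep("ATG", 10L))  # 10 codons
  no_reps <- phase_repeats(cds_set(list()), min_arm = 5)[0, ]
  expect_equal(phase_region_mask(rec, no_reps), rep(0L, 10))
  # one phase-2 repeat covering codons 2-3 (bases 3..8, 0-based)
  one <- data.frame(arm5_start = 3L, arm5_end = 6L, arm3_start = 6L,
                    arm3_end = 9L, arm_len = 3L, phase = 2L)
  expect_equal(phase_region_mask(rec, one), c(0L, 2L, 2L, rep(0L, 7)))
  # overlap: phase 1 arm 30 beats phase 3 arm 12 on the shared codon
  big <- data.frame(arm5_start = c(0L, 6L), arm5_end = c(9L, 12L),
                    arm3_start = c(15L, 18L), arm3_end = c(24L, 24L),
                    arm_len = c(30L, 12L), phase = c(1L, 3L))
  mask <- phase_region_mask(rec, big)
  expect_equal(mask[3], 1L)  # codon 3 covered by both arms -> longest wins
})

test_that("shared midpoints group homologous hairpins across species", {
  # four identical CDS with the same embedded repeat
  base <- generate_cds(80, seed = 41, ir_free_min_arm = 10)
  rec <- embed_repeat(base, phase = 1, arm_len = 12, loop_len = 5, seed = 42)
  species <- paste0("sp", 1:4)
  recs <- lapply(species, function(sp) {
    r <- rec; r$species <- sp; r$gene <- "nad1"; r
  })
  cds <- cds_set(recs)
  phased <- phase_repeats(cds, min_arm = 12)
  aln <- Biostrings::DNAStringSet(stats::setNames(
    rep(rec$seq, 4), species))
  groups <- shared_midpoints(list(nad1 = aln), phased, cds, tolerance = 0)
  expect_equal(nrow(groups), 4L)
  expect_equal(unique(groups$n_species), 4L)

  # tolerance semantics: midpoints 2 columns apart group at 3, not at 1
  g <- data.frame(species = c("a", "b"), gene = "g",
                  midpoint = c(10, 12), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    rep(strrep("A", 30), 2), c("a", "b")))
  grouped <- shared_midpoints(list(g = seqs), g, cds_set(list()),
                              tolerance = 3)
  expect_equal(nrow(grouped), 2L)
  apart <- shared_midpoints(list(g = seqs), g, cds_set(list()),
                            tolerance = 1)
  expect_equal(nrow(apart), 0L)

  # mismatching alignment row is reported with the offending record
  bad <- Biostrings::DNAStringSet(stats::setNames(
    c(rec$seq, rec$seq, rec$seq, strrep("A", nchar(rec$seq))), species))
  expect_error(shared_midpoints(list(nad1 = bad), phased, cds),
               "sp4/nad1")
})
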