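test_that("worked examples of the perfect detector", {
  r <- find_perfect_irs("AAAGAATTCAAA", min_arm = 3)
  expect_equal(nrow(r), 1L)
  expect_equal(r$arm5_start, 3L); expect_equal(r$arm5_end, 6L)
  expect_equal(r$arm3_start, 6L); expect_equal(r$arm3_end, 9L)
  expect_equal(r$loop_len, 0L); expect_equal(r$arm_len, 3L)

  r2 <- find_perfect_irs("ACGT", min_arm = 2)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$arm5_start, r2$arm5_end, r2$arm3_start, r2$arm3_end),
               c(0L, 2L, 2L, 4L))

  expect_equal(nrow(find_perfect_irs("AAAAAA", min_arm = 2)), 0L)
})

test_that("perfect detector equals the innermost-pair oracle on random input", {
  set.seed(2301)
  for (i in 1:60) {
    s <- random_dna(sample(50:300, 1), gc = runif(1, 0.2, 0.8))
    min_arm <- sample(2:5, 1)
    got <- find_perfect_irs(s, min_arm = min_arm)
    exp <- oracle_find_irs(s, min_arm = min_arm)
    expect_equal(got[, names(exp)], exp, label = paste("seq", i))
  }
})

test_that("every reported repeat is perfect and maximal by definition", {
  set.seed(2302)
  for (i in 1:30) {
    s <- random_dna(200, gc = runif(1, 0.3, 0.7))
    r <- find_perfect_irs(s, min_arm = 3)
    for (k in seq_len(nrow(r))) {
      expect_true(is_maximal_ir(s, r$arm5_start[k], r$arm5_end[k],
                                r$arm3_start[k], r$arm3_end[k]))
    }
  }
})

test_that("repeat count is invariant to reverse-complementing the input", {
  set.seed(2303)
  for (i in 1:20) {
    s <- random_dna(300, gc = runif(1, 0.25, 0.75))
    a <- find_perfect_irs(s, min_arm = 4)
    b <- find_perfect_irs(reverse_complement(s), min_arm = 4)
    expect_equal(nrow(a), nrow(b))
    expect_equal(sort(a$arm_len), sort(b$arm_len))
  }
})

test_that("max_loop bounds the spacer", {
  s <- paste0("CCCCAA", strrep("A", 30), "TTGGGG")
  unbounded <- find_perfect_irs(s, min_arm = 3)
  bounded <- find_perfect_irs(s, min_arm = 3, max_loop = 10)
  expect_true(any(unbounded$loop_len > 10))
  expect_true(all(bounded$loop_len <= 10))
})

test_that("scored detector reproduces the einverted scoring arithmetic", {
  # perfect stem of 5 paired columns: 5 x 3 = 15, at threshold
  s5 <- paste0("AAAAA", "GATCC", "TTT", "GGATC", "AAAAA")
  r5 <- find_scored_irs(s5, threshold = 15)
  expect_equal(nrow(r5), 1L)
  expect_equal(r5$score, 15)
  expect_equal(r5$n_match, 5L)

  # perfect stem of 6: score 18
  s6 <- paste0("AAAAA", "GATCCG", "TTT", "CGGATC", "AAAAA")
  r6 <- find_scored_irs(s6, threshold = 15)
  expect_equal(r6$score[1], 18)
  expect_equal(r6$n_match[1], 6L)

  # 7 columns with 1 mismatch: 6 x 3 - 4 = 14 < 15, not reported
  # (stem GATCCGA / TCGCATC pairs 6 of 7 columns)
  s7 <- paste0("AAAAA", "GATCCGA", "TTT", "TCGCATC", "AAAAA")
  r7 <- find_scored_irs(s7, threshold = 15)
  expect_equal(nrow(r7), 0L)
  # same stem clears a threshold of 14
  r7b <- find_scored_irs(s7, threshold = 14)
  expect_equal(r7b$score[1], 14)
  expect_equal(r7b$n_match[1], 6L)
})

test_that("scored detector with infinite penalties recovers perfect repeats", {
  set.seed(2304)
  key <- function(d) paste(d$arm5_start, d$arm5_end, d$arm3_start, d$arm3_end)
  for (i in 1:10) {
    s <- random_dna(150, gc = 0.5)
    perfect <- find_perfect_irs(s, min_arm = 5)
    scored <- find_scored_irs(s, mismatch = -Inf, gap = -Inf, threshold = 15)
    if (nrow(scored) > 0L) {
      # all stems are perfect and scored accordingly
      expect_equal(scored$n_match, scored$arm_len)
      expect_equal(scored$score, 3 * scored$arm_len)
      for (k in seq_len(nrow(scored))) {
        arm5 <- substr(s, scored$arm5_start[k] + 1, scored$arm5_end[k])
        arm3 <- substr(s, scored$arm3_start[k] + 1, scored$arm3_end[k])
        expect_identical(arm5, reverse_complement(arm3))
      }
      # the top-scoring stem (extracted before any masking) is one of the
      # maximal perfect repeats; later stems may be truncated by overlap
      top <- scored[which.max(scored$score), ]
      expect_true(key(top) %in% key(perfect))
    }
  }
  # single embedded stem: exact agreement
  cds <- generate_cds(80, seed = 5, ir_free_min_arm = 8)
  rec <- embed_repeat(cds, phase = 1, arm_len = 12, loop_len = 6, seed = 6)
  p <- find_perfect_irs(rec$seq, min_arm = 8)
  sc <- find_scored_irs(rec$seq, mismatch = -Inf, gap = -Inf, threshold = 24)
  expect_equal(nrow(sc), 1L)
  expect_true(sc$arm5_start <= p$arm5_start[1] + 1)
  expect_equal(sc$score, 3 * sc$arm_len)
})

test_that("repeat summary statistics are arithmetic means", {
  df <- data.frame(arm_len = c(15, 43, 142), loop_len = c(4, 4, 4),
                   at_content = c(1, 0.5, 0.3))
  s <- repeat_summary(df)
  expect_equal(s$count, 3L)
  expect_equal(round(s$mean_arm_len, 1), 66.7)
  expect_equal(s$mean_loop_len, 4)
  empty <- repeat_summary(df[0, ])
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$mean_arm_len))
  # all-AT arms give AT content 1
  r <- find_perfect_irs("CCAAAATTTTCC", min_arm = 4)
  expect_equal(r$at_content[r$arm_len == 4][1], 1)
})
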