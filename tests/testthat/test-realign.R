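test_that("identical sequences align as a single full-score block", {
  set.seed(71)
  s <- rand_dna(10)
  a <- spliced_align(s, s)
  expect_equal(a$score, 80)
  expect_equal(nrow(a$blocks), 1)
  expect_equal(a$identity, 1)
  expect_equal(a$aligned_fraction, 1)
})

test_that("an intron in the window is bridged by a cheap transcript-side gap", {
  set.seed(73)
  e1 <- rand_dna(50); e2 <- rand_dna(50); intr <- rand_dna(90)
  a <- spliced_align(paste0(e1, e2), paste0(e1, intr, e2))
  expect_equal(a$score, 100 * 8 - 90 * 1)
  expect_equal(nrow(a$blocks), 2)
  expect_equal(a$blocks$w_start, c(0L, 140L))
})

test_that("no aligned block shorter than the minimum ever appears", {
  set.seed(79)
  for (i in 1:25) {
    b <- rand_dna(sample(5:30, 1))
    w <- rand_dna(sample(10:60, 1))
    a <- spliced_align(b, w)
    if (nrow(a$blocks) > 0)
      expect_true(all(a$blocks$bes_end - a$blocks$bes_start >= 4))
  }
})

test_that("constrained aligner score matches exhaustive enumeration on tiny pairs", {
  set.seed(83)
  for (i in 1:30) {
    b <- rand_dna(sample(4:7, 1))
    w <- rand_dna(sample(4:8, 1))
    got <- spliced_align(b, w)$score
    want <- oracle_spliced_score(b, w)
    expect_equal(got, want, info = paste(b, w))
  }
  # and with N characters on either side
  for (i in 1:10) {
    b <- chartr("T", "N", rand_dna(sample(4:6, 1)))
    w <- chartr("G", "N", rand_dna(sample(4:7, 1)))
    expect_equal(spliced_align(b, w)$score, oracle_spliced_score(b, w),
                 info = paste(b, w))
  }
})

test_that("window overhang is free and leading placement is found", {
  set.seed(89)
  core <- rand_dna(20)
  w <- paste0(rand_dna(30), core, rand_dna(25))
  a <- spliced_align(core, w)
  expect_equal(a$score, 160)
  expect_equal(a$blocks$w_start, 30L)
})

test_that("introducing a mismatch never increases the score", {
  set.seed(97)
  for (i in 1:10) {
    b <- rand_dna(30)
    w <- paste0(rand_dna(10), b, rand_dna(10))
    s0 <- spliced_align(b, w)$score
    ch <- strsplit(b, "", fixed = TRUE)[[1]]
    p <- sample(30, 1)
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    s1 <- spliced_align(paste(ch, collapse = ""), w)$score
    expect_lte(s1, s0)
  }
})

make_bes <- function(gene_id, sequence, up = 0L, down = 0L,
                     bridged = 0L, unresolved = 0L) {
  structure(list(
    gene_id = gene_id, sequence = sequence,
    bridged_flags = tibble::tibble(flag = seq_len(bridged),
                                   offset_used = 6L,
                                   spanning_len = 50L)[seq_len(bridged), ],
    unresolved_flags = tibble::tibble(flag = integer(unresolved),
                                      reason = character(unresolved)),
    upstream_extension_len = up, downstream_extension_len = down,
    fdm = NULL), class = "bes")
}

test_that("BES trimming and window selection follow the 5 percent / 3x rules", {
  fx <- toy_gene(c(200L, 150L), 80L, seed = 101, flank = 400)
  tx <- transcript_sequences(fx$model, fx$genome)
  bes <- make_bes("toy1", paste0(rand_dna(100), tx$seq, rand_dna(40)),
                  up = 100L, down = 40L)
  prep <- prepare_bes(bes, fx$model, fx$genome)
  expect_equal(prep$trim_up, 5L)
  expect_equal(prep$trim_down, 2L)
  expect_equal(nchar(prep$bes_seq), 100 + nchar(tx$seq) + 40 - 7)
  expect_equal(prep$window$start, fx$model$start[1] - 300L)
  expect_equal(prep$window$end, max(fx$model$end) + 120L)

  # zero extensions: window equals the model span
  bes0 <- make_bes("toy1", tx$seq)
  prep0 <- prepare_bes(bes0, fx$model, fx$genome)
  expect_equal(prep0$bes_seq, tx$seq)
  expect_equal(prep0$window$start, fx$model$start[1])
  expect_equal(prep0$window$end, max(fx$model$end))

  # clipping at the scaffold edge
  fx2 <- toy_gene(c(60L), integer(0), seed = 103, flank = 10)
  bes2 <- make_bes("toy1", paste0(rand_dna(50), substr(fx2$genome$seq, 11,
                                                       70)), up = 50L)
  prep2 <- prepare_bes(bes2, fx2$model, fx2$genome)
  expect_equal(prep2$window$start, 0L)
})

test_that("structure recovery returns the true exons and flips strand when needed", {
  for (strand in c("+", "-")) {
    fx <- toy_gene(c(120L, 60L, 90L), c(70L, 55L), strand = strand,
                   seed = 107)
    tx <- transcript_sequences(fx$model, fx$genome)
    bes <- make_bes("toy1", tx$seq)
    cm <- recover_structure(bes, fx$model, fx$genome)
    expect_equal(cm$outcome, "validated")
    expect_equal(cm$orientation, strand)
    expect_equal(cm$exons$start, fx$model$start)
    expect_equal(cm$exons$end, fx$model$end)
  }
})

test_that("unresolved flags or absent alignment fail the model", {
  fx <- toy_gene(c(120L, 60L), 70L, seed = 109)
  bes_x <- make_bes("toy1", paste0(rand_dna(50), "X", rand_dna(50)),
                    unresolved = 1L)
  cm <- recover_structure(bes_x, fx$model, fx$genome)
  expect_equal(cm$outcome, "failed")
  expect_equal(cm$reason, "unresolved_flags")

  bes_junk <- make_bes("toy1", rand_dna(180))
  cm2 <- recover_structure(bes_junk, fx$model, fx$genome)
  expect_equal(cm2$outcome, "failed")
  expect_equal(cm2$reason, "no_alignment")
})

test_that("outcome classification applies the three change criteria", {
  base_change <- list(bridged_flag_count = 0L, exon_count_delta = 0L,
                      size_change_fraction = 0)
  new <- list(change_record = base_change)
  expect_equal(classify_outcome(NULL, new, NULL), "validated")
  new$change_record$bridged_flag_count <- 1L
  expect_equal(classify_outcome(NULL, new, NULL), "corrected")
  new$change_record <- base_change
  new$change_record$exon_count_delta <- -1L
  expect_equal(classify_outcome(NULL, new, NULL), "corrected")
  new$change_record <- base_change
  new$change_record$size_change_fraction <- 0.3
  expect_equal(classify_outcome(NULL, new, NULL), "corrected")
  new$change_record$size_change_fraction <- 0.09
  expect_equal(classify_outcome(NULL, new, NULL), "validated")
})
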