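test_that("ungapped aligner reports exact, mismatched and reverse placements", {
  set.seed(21)
  ref <- tibble::tibble(id = "ref", seq = rand_dna(200))
  r1 <- substr(ref$seq, 11, 56)                 # offset 10, forward
  r2 <- rc_chr(substr(ref$seq, 1, 46))          # offset 0, reverse
  ch <- strsplit(substr(ref$seq, 61, 106), "", fixed = TRUE)[[1]]
  ch[c(3, 17, 30)] <- vapply(ch[c(3, 17, 30)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  r3 <- paste(ch, collapse = "")                # 3 mismatches everywhere
  reads <- tibble::tibble(id = c("r1", "r2", "r3"), seq = c(r1, r2, r3))
  aln <- align_ungapped(reads, ref, max_mismatch = 2)
  a1 <- aln[aln$read_id == "r1", ]
  expect_true(any(a1$offset == 10 & a1$orientation == "+" &
                    a1$mismatches == 0))
  a2 <- aln[aln$read_id == "r2", ]
  expect_true(any(a2$offset == 0 & a2$orientation == "-" &
                    a2$mismatches == 0))
  expect_equal(nrow(aln[aln$read_id == "r3", ]), 0)
  expect_equal(nrow(align_ungapped(reads[0, ], ref, 2)), 0)
})

test_that("aligner agrees with a brute-force Hamming scan", {
  for (seed in c(3, 9)) {
    set.seed(seed)
    refs <- tibble::tibble(id = c("a", "b"),
                           seq = c(rand_dna(400), rand_dna(250)))
    reads <- tibble::tibble(id = sprintf("q%d", 1:6),
                            seq = c(substr(refs$seq[1], 21, 40),
                                    rc_chr(substr(refs$seq[2], 101, 120)),
                                    replicate(4, rand_dna(20))))
    got <- align_ungapped(reads, refs, max_mismatch = 2)
    want <- oracle_align(reads, refs, 2)
    key <- function(d) sort(paste(d$read_id, d$ref_id, d$offset,
                                  d$orientation, d$mismatches))
    expect_equal(key(got), key(want))
  }
})

test_that("alignment sets obey the Set 1/2/3 definitions", {
  genome <- tibble::tibble(
    read_id = c("a", "b"), ref_id = "scaf", offset = c(0L, 5L),
    orientation = "+", mismatches = 0L)
  models <- tibble::tibble(
    read_id = c("b", "c"), ref_id = "g1", offset = c(2L, 9L),
    orientation = "+", mismatches = 0L)
  sets <- partition_alignment_sets(genome, models)
  expect_equal(sets$set2$read_id, "c")          # b has a genome alignment
  expect_equal(sort(unique(sets$set3$read_id)), c("b", "c"))
  expect_length(intersect(sets$set2$read_id, genome$read_id), 0)
})

test_that("junction-spanning reads land in Set 2 exactly as the exon map predicts", {
  # with a zero-mismatch budget, a tiled read is in Set 2 iff its window
  # crosses an intron by at least one base on each side
  fx <- toy_gene(c(120L, 80L, 100L), c(60L, 70L), seed = 31)
  tx <- transcript_sequences(fx$model, fx$genome)
  reads <- tile_reads(tx$seq, 46)
  sets <- partition_alignment_sets(
    align_ungapped(reads, fx$genome, 0),
    align_ungapped(reads, tx, 0))
  junctions <- cumsum(c(120L, 80L))             # transcript coords
  starts <- 0:(nchar(tx$seq) - 46)
  crossing <- vapply(starts, function(o)
    any(o + 1 <= junctions & o + 46 - 1 >= junctions), logical(1))
  expect_equal(sort(unique(sets$set2$read_id)), sort(reads$id[crossing]))
})

test_that("coverage profiles conserve alignment bases and count junction support", {
  fx <- toy_gene(c(120L, 80L, 100L), c(60L, 70L), seed = 31)
  tx <- transcript_sequences(fx$model, fx$genome)
  reads <- tile_reads(tx$seq, 46)
  sets <- partition_alignment_sets(
    align_ungapped(reads, fx$genome, 0),
    align_ungapped(reads, tx, 0))
  prof <- coverage_profile(fx$model, sets, read_len = 46)
  # conservation: every Set-1 alignment contributes exactly read_len bases
  # (toy scaffold holds a single gene, all alignments inside the span)
  expect_equal(sum(prof$genome_align), nrow(sets$set1) * 46)
  # tiling support: read_len - 2 * min_overhang + 1 per internal junction
  expect_equal(prof$junctions$support, c(41L, 41L))
  # zero reads give an all-zero profile
  empty <- partition_alignment_sets(
    align_ungapped(reads[0, ], fx$genome, 0),
    align_ungapped(reads[0, ], tx, 0))
  p0 <- coverage_profile(fx$model, empty, read_len = 46)
  expect_true(all(p0$genome_align == 0) && all(p0$border_align == 0))
  expect_true(all(p0$junctions$support == 0))
})

test_that("a single genome read covers exactly its footprint", {
  fx <- toy_gene(c(200L), integer(0), seed = 8)
  read <- tibble::tibble(id = "r", seq = substr(fx$genome$seq, 101, 146))
  tx <- transcript_sequences(fx$model, fx$genome)
  sets <- partition_alignment_sets(align_ungapped(read, fx$genome, 0),
                                   align_ungapped(read, tx, 0))
  prof <- coverage_profile(fx$model, sets, read_len = 46)
  expect_equal(sum(prof$genome_align), 46L)
  expect_equal(max(prof$genome_align), 1L)
})

test_that("expression summaries reproduce the RPK to depth correspondence", {
  model <- tibble::tibble(gene_id = "g", scaffold_id = "s", strand = "+",
                          exon_rank = 1L, start = 0L, end = 1000L)
  sets <- structure(list(
    set1 = tibble::tibble(read_id = character(), ref_id = character(),
                          offset = integer(), orientation = character(),
                          mismatches = integer()),
    set2 = tibble::tibble(read_id = character(), ref_id = character(),
                          offset = integer(), orientation = character(),
                          mismatches = integer()),
    set3 = tibble::tibble(read_id = sprintf("r%d", 1:500), ref_id = "g",
                          offset = 0L, orientation = "+",
                          mismatches = 0L)), class = "alignment_sets")
  e <- compute_expression(model, sets, read_len = 46)
  expect_equal(e$rpk, 500)
  expect_equal(e$mean_depth, 23)

  model2 <- dplyr::mutate(model, end = 2000L)
  sets$set3 <- sets$set3[1:120, ]
  e2 <- compute_expression(model2, sets, read_len = 46)
  expect_equal(e2$rpk, 60)
  expect_equal(e2$mean_depth, 2.76)

  sets$set3 <- sets$set3[0, ]
  e0 <- compute_expression(model, sets, read_len = 46)
  expect_equal(e0$rpk, 0)
  expect_equal(e0$mean_depth, 0)

  bad <- dplyr::mutate(model, end = 0L)
  expect_error(compute_expression(bad, sets, 46), "zero length")
})
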