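test_that("truth sets are deterministic and corruption-free configs change nothing", {
  cfg <- fixture_config(seed = 5, n_genes = 6, n_scaffolds = 2,
                        corruption = c(splice_shift = 0,
                                       spurious_intron = 0,
                                       missing_exon = 0,
                                       truncated_terminus = 0,
                                       extended_terminus = 0))
  t1 <- generate_truth_set(cfg)
  t2 <- generate_truth_set(cfg)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$true_models, t2$true_models)
  expect_identical(t1$corrupted_models, t2$corrupted_models)
  expect_identical(t1$true_models, t1$corrupted_models)
  expect_true(all(t1$ledger$corruption == "none"))
  r1 <- simulate_reads(t1)
  r2 <- simulate_reads(t2)
  expect_identical(r1, r2)
})

test_that("corruption counts are exact by construction", {
  cfg <- fixture_config(seed = 9, n_genes = 10,
                        corruption = c(splice_shift = 1,
                                       spurious_intron = 0,
                                       missing_exon = 0,
                                       truncated_terminus = 0,
                                       extended_terminus = 0))
  t <- generate_truth_set(cfg)
  expect_equal(sum(t$ledger$corruption == "splice_shift"), 10)
  # every corrupted model differs from its true model
  for (g in t$ledger$gene_id)
    expect_false(identical(
      t$true_models[t$true_models$gene_id == g, ],
      t$corrupted_models[t$corrupted_models$gene_id == g, ]))

  cfg2 <- fixture_config(seed = 9, n_genes = 20)
  t2 <- generate_truth_set(cfg2)
  expect_equal(unname(table(t2$ledger$corruption)[
    c("splice_shift", "spurious_intron", "missing_exon",
      "truncated_terminus", "extended_terminus")]),
    rep(4L, 5), ignore_attr = TRUE)
})

test_that("step-1 tiling emits every window and random mode hits the depth formula", {
  # single-exon 100-bp gene: 55 windows of 46 nt
  cfg <- fixture_config(seed = 3, n_genes = 1, n_scaffolds = 1,
                        exon_count_range = 1L,
                        exon_len_range = c(100, 100),
                        corruption = c(splice_shift = 0,
                                       spurious_intron = 0,
                                       missing_exon = 0,
                                       truncated_terminus = 0,
                                       extended_terminus = 0),
                        depth = 1)
  t <- generate_truth_set(cfg)
  reads <- simulate_reads(t)
  expect_equal(nrow(reads), 100 - 46 + 1)
  # interior coverage is read_len: count reads covering position 50
  tx <- transcript_sequences(t$true_models, t$genome)
  aln <- align_ungapped(reads, tx, 0)
  expect_equal(sum(aln$offset <= 50 & aln$offset + 45 >= 50), 46)
  # every error-free read is a transcript substring in some orientation
  ok <- vapply(reads$seq, function(r)
    grepl(r, tx$seq, fixed = TRUE) ||
      grepl(rc_chr(r), tx$seq, fixed = TRUE), logical(1))
  expect_true(all(ok))

  # random mode at depth 23 on a 1-kb transcript: 500 reads
  cfg2 <- fixture_config(seed = 3, n_genes = 1, n_scaffolds = 1,
                         exon_count_range = 1L,
                         exon_len_range = c(1000, 1000),
                         corruption = c(splice_shift = 0,
                                        spurious_intron = 0,
                                        missing_exon = 0,
                                        truncated_terminus = 0,
                                        extended_terminus = 0),
                         depth = 23, tiling = "random")
  t2 <- generate_truth_set(cfg2)
  expect_equal(nrow(simulate_reads(t2)), 500)
})

test_that("read errors are applied at the requested rate", {
  cfg <- fixture_config(seed = 13, n_genes = 1, n_scaffolds = 1,
                        exon_count_range = 1L,
                        exon_len_range = c(2000, 2000),
                        corruption = c(splice_shift = 0,
                                       spurious_intron = 0,
                                       missing_exon = 0,
                                       truncated_terminus = 0,
                                       extended_terminus = 0),
                        depth = 1, read_error_rate = 0.02)
  t <- generate_truth_set(cfg)
  reads <- simulate_reads(t)
  tx <- transcript_sequences(t$true_models, t$genome)
  # step-1 tiling is deterministic: read i starts at i - 1 and alternates
  # orientation, so the error count is a direct comparison with the truth
  mm <- vapply(seq_len(nrow(reads)), function(i) {
    truth <- substr(tx$seq, i, i + 45)
    s <- if (i %% 2 == 1) reads$seq[i] else rc_chr(reads$seq[i])
    sum(strsplit(s, "")[[1]] != strsplit(truth, "")[[1]])
  }, numeric(1))
  rate <- mean(mm) / 46
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.04)
})

test_that("the exon-length series fixture merges the two introns in the prediction", {
  t <- exon_series_fixture(mid_lens = c(9L, 21L), seed = 2)
  expect_equal(nrow(t$true_models), 6)
  expect_equal(nrow(t$corrupted_models), 4)
  g9_true <- t$true_models[t$true_models$gene_id == "series009", ]
  g9_pred <- t$corrupted_models[t$corrupted_models$gene_id == "series009", ]
  expect_equal(g9_true$end - g9_true$start, c(200L, 9L, 200L))
  expect_equal(nrow(g9_pred), 2)
  expect_equal(g9_pred$start, g9_true$start[c(1, 3)])
})

test_that("truth sets round-trip to disk in standard formats", {
  cfg <- fixture_config(seed = 15, n_genes = 3, n_scaffolds = 1)
  t <- generate_truth_set(cfg)
  dir <- withr::local_tempdir()
  write_truth_set(t, dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fa", "true.gff3",
                                               "predicted.gff3",
                                               "reads.fastq",
                                               "ledger.tsv")))))
  g <- read_sequences(file.path(dir, "genome.fa"))
  expect_identical(g, t$genome)
  m <- read_gene_models(file.path(dir, "true.gff3"))
  expect_equal(as.data.frame(dplyr::arrange(m, gene_id, exon_rank)),
               as.data.frame(dplyr::arrange(t$true_models, gene_id,
                                            exon_rank)))
})
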