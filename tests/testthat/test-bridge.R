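test_that("probe queries and consensus agree with a direct tally", {
  set.seed(41)
  s <- rand_dna(500)
  reads <- tile_reads(s, 46)
  idx <- read_index(reads)
  probe <- substr(s, 1, 18)
  expect_equal(find_next_probe(idx, probe), substr(s, 19, 36))
  expect_equal(find_next_probe(idx, substr(s, 101, 118)),
               substr(s, 119, 136))
  # agreement with the oracle tally at several probes
  for (p0 in c(1, 57, 200, 433)) {
    probe <- substr(s, p0, p0 + 17)
    expect_equal(find_next_probe(idx, probe),
                 oracle_next_probe(reads, probe))
  }
  # absent probe: zero coverage everywhere
  absent <- strrep("A", 18)
  expect_equal(find_next_probe(idx, absent), strrep("N", 18))
  # queries in the reverse orientation are found
  hits <- index_query(idx, rc_chr(substr(s, 10, 27)))
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$orientation == "-"))
})

test_that("consensus follows the strict majority and calls N on ties", {
  set.seed(43)
  a <- rand_dna(200)
  pos <- 90
  b_ch <- strsplit(a, "", fixed = TRUE)[[1]]
  b_ch[pos] <- setdiff(c("A", "C", "G", "T"), b_ch[pos])[1]
  b <- paste(b_ch, collapse = "")
  probe <- substr(a, 61, 78)   # the divergent base is 12 bases downstream
  # 60/40 mixture: the majority variant's base is emitted
  reads_60_40 <- dplyr::bind_rows(
    tile_reads(a, 46, "a1"), tile_reads(a, 46, "a2"),
    tile_reads(a, 46, "a3"), tile_reads(b, 46, "b1"),
    tile_reads(b, 46, "b2"))
  nxt <- find_next_probe(read_index(reads_60_40), probe)
  expect_equal(substr(nxt, 12, 12), substr(a, 90, 90))
  # 50/50 tie: N
  reads_50_50 <- dplyr::bind_rows(tile_reads(a, 46, "a1"),
                                  tile_reads(b, 46, "b1"))
  nxt2 <- find_next_probe(read_index(reads_50_50), probe)
  expect_equal(substr(nxt2, 12, 12), "N")
  # all other positions agree between variants and are called normally
  expect_equal(substr(nxt2, 1, 11), substr(a, 79, 89))
  expect_equal(substr(nxt2, 13, 18), substr(a, 91, 96))
})

test_that("bridging reconstructs the true inter-probe sequence exactly", {
  set.seed(47)
  s <- rand_dna(600)
  idx <- read_index(tile_reads(s, 46))
  start_probe <- substr(s, 101, 118)
  end_probe <- substr(s, 209, 226)   # 90 bp between the probes
  res <- bridge_probes(idx, start_probe, end_probe)
  expect_equal(res$status, "end_probe_found")
  expect_equal(res$sequence, substr(s, 101, 226))
  expect_equal(res$n_count, 0L)
  # property: arbitrary probe pairs along a deeply tiled transcript
  for (a0 in c(1, 50, 150)) {
    b0 <- a0 + sample(40:300, 1)
    r <- bridge_probes(idx, substr(s, a0, a0 + 17),
                       substr(s, b0, b0 + 17))
    expect_equal(r$status, "end_probe_found")
    expect_equal(r$sequence, substr(s, a0, b0 + 17))
  }
})

test_that("bridging stops at the iteration and N budgets", {
  set.seed(53)
  s <- rand_dna(700)
  other <- rand_dna(100)
  idx <- read_index(tile_reads(s, 46))
  # end probe from a never-expressed sequence: the contig grows cleanly
  # until the iteration budget runs out
  res <- bridge_probes(idx, substr(s, 1, 18), substr(other, 1, 18))
  expect_equal(res$status, "max_look_exceeded")
  expect_equal(res$iterations_used, 27L)
  # a coverage hole accumulates N beyond the budget
  hole <- dplyr::bind_rows(tile_reads(substr(s, 1, 200), 46, "l"),
                           tile_reads(substr(s, 251, 700), 46, "r"))
  res2 <- bridge_probes(read_index(hole), substr(s, 101, 118),
                        substr(s, 301, 318))
  expect_equal(res2$status, "max_n_exceeded")
  expect_gt(res2$n_count, 6)
  # no occurrence of the start probe at all
  res3 <- bridge_probes(idx, strrep("A", 18), substr(s, 101, 118))
  expect_equal(res3$status, "no_reads_matched")
})

test_that("flag resolution walks the probe-offset ladder", {
  set.seed(59)
  s <- rand_dna(400)
  flag_at <- 200L  # transcript position of a 1-bp flagged deviation
  fdm <- make_fdm(list(kind = "seq", seq = substr(s, 1, flag_at)),
                  list(kind = "X"),
                  list(kind = "seq", seq = substr(s, flag_at + 2, 400)))
  fdm$trimmed <- TRUE
  idx <- read_index(tile_reads(s, 46))
  res <- resolve_flag(fdm, 1, idx)
  expect_equal(res$offset_used, 6)
  # the spanning sequence covers probe + margin + flag + margin + probe
  expect_equal(res$sequence,
               substr(s, flag_at - 6 - 18 + 1, flag_at + 1 + 6 + 18))

  # corrupt the offset-6 upstream probe site in every read: reads carry a
  # substitution 10 bp before the flag, inside the first probe window but
  # outside the offset-15 window
  s_mut <- s
  substr(s_mut, flag_at - 10, flag_at - 10) <-
    setdiff(c("A", "C", "G", "T"),
            substr(s, flag_at - 10, flag_at - 10))[1]
  idx_mut <- read_index(tile_reads(s_mut, 46))
  res2 <- resolve_flag(fdm, 1, idx_mut)
  expect_equal(res2$offset_used, 15)

  # no coverage at all: unresolved
  idx_empty <- read_index(tile_reads(rand_dna(200), 46))
  expect_null(resolve_flag(fdm, 1, idx_empty))
})

test_that("BES assembly bridges flags, extends termini, and keeps books", {
  set.seed(61)
  s <- rand_dna(500)
  idx <- read_index(tile_reads(s, 46))
  # FDM covering only the middle of the expressed transcript
  fdm <- make_fdm(list(kind = "seq", seq = substr(s, 101, 300)))
  fdm$trimmed <- TRUE
  bes <- assemble_bes(fdm, idx)
  expect_equal(bes$sequence, s)
  expect_equal(bes$upstream_extension_len, 100L)
  expect_equal(bes$downstream_extension_len, 200L)

  # nothing beyond the termini: extensions are empty
  fdm_full <- make_fdm(list(kind = "seq", seq = s))
  fdm_full$trimmed <- TRUE
  bes2 <- assemble_bes(fdm_full, idx)
  expect_equal(bes2$sequence, s)
  expect_equal(bes2$upstream_extension_len, 0L)
  expect_equal(bes2$downstream_extension_len, 0L)

  # one resolvable and one unresolvable flag
  t <- rand_dna(420)
  reads_t <- tile_reads(t, 46)
  # remove every read that could anchor or span the second flag region
  keep <- !(as.integer(sub("^t", "", reads_t$id)) %in% 255:345)
  idx3 <- read_index(reads_t[keep, ])
  fdm3 <- make_fdm(list(kind = "seq", seq = substr(t, 1, 150)),
                   list(kind = "X"),
                   list(kind = "seq", seq = substr(t, 152, 300)),
                   list(kind = "X"),
                   list(kind = "seq", seq = substr(t, 302, 420)))
  fdm3$trimmed <- TRUE
  bes3 <- assemble_bes(fdm3, idx3)
  expect_equal(nrow(bes3$bridged_flags), 1L)
  expect_equal(nrow(bes3$unresolved_flags), 1L)
  expect_equal(sum(strsplit(bes3$sequence, "")[[1]] == "X"), 1L)
})

test_that("bridged sequence length stays within the budget bound", {
  set.seed(67)
  s <- rand_dna(700)
  idx <- read_index(tile_reads(s, 46))
  r <- bridge_probes(idx, substr(s, 1, 18), substr(s, 451, 468))
  expect_equal(r$status, "end_probe_found")
  expect_lte(nchar(r$sequence), 18 * (27 + 2))
})
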