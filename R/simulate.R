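# Ground-truth fixture generation: synthetic genomes with known multi-exon
# genes, deliberately corrupted predicted models, and reads simulated from
# the TRUE structures -- so the pipeline can be scored against a known
# answer with no external data.

# evaluate with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() treats a scalar first argument as 1:n; these helpers avoid that
sample_range <- function(lo, hi, n = 1) {
  if (lo >= hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}
resample <- function(x, n = 1) x[sample.int(length(x), n)]

#' Configuration of a synthetic truth set
#'
#' Bundles every knob of the fixture generator. The defaults describe a
#' compact fungal-style gene complement: genes of 3-8 exons (mean near five
#' and a half), exons of 60-300 bp with one guaranteed long internal exon,
#' introns of 50-200 bp, 46-nt reads tiled at unit step from the true
#' spliced transcripts, and one structural corruption per gene spread
#' evenly over the five corruption types.
#'
#' @param seed Integer RNG seed; the whole truth set is a deterministic
#'   function of the config.
#' @param n_genes Number of genes (default 20).
#' @param n_scaffolds Number of scaffolds the genes are spread over
#'   (default 4).
#' @param exon_count_range Inclusive range of exons per gene (default 3:8).
#' @param exon_len_range Exon length range in bp (default c(60, 300)).
#' @param long_exon_min Guaranteed minimum length of one internal exon per
#'   gene, the spurious-intron host (default 170).
#' @param intron_len_range Intron length range in bp (default c(50, 200)).
#' @param flank Intergenic flank around every gene in bp (default 300).
#' @param corruption Named numeric rates in `[0, 1]` over
#'   `splice_shift`, `spurious_intron`, `missing_exon`,
#'   `truncated_terminus`, `extended_terminus`; counts are exact
#'   (`rate * n_genes` genes get that corruption). Defaults to 0.2 each.
#' @param splice_shift_bp,spurious_intron_len,truncate_bp,extend_bp
#'   Corruption magnitudes (defaults 4, 80, 15, 15).
#' @param read_len Read length (default 46).
#' @param depth Target mean depth of coverage (default 23, i.e. 500 reads
#'   per kilobase at 46 nt).
#' @param read_error_rate Per-base substitution rate in reads (default 0).
#' @param tiling `"step1"` (every window, deterministic; interior coverage
#'   is `read_len` per pass) or `"random"` (`depth * len / read_len` random
#'   starts per transcript).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1, n_genes = 20, n_scaffolds = 4,
                           exon_count_range = 3:8,
                           exon_len_range = c(60, 300),
                           long_exon_min = 170,
                           intron_len_range = c(50, 200), flank = 300,
                           corruption = c(splice_shift = 0.2,
                                          spurious_intron = 0.2,
                                          missing_exon = 0.2,
                                          truncated_terminus = 0.2,
                                          extended_terminus = 0.2),
                           splice_shift_bp = 4, spurious_intron_len = 80,
                           truncate_bp = 15, extend_bp = 15,
                           read_len = 46, depth = 23, read_error_rate = 0,
                           tiling = c("step1", "random")) {
  tiling <- match.arg(tiling)
  stopifnot(all(corruption >= 0), all(corruption <= 1),
            sum(corruption) <= 1 + 1e-9, depth > 0, read_len >= 2 * 18,
            read_error_rate >= 0, read_error_rate <= 1)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_scaffolds = n_scaffolds,
                 exon_count_range = exon_count_range,
                 exon_len_range = exon_len_range,
                 long_exon_min = long_exon_min,
                 intron_len_range = intron_len_range, flank = flank,
                 corruption = corruption,
                 splice_shift_bp = splice_shift_bp,
                 spurious_intron_len = spurious_intron_len,
                 truncate_bp = truncate_bp, extend_bp = extend_bp,
                 read_len = read_len, depth = depth,
                 read_error_rate = read_error_rate, tiling = tiling),
            class = "fixture_config")
}

# Replace the first and last base of an intron so that the exon/intron
# boundary cannot slide: a junction is positionally ambiguous to any
# sequence-based aligner exactly when the last intron base equals the last
# base of the upstream exon (or the first intron base equals the first base
# of the downstream exon). The fixture removes that ambiguity so "exact
# structure recovery" is well defined.
disambiguate_junctions <- function(seq_chars, exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) < 2) return(seq_chars)
  for (i in seq_len(nrow(exons) - 1L)) {
    a_end <- exons$end[i]       # first intron base index (0-based)
    b_start <- exons$start[i + 1L]
    # 1-based indexing into the char vector
    if (seq_chars[a_end + 1L] == seq_chars[b_start + 1L])
      seq_chars[a_end + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                              seq_chars[b_start + 1L]), 1)
    if (seq_chars[b_start] == seq_chars[a_end])
      seq_chars[b_start] <- sample(setdiff(c("A", "C", "G", "T"),
                                           seq_chars[a_end]), 1)
  }
  seq_chars
}

# Make internal exons distinguishable from their neighbours at the
# boundaries: if an internal exon's first (last) three bases equal the next
# (previous) exon's first (last) three bases, a read spanning the junction
# left by OMITTING that exon matches the merged neighbour junction exactly,
# and the omission becomes undetectable in principle. The guard edits the
# internal exon's third boundary base. Conditions are enforced in scaffold
# space on both sides, which covers both strands by symmetry.
guard_internal_exons <- function(seq_chars, exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  if (n < 3) return(seq_chars)
  pick_other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  for (i in 2:(n - 1)) {
    bs <- exons$start[i]; be <- exons$end[i]
    cs <- exons$start[i + 1]
    ae <- exons$end[i - 1]
    if (all(seq_chars[bs + 1:3] == seq_chars[cs + 1:3]))
      seq_chars[bs + 3L] <- pick_other(seq_chars[cs + 3L])
    if (all(seq_chars[(be - 2L):be] == seq_chars[(ae - 2L):ae]))
      seq_chars[be - 2L] <- pick_other(seq_chars[ae - 2L])
  }
  seq_chars
}

#' Generate a synthetic truth set
#'
#' Deterministically (given the config seed) lays out non-overlapping
#' multi-exon genes on random scaffolds, then derives a corrupted "predicted"
#' model set by applying the configured structural corruptions to the true
#' models. Reads are later simulated from the TRUE structures while the
#' pipeline only sees the corrupted models — the heart of every end-to-end
#' test. Splice junctions are generated positionally unambiguous (see the
#' package vignette), so exact recovery is a well-posed target.
#'
#' @param config A [fixture_config()].
#' @return A `truth_set`: `genome` (sequence tibble), `true_models`,
#'   `corrupted_models` (gene-model tibbles), `ledger` (per-gene corruption
#'   record), and the config.
#' @export
generate_truth_set <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    # per-gene structures
    genes <- vector("list", n)
    for (g in seq_len(n)) {
      n_ex <- resample(config$exon_count_range)
      lens <- sample_range(config$exon_len_range[1],
                           config$exon_len_range[2], n_ex)
      if (n_ex >= 3) {
        host <- 2L  # guaranteed spurious-intron host
        lens[host] <- sample_range(
          max(config$long_exon_min, config$exon_len_range[1]),
          max(config$long_exon_min, config$exon_len_range[2]))
      }
      introns <- if (n_ex > 1)
        sample_range(config$intron_len_range[1],
                     config$intron_len_range[2], n_ex - 1L) else integer(0)
      strand <- sample(c("+", "-"), 1)
      genes[[g]] <- list(exon_lens = lens, intron_lens = introns,
                         strand = strand)
    }
    # placement: round-robin over scaffolds, flank bp on each side
    scaffold_of <- rep_len(seq_len(config$n_scaffolds), n)
    cursor <- rep(config$flank, config$n_scaffolds)
    rows <- list()
    for (g in seq_len(n)) {
      sc <- scaffold_of[g]
      s0 <- cursor[sc]
      starts <- s0 + cumsum(c(0L, head(genes[[g]]$exon_lens, -1) +
                                genes[[g]]$intron_lens))
      ends <- starts + genes[[g]]$exon_lens
      rows[[g]] <- tibble(gene_id = sprintf("gene%03d", g),
                          scaffold_id = sprintf("scaffold%02d", sc),
                          strand = genes[[g]]$strand,
                          exon_rank = seq_along(starts),
                          start = as.integer(starts),
                          end = as.integer(ends))
      cursor[sc] <- max(ends) + 2L * config$flank
    }
    true_models <- bind_rows(rows)
    scaff_len <- vapply(seq_len(config$n_scaffolds), function(sc)
      cursor[sc] + config$flank, numeric(1))
    genome <- tibble(id = sprintf("scaffold%02d",
                                  seq_len(config$n_scaffolds)),
                     seq = vapply(scaff_len, random_dna, character(1)))
    # unambiguous junctions
    for (sc in seq_len(config$n_scaffolds)) {
      chars <- strsplit(genome$seq[sc], "", fixed = TRUE)[[1]]
      for (gid in unique(true_models$gene_id[
        true_models$scaffold_id == genome$id[sc]])) {
        gx <- true_models[true_models$gene_id == gid, , drop = FALSE]
        chars <- disambiguate_junctions(chars, gx)
        chars <- guard_internal_exons(chars, gx)
      }
      genome$seq[sc] <- paste(chars, collapse = "")
    }
    # corruption assignment: exact counts, shuffled over genes; rounding of
    # fractional rate * n is trimmed so the total never exceeds n
    counts <- round(config$corruption * n)
    while (sum(counts) > n) {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
    }
    kinds <- c(rep(names(counts), counts),
               rep("none", n - sum(counts)))
    kinds <- sample(kinds, n)
    corrupted <- list(); ledger <- list()
    for (g in seq_len(n)) {
      gid <- sprintf("gene%03d", g)
      m <- true_models[true_models$gene_id == gid, , drop = FALSE]
      m <- m[order(m$exon_rank), , drop = FALSE]
      kind <- kinds[g]
      detail <- ""
      if (kind == "splice_shift") {
        ok <- which((m$start[-1] - m$end[-nrow(m)]) >
                      config$splice_shift_bp + 10L)
        j <- if (length(ok)) ok[sample.int(length(ok), 1)] else NA
        if (is.na(j)) kind <- "none" else {
          m$end[j] <- m$end[j] + config$splice_shift_bp
          detail <- sprintf("intron %d donor shifted +%d bp", j,
                            config$splice_shift_bp)
        }
      } else if (kind == "spurious_intron") {
        w <- m$end - m$start
        host <- which.max(w)
        il <- config$spurious_intron_len
        if (w[host] < il + 40L) kind <- "none" else {
          w1 <- (w[host] - il) %/% 2L
          # the carved-out segment must not mimic the flanking sequence at
          # the new junction (same reasoning as guard_internal_exons, with
          # the carved segment in the role of the omitted exon)
          sc <- which(genome$id == m$scaffold_id[1])
          gch <- strsplit(genome$seq[sc], "", fixed = TRUE)[[1]]
          cut <- m$start[host] + w1        # 0-based cut position
          pick_other <- function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          if (all(gch[cut + 1:3] == gch[cut + il + 1:3]))
            gch[cut + 3L] <- pick_other(gch[cut + il + 3L])
          if (all(gch[(cut + il - 2L):(cut + il)] ==
                    gch[(cut - 2L):cut]))
            gch[cut + il - 2L] <- pick_other(gch[cut - 2L])
          genome$seq[sc] <- paste(gch, collapse = "")
          new1 <- m[host, ]; new2 <- m[host, ]
          new1$end <- m$start[host] + w1
          new2$start <- m$start[host] + w1 + il
          m <- bind_rows(m[seq_len(host - 1L), ], new1, new2,
                         m[setdiff(seq_len(nrow(m)), seq_len(host)), ])
          m$exon_rank <- seq_len(nrow(m))
          detail <- sprintf("spurious %d bp intron inside exon %d", il, host)
        }
      } else if (kind == "missing_exon") {
        if (nrow(m) < 3) kind <- "none" else {
          drop <- resample(2:(nrow(m) - 1L))
          detail <- sprintf("internal exon %d (%d bp) omitted", drop,
                            m$end[drop] - m$start[drop])
          m <- m[-drop, , drop = FALSE]
          m$exon_rank <- seq_len(nrow(m))
        }
      } else if (kind == "truncated_terminus") {
        which_end <- sample(c("left", "right"), 1)
        bp <- config$truncate_bp
        if (which_end == "left") {
          m$start[1] <- m$start[1] + bp
        } else {
          m$end[nrow(m)] <- m$end[nrow(m)] - bp
        }
        detail <- sprintf("%s terminus clipped %d bp", which_end, bp)
      } else if (kind == "extended_terminus") {
        which_end <- sample(c("left", "right"), 1)
        bp <- config$extend_bp
        if (which_end == "left") {
          m$start[1] <- m$start[1] - bp
        } else {
          m$end[nrow(m)] <- m$end[nrow(m)] + bp
        }
        detail <- sprintf("%s terminus extended %d bp into flank",
                          which_end, bp)
      }
      corrupted[[g]] <- m
      ledger[[g]] <- tibble(gene_id = gid, corruption = kind,
                            detail = detail)
    }
    out <- list(genome = genome, true_models = true_models,
                corrupted_models = bind_rows(corrupted),
                ledger = bind_rows(ledger), config = config)
    validate_gene_models(out$true_models, out$genome)
    validate_gene_models(out$corrupted_models, out$genome)
    structure(out, class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>", length(unique(x$true_models$gene_id)), "genes on",
      nrow(x$genome), "scaffolds (seed", x$config$seed, ")\n")
  print(table(x$ledger$corruption))
  invisible(x)
}

#' Simulate fixed-length reads from the true transcripts
#'
#' Reads are drawn from the TRUE spliced transcripts, in both orientations.
#' `step1` tiling emits every transcript window at unit step,
#' `max(1, ceiling(depth / read_len))` times, alternating orientation —
#' deterministic, with interior coverage of `read_len` per pass. `random`
#' mode draws `round(depth * len / read_len)` uniform start positions per
#' transcript (so expression lands at `depth * 1000 / read_len` reads per
#' kilobase). Substitution errors are applied at `read_error_rate`.
#'
#' @param truth A `truth_set`.
#' @param config Defaults to `truth$config`.
#' @return Read tibble (`id`, `seq`). Transcripts shorter than the read
#'   length are skipped with a warning.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  tx <- transcript_sequences(truth$true_models, truth$genome)
  read_len <- config$read_len
  with_seed(config$seed + 1L, {
    out <- vector("list", nrow(tx))
    for (i in seq_len(nrow(tx))) {
      s <- tx$seq[i]
      L <- nchar(s)
      if (L < read_len) {
        warn(paste0("transcript '", tx$id[i],
                    "' shorter than the read length; skipped"))
        next
      }
      if (config$tiling == "step1") {
        copies <- max(1L, as.integer(ceiling(config$depth / read_len)))
        starts <- rep(0:(L - read_len), copies)
        orient <- rep_len(c("+", "-"), length(starts))
      } else {
        n_reads <- max(1L, round(config$depth * L / read_len))
        starts <- sample(0:(L - read_len), n_reads, replace = TRUE)
        orient <- sample(c("+", "-"), n_reads, replace = TRUE)
      }
      reads <- substring(s, starts + 1L, starts + read_len)
      flip <- orient == "-"
      if (any(flip)) reads[flip] <- reverse_complement(reads[flip])
      if (config$read_error_rate > 0) {
        for (r in seq_along(reads)) {
          hits <- which(stats::runif(read_len) < config$read_error_rate)
          if (length(hits)) {
            ch <- strsplit(reads[r], "", fixed = TRUE)[[1]]
            for (h in hits)
              ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
            reads[r] <- paste(ch, collapse = "")
          }
        }
      }
      out[[i]] <- tibble(
        id = sprintf("%s_r%05d", tx$id[i], seq_along(reads)),
        seq = reads)
    }
    bind_rows(out)
  })
}

#' Three-exon gene series with the middle exon omitted from the prediction
#'
#' The short-exon recovery benchmark: one gene per middle-exon length, with
#' fixed flanking exons and introns, a predicted model that merges the two
#' introns over the missing middle exon, and error-free step-1 tiled reads
#' from the true transcripts. Junctions are generated positionally
#' unambiguous, like every fixture in the package.
#'
#' @param mid_lens Middle-exon lengths to scan (default 3:30).
#' @param flank_exon Flanking exon length (default 200).
#' @param intron Intron length (default 80).
#' @param flank Intergenic flank (default 300).
#' @param read_len,depth Read parameters (defaults 46 and 23).
#' @param seed RNG seed.
#' @return A `truth_set` whose `ledger` records the middle-exon length per
#'   gene.
#' @export
exon_series_fixture <- function(mid_lens = 3:30, flank_exon = 200,
                                intron = 80, flank = 300, read_len = 46,
                                depth = 23, seed = 1) {
  with_seed(seed, {
    rows_true <- list(); rows_pred <- list(); ledger <- list()
    genome <- list()
    for (i in seq_along(mid_lens)) {
      m <- mid_lens[i]
      gid <- sprintf("series%03d", m)
      sid <- sprintf("sscaf%03d", m)
      starts <- flank + cumsum(c(0L, flank_exon + intron, m + intron))
      ends <- starts + c(flank_exon, m, flank_exon)
      tm <- tibble(gene_id = gid, scaffold_id = sid, strand = "+",
                   exon_rank = 1:3, start = as.integer(starts),
                   end = as.integer(ends))
      slen <- max(ends) + flank
      chars <- strsplit(random_dna(slen), "", fixed = TRUE)[[1]]
      chars <- disambiguate_junctions(chars, tm)
      chars <- guard_internal_exons(chars, tm)
      genome[[i]] <- tibble(id = sid, seq = paste(chars, collapse = ""))
      rows_true[[i]] <- tm
      pm <- tm[c(1, 3), , drop = FALSE]
      pm$exon_rank <- 1:2
      rows_pred[[i]] <- pm
      ledger[[i]] <- tibble(gene_id = gid, corruption = "missing_exon",
                            detail = sprintf("middle exon %d bp omitted", m))
    }
    config <- fixture_config(seed = seed, n_genes = length(mid_lens),
                             n_scaffolds = length(mid_lens),
                             read_len = read_len, depth = depth,
                             tiling = "step1")
    structure(list(genome = bind_rows(genome),
                   true_models = bind_rows(rows_true),
                   corrupted_models = bind_rows(rows_pred),
                   ledger = bind_rows(ledger), config = config),
              class = "truth_set")
  })
}

#' Write a truth set to disk
#'
#' Emits `genome.fa`, `true.gff3`, `predicted.gff3`, `reads.fastq`, and
#' `ledger.tsv` under `dir`.
#'
#' @param truth A `truth_set`.
#' @param dir Output directory (created if needed).
#' @param reads Optional read tibble; simulated from the truth set when
#'   omitted.
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(truth, dir, reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sequences(truth$genome, file.path(dir, "genome.fa"))
  write_gene_models(truth$true_models, file.path(dir, "true.gff3"))
  write_gene_models(truth$corrupted_models, file.path(dir,
                                                      "predicted.gff3"))
  if (is.null(reads)) reads <- simulate_reads(truth)
  write_sequences(reads, file.path(dir, "reads.fastq"), format = "fastq")
  write.table(truth$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
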