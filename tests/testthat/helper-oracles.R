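# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation they check.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# every placement of every read (both orientations) by direct sliding scan
oracle_align <- function(reads, refs, max_mm) {
  out <- list()
  for (ri in seq_len(nrow(refs))) {
    ref <- strsplit(refs$seq[ri], "", fixed = TRUE)[[1]]
    for (qi in seq_len(nrow(reads))) {
      for (orient in c("+", "-")) {
        s <- if (orient == "+") reads$seq[qi] else rc_chr(reads$seq[qi])
        q <- strsplit(s, "", fixed = TRUE)[[1]]
        L <- length(q)
        if (L > length(ref)) next
        for (p in 0:(length(ref) - L)) {
          mm <- sum(q != ref[(p + 1):(p + L)])
          if (mm <= max_mm)
            out[[length(out) + 1]] <- data.frame(
              read_id = reads$id[qi], ref_id = refs$id[ri], offset = p,
              orientation = orient, mismatches = mm)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(read_id = character(), ref_id = character(),
                      offset = integer(), orientation = character(),
                      mismatches = integer()))
  do.call(rbind, out)
}

# strict-majority consensus following a probe, by direct tally
oracle_next_probe <- function(reads, probe, k = 18) {
  tally <- matrix(0L, nrow = 4, ncol = k,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  seqs <- c(reads$seq, vapply(reads$seq, rc_chr, character(1)))
  for (s in seqs) {
    hits <- gregexpr(probe, s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    for (h in hits) {
      after <- substr(s, h + k, min(nchar(s), h + 2 * k - 1))
      ch <- strsplit(after, "", fixed = TRUE)[[1]]
      for (p in seq_along(ch))
        if (ch[p] %in% rownames(tally))
          tally[ch[p], p] <- tally[ch[p], p] + 1L
    }
  }
  out <- rep("N", k)
  for (p in seq_len(k)) {
    tot <- sum(tally[, p])
    if (tot > 0 && max(tally[, p]) * 2 > tot)
      out[p] <- rownames(tally)[which.max(tally[, p])]
  }
  paste(out, collapse = "")
}

# exhaustive enumeration of constrained spliced alignments (tiny strings)
oracle_spliced_score <- function(b, w, match = 8, mismatch = -12,
                                 n_match = 4, gap_scaffold = -24,
                                 gap_bes = -1, min_block = 4) {
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  wc <- strsplit(w, "", fixed = TRUE)[[1]]
  m <- length(bc); n <- length(wc)
  best <- -Inf
  rec <- function(i, j, run, score) {
    if (i == m) {
      if (run == 0 || run >= min_block) best <<- max(best, score)
      return(invisible(NULL))
    }
    if (j < n) {
      s <- if (bc[i + 1] == "N" || wc[j + 1] == "N") n_match
      else if (bc[i + 1] == wc[j + 1]) match else mismatch
      rec(i + 1, j + 1, run + 1, score + s)
    }
    if (run == 0 || run >= min_block) {
      rec(i + 1, j, 0, score + gap_scaffold)
      if (j < n)
        rec(i, j + 1, 0, score + if (i == 0) 0 else gap_bes)
    }
  }
  rec(0, 0, 0, 0)
  best
}

# cumulative binomial by direct summation
oracle_cbd <- function(x, n, p) {
  sum(vapply(0:x, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# step-1 tiled reads (forward orientation only, for controlled fixtures)
tile_reads <- function(seq, read_len = 46, prefix = "t") {
  L <- nchar(seq)
  starts <- 0:(L - read_len)
  tibble::tibble(id = sprintf("%s%04d", prefix, starts),
                 seq = substring(seq, starts + 1, starts + read_len))
}

# random valid gene-model table for round-trip properties
random_models <- function(n_genes = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genes)) {
    n_ex <- sample(1:5, 1)
    pos <- 0L
    starts <- integer(0); ends <- integer(0)
    for (e in seq_len(n_ex)) {
      pos <- pos + sample(1:50, 1)          # intron / leading gap >= 1
      w <- sample(1:80, 1)
      starts <- c(starts, pos); ends <- c(ends, pos + w)
      pos <- pos + w
    }
    rows[[g]] <- tibble::tibble(
      gene_id = sprintf("g%02d", g), scaffold_id = "s1",
      strand = sample(c("+", "-"), 1), exon_rank = seq_len(n_ex),
      start = starts, end = ends)
  }
  dplyr::bind_rows(rows)
}

# a single-gene toy fixture: handcrafted scaffold + model table
toy_gene <- function(exon_lens, intron_lens, strand = "+", flank = 60,
                     seed = 42, gene_id = "toy1", scaffold_id = "toyscaf") {
  set.seed(seed)
  starts <- flank + cumsum(c(0L, head(exon_lens, -1) + intron_lens))
  ends <- starts + exon_lens
  slen <- max(ends) + flank
  model <- tibble::tibble(gene_id = gene_id, scaffold_id = scaffold_id,
                          strand = strand, exon_rank = seq_along(starts),
                          start = as.integer(starts), end = as.integer(ends))
  chars <- strsplit(rand_dna(slen), "", fixed = TRUE)[[1]]
  chars <- rnarefine:::disambiguate_junctions(chars, model)
  genome <- tibble::tibble(id = scaffold_id, seq = paste(chars,
                                                         collapse = ""))
  list(genome = genome, model = model)
}

# assemble a synthetic fdm_seq object from (kind, seq) pairs for testing the
# post-processing rules in isolation
make_fdm <- function(..., gene_id = "fake", strand = "+") {
  pieces <- list(...)
  pos <- 0L
  seg <- lapply(pieces, function(p) {
    w <- if (p$kind == "X") p$width %||% 1L else nchar(p$seq)
    row <- tibble::tibble(kind = p$kind,
                          seq = if (p$kind == "X") NA_character_ else p$seq,
                          tx_start = pos, tx_end = pos + w,
                          anchor_start = pos, anchor_end = pos + w)
    pos <<- pos + w
    row
  })
  structure(list(gene_id = gene_id, scaffold_id = "fakescaf",
                 strand = strand, threshold = 2,
                 segments = dplyr::bind_rows(seg), e_start = FALSE,
                 e_end = FALSE, e_start_len = 0L, e_end_len = 0L,
                 trimmed = FALSE, model = NULL),
            class = "fdm_seq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seg_kinds <- function(fdm) fdm$segments$kind

exact_match <- function(truth_models, recovered, gene) {
  a <- truth_models[truth_models$gene_id == gene, , drop = FALSE]
  b <- recovered[recovered$gene_id == gene, , drop = FALSE]
  nrow(a) == nrow(b) && identical(a$start, b$start) &&
    identical(a$end, b$end) && all(a$strand == b$strand)
}
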