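#' Ungapped alignment of fixed-length reads to reference sequences
#'
#' A deterministic, quality-blind stand-in for a short-read aligner: every
#' placement of every read (and its reverse complement) on every reference
#' with Hamming distance at most `max_mismatch` is reported, multi-mappers
#' included. Reads longer than a reference simply produce no placements
#' there.
#'
#' @param reads Tibble with columns `id`, `seq`; all reads the same length.
#' @param refs Tibble with columns `id`, `seq` (genome scaffolds or spliced
#'   transcripts).
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return Tibble with columns `read_id`, `ref_id`, `offset` (0-based start on
#'   the reference), `orientation` (`+`/`-`), `mismatches`.
#' @export
align_ungapped <- function(reads, refs, max_mismatch = 2) {
  stopifnot(max_mismatch >= 0)
  empty <- tibble(read_id = character(), ref_id = character(),
                  offset = integer(), orientation = character(),
                  mismatches = integer())
  if (nrow(reads) == 0 || nrow(refs) == 0) return(empty)
  lens <- unique(nchar(reads$seq))
  if (length(lens) != 1L)
    abort("reads must all have the same length")
  reads_rc <- reverse_complement(reads$seq)
  out <- lapply(seq_len(nrow(refs)), function(i) {
    hits <- cpp_align_hamming(reads$seq, reads_rc, refs$seq[i],
                              as.integer(max_mismatch))
    if (nrow(hits) == 0) return(NULL)
    tibble(read_id = reads$id[hits$read],
           ref_id = refs$id[i],
           offset = as.integer(hits$offset),
           orientation = c("+", "-")[hits$orient + 1L],
           mismatches = as.integer(hits$mismatches))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' Import ungapped read alignments from SAM
#'
#' Alternative front end to [align_ungapped()] so that alignments produced by
#' a production aligner can be substituted at scale. Only mapped, ungapped
#' records (CIGAR a single `M` run) are converted; everything else is
#' dropped. Requires the Rsamtools package.
#'
#' @param path SAM/BAM file path.
#' @return Alignment tibble in the [align_ungapped()] layout (`mismatches` is
#'   taken from the `NM` tag when present, otherwise 0).
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    abort("read_alignments_sam() requires the Rsamtools package")
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE) else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- grepl("^[0-9]+M$", x$cigar)
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(x$qname))
  nm[is.na(nm)] <- 0L
  tibble(read_id = x$qname[keep],
         ref_id = as.character(x$rname)[keep],
         offset = x$pos[keep] - 1L,
         orientation = as.character(x$strand)[keep],
         mismatches = as.integer(nm[keep]))
}

#' Partition read alignments into the three evidence sets
#'
#' Set 1 holds the alignments to genomic sequence; Set 3 the alignments to
#' spliced gene-model transcripts; Set 2 restricts Set 3 to reads with zero
#' genome alignments — the reads whose only explanation is a splice junction.
#'
#' @param genome_alns Alignment tibble against the genome.
#' @param model_alns Alignment tibble against model transcripts, produced
#'   from the same read set.
#' @return An `alignment_sets` object (list with `set1`, `set2`, `set3`).
#' @export
partition_alignment_sets <- function(genome_alns, model_alns) {
  genome_reads <- unique(genome_alns$read_id)
  set2 <- model_alns |> filter(!.data$read_id %in% genome_reads)
  stopifnot(length(intersect(unique(set2$read_id), genome_reads)) == 0)
  structure(list(set1 = genome_alns, set2 = set2, set3 = model_alns),
            class = "alignment_sets")
}

#' @export
print.alignment_sets <- function(x, ...) {
  cat("<alignment_sets>\n")
  cat("  Set 1 (genome):            ", nrow(x$set1), "alignments,",
      length(unique(x$set1$read_id)), "reads\n")
  cat("  Set 2 (junction evidence): ", nrow(x$set2), "alignments,",
      length(unique(x$set2$read_id)), "reads\n")
  cat("  Set 3 (transcripts):       ", nrow(x$set3), "alignments,",
      length(unique(x$set3$read_id)), "reads\n")
  invisible(x)
}

#' Per-base and per-junction coverage profile of one gene model
#'
#' Builds the evidence profile the deviation-flagging step consumes:
#' `genome_align` counts Set-1 alignment bases at every scaffold position of
#' the gene's span; `border_align` projects each Set-2 alignment to this
#' model through the exon map onto scaffold positions; `junction_support`
#' counts the Set-2 alignments that cross each predicted intron's junction
#' with at least `min_overhang` bases on both sides.
#'
#' @param model Exon tibble of a single gene.
#' @param sets An `alignment_sets` object.
#' @param read_len Read length used in the alignments.
#' @param min_overhang Minimum bases on each side of a junction for a read to
#'   count as spanning it (default 3, tolerating slight overhangs across an
#'   intron-exon boundary).
#' @param junction_max_mismatch Maximum mismatches allowed in an alignment
#'   counted as junction support (default 0). Junction evidence must be
#'   unambiguous: a read overhanging a wrong junction by a few bases can
#'   still pass a lenient whole-read mismatch budget, so mismatch-tolerant
#'   support would let spurious introns masquerade as confirmed.
#' @return A `coverage_profile` object.
#' @export
coverage_profile <- function(model, sets, read_len, min_overhang = 3,
                             junction_max_mismatch = 0) {
  stopifnot(inherits(sets, "alignment_sets"))
  model <- model[order(model$exon_rank), , drop = FALSE]
  gene_id <- model$gene_id[1]
  scaffold_id <- model$scaffold_id[1]
  strand <- model$strand[1]
  span_start <- min(model$start)
  span_end <- max(model$end)
  span_w <- span_end - span_start
  tmap <- transcript_map(model)
  tx_len <- length(tmap)

  genome_align <- integer(span_w)
  g <- sets$set1 |> filter(.data$ref_id == scaffold_id)
  if (nrow(g) > 0) {
    ir <- IRanges::IRanges(start = g$offset + 1L, width = read_len)
    cov <- IRanges::coverage(ir, width = max(span_end, max(g$offset) +
                                               read_len))
    genome_align <- as.integer(S4Vectors::window(cov, span_start + 1L,
                                                 span_end))
  }

  border_align <- integer(span_w)
  b <- sets$set2 |> filter(.data$ref_id == gene_id)
  if (nrow(b) > 0) {
    if (any(b$offset < 0L) || any(b$offset + read_len > tx_len))
      abort(paste0("Set-2 alignment projects outside the span of model '",
                   gene_id, "'"))
    ir <- IRanges::IRanges(start = b$offset + 1L, width = read_len)
    tx_cov <- as.integer(IRanges::coverage(ir, width = tx_len))
    # scatter transcript coverage onto scaffold positions
    idx <- tmap - span_start + 1L
    border_align[idx] <- border_align[idx] + tx_cov
  }

  # introns in transcript order, with junction transcript coordinates
  ex <- model
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  widths <- ex$end - ex$start
  junctions <- tibble(tx_index = integer(), junction_pos = integer(),
                      intron_start = integer(), intron_end = integer(),
                      support = integer())
  if (nrow(ex) > 1) {
    jpos <- cumsum(widths)[-nrow(ex)]
    if (strand == "+") {
      intron_start <- ex$end[-nrow(ex)]
      intron_end <- ex$start[-1]
    } else {
      intron_start <- ex$start[-nrow(ex)]
      intron_end <- ex$end[-1]
      tmp <- intron_start
      intron_start <- intron_end
      intron_end <- tmp
    }
    bj <- b[b$mismatches <= junction_max_mismatch, , drop = FALSE]
    support <- vapply(jpos, function(cj) {
      if (nrow(bj) == 0) return(0L)
      sum(bj$offset + min_overhang <= cj &
            bj$offset + read_len - min_overhang >= cj)
    }, integer(1))
    junctions <- tibble(tx_index = seq_along(jpos), junction_pos = jpos,
                        intron_start = intron_start, intron_end = intron_end,
                        support = as.integer(support))
  }

  structure(list(gene_id = gene_id, scaffold_id = scaffold_id,
                 strand = strand, span_start = span_start,
                 span_end = span_end, genome_align = genome_align,
                 border_align = border_align, junctions = junctions,
                 read_len = read_len, min_overhang = min_overhang,
                 model = model),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> gene", x$gene_id, "on", x$scaffold_id,
      paste0("(", x$strand, ")"), "span",
      paste0("[", x$span_start, ",", x$span_end, ")"), "\n")
  cat("  genome_align: total", sum(x$genome_align), "bases;",
      "border_align: total", sum(x$border_align), "bases\n")
  if (nrow(x$junctions))
    cat("  junction support:", paste(x$junctions$support, collapse = ", "),
        "\n")
  invisible(x)
}

#' Tidy a coverage profile into a per-position tibble
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return Tibble with `scaffold_pos`, `genome_align`, `border_align`,
#'   `exonic`.
#' @method tidy coverage_profile
#' @export
tidy.coverage_profile <- function(x, ...) {
  pos <- seq.int(x$span_start, x$span_end - 1L)
  exonic <- logical(length(pos))
  for (i in seq_len(nrow(x$model))) {
    exonic[pos >= x$model$start[i] & pos < x$model$end[i]] <- TRUE
  }
  tibble(scaffold_pos = pos, genome_align = x$genome_align,
         border_align = x$border_align, exonic = exonic)
}

#' Expression summary of one gene model
#'
#' Reads-per-kilobase (RPK) of model transcript length from Set-3 alignment
#' counts, plus the implied mean depth of coverage
#' `rpk * read_len / 1000`. With 46-nt reads, 500 RPK corresponds to a mean
#' depth of 23 and 60 RPK to a mean depth of about 3.
#'
#' @param model Exon tibble of a single gene.
#' @param sets An `alignment_sets` object.
#' @param read_len Read length.
#' @return Tibble with `gene_id`, `aligned_read_count`, `rpk`, `mean_depth`.
#' @export
compute_expression <- function(model, sets, read_len) {
  stopifnot(read_len > 0)
  gene_id <- model$gene_id[1]
  tx_len <- sum(model$end - model$start)
  if (tx_len <= 0) abort(paste0("model '", gene_id, "' has zero length"))
  n <- sum(sets$set3$ref_id == gene_id)
  rpk <- n / (tx_len / 1000)
  tibble(gene_id = gene_id, aligned_read_count = n, rpk = rpk,
         mean_depth = rpk * read_len / 1000)
}
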