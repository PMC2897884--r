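#' Build the flagged-deviations sequence of a gene model
#'
#' Walks the model's transcript positions in 5'->3' order and emits the
#' scaffold base (complemented for minus-strand genes) wherever the combined
#' per-base evidence `genome_align + border_align` reaches `threshold`, and
#' the flag character `X` where it does not. Additionally, every predicted
#' intron whose junction has fewer than `threshold` spanning reads receives
#' an `X` flag at the junction, so a spurious intron flanked by well-covered
#' exons is still flagged. The result records, segment by segment, where
#' each piece anchors on the scaffold.
#'
#' @param model Exon tibble of a single gene.
#' @param profile [coverage_profile()] of the same gene.
#' @param scaffold Single-row sequence tibble (or list with `id`, `seq`)
#'   holding the gene's scaffold.
#' @param threshold Minimum read alignments to call a position expressed
#'   (default 2).
#' @return An `fdm_seq` object: ordered segments of expressed sequence and
#'   `X` flags with scaffold anchors, before post-processing (see
#'   [merge_and_trim_flags()]).
#' @export
build_fdm <- function(model, profile, scaffold, threshold = 2) {
  stopifnot(inherits(profile, "coverage_profile"), threshold >= 1)
  model <- model[order(model$exon_rank), , drop = FALSE]
  if (model$gene_id[1] != profile$gene_id)
    abort("model and profile describe different genes")
  if (scaffold$id[1] != model$scaffold_id[1])
    abort(paste0("scaffold id mismatch for gene '", model$gene_id[1], "'"))
  if (max(model$end) > nchar(scaffold$seq[1]))
    abort(paste0("model '", model$gene_id[1], "' exceeds scaffold bounds"))
  strand <- model$strand[1]
  tmap <- transcript_map(model)            # tx pos -> scaffold pos
  base <- substring(scaffold$seq[1], tmap + 1L, tmap + 1L)
  if (strand == "-") base <- chartr("ACGTN", "TGCAN", base)
  cov <- profile$genome_align + profile$border_align
  ok <- cov[tmap - profile$span_start + 1L] >= threshold

  # junction flags, keyed by the transcript position before which they sit
  jx <- profile$junctions
  flag_before <- if (nrow(jx)) jx$junction_pos[jx$support < threshold]
    else integer(0)

  segments <- list()
  emit <- function(kind, seq, tx_start, tx_end, a_start, a_end) {
    segments[[length(segments) + 1L]] <<- tibble(
      kind = kind, seq = seq, tx_start = tx_start, tx_end = tx_end,
      anchor_start = a_start, anchor_end = a_end)
  }
  runs <- rle(ok)
  tx0 <- 0L
  # split per-bp runs further at junction-flag positions so junction X
  # segments can be interleaved at exactly the junction coordinate
  bounds <- sort(unique(c(0L, cumsum(runs$lengths), flag_before,
                          if (nrow(jx)) jx$junction_pos else integer(0))))
  for (bi in seq_len(length(bounds) - 1L)) {
    t1 <- bounds[bi]; t2 <- bounds[bi + 1L]
    if (t1 %in% flag_before) {
      j <- jx[jx$junction_pos == t1, , drop = FALSE][1, ]
      emit("X", NA_character_, t1, t1, j$intron_start, j$intron_end)
    }
    span <- tmap[(t1 + 1L):t2]
    a1 <- min(span); a2 <- max(span) + 1L
    if (ok[t1 + 1L]) {
      emit("seq", paste(base[(t1 + 1L):t2], collapse = ""), t1, t2, a1, a2)
    } else {
      emit("X", NA_character_, t1, t2, a1, a2)
    }
  }
  tx_len <- length(tmap)
  if (tx_len %in% flag_before) {
    j <- jx[jx$junction_pos == tx_len, , drop = FALSE][1, ]
    emit("X", NA_character_, tx_len, tx_len, j$intron_start, j$intron_end)
  }
  structure(list(gene_id = model$gene_id[1],
                 scaffold_id = model$scaffold_id[1], strand = strand,
                 threshold = threshold, segments = bind_rows(segments),
                 e_start = FALSE, e_end = FALSE,
                 e_start_len = 0L, e_end_len = 0L,
                 trimmed = FALSE, model = model),
            class = "fdm_seq")
}

#' Post-process the flags of an FDM sequence
#'
#' Applies the three clean-up rules that make flags bridgeable: contiguous
#' flags collapse into a single flag; expressed segments shorter than
#' `min_segment` caught between two flags are absorbed into one flag (too
#' short to host an anchoring probe on each side); and flags at the sequence
#' termini are noted as terminal (`E`) deviations and removed from the
#' working sequence, to be handled by terminus extension instead of
#' bridging.
#'
#' @param fdm An `fdm_seq` from [build_fdm()].
#' @param min_segment Minimum expressed-segment length retained between two
#'   flags (default 36 = two probe lengths).
#' @return The post-processed `fdm_seq` (`trimmed = TRUE`, terminal-flag
#'   bookkeeping filled in).
#' @export
merge_and_trim_flags <- function(fdm, min_segment = 36) {
  stopifnot(inherits(fdm, "fdm_seq"))
  seg <- fdm$segments
  merge_pass <- function(seg) {
    # collapse adjacent X segments
    if (nrow(seg) > 1) {
      keep <- rep(TRUE, nrow(seg))
      for (i in 2:nrow(seg)) {
        if (seg$kind[i] == "X" && seg$kind[i - 1L] == "X" && keep[i - 1L]) {
          seg$tx_start[i] <- seg$tx_start[i - 1L]
          seg$anchor_start[i] <- min(seg$anchor_start[i - 1L],
                                     seg$anchor_start[i])
          seg$anchor_end[i] <- max(seg$anchor_end[i - 1L], seg$anchor_end[i])
          keep[i - 1L] <- FALSE
        }
      }
      seg <- seg[keep, , drop = FALSE]
    }
    seg
  }
  absorb_pass <- function(seg) {
    if (nrow(seg) < 3) return(seg)
    short <- seg$kind == "seq" &
      nchar(ifelse(is.na(seg$seq), "", seg$seq)) < min_segment
    inner <- seq_len(nrow(seg)) > 1 & seq_len(nrow(seg)) < nrow(seg)
    flanked <- rep(FALSE, nrow(seg))
    flanked[inner] <- seg$kind[which(inner) - 1L] == "X" &
      seg$kind[which(inner) + 1L] == "X"
    hit <- which(short & flanked)
    if (length(hit) == 0) return(seg)
    i <- hit[1]
    seg$kind[i] <- "X"
    seg$seq[i] <- NA_character_
    merge_pass(seg)
  }
  repeat {
    before <- nrow(seg)
    seg <- merge_pass(seg)
    seg <- absorb_pass(seg)
    if (nrow(seg) == before) break
  }
  e_start <- FALSE; e_end <- FALSE
  e_start_len <- fdm$e_start_len; e_end_len <- fdm$e_end_len
  if (nrow(seg) > 0 && seg$kind[1] == "X") {
    e_start <- TRUE
    e_start_len <- e_start_len + (seg$tx_end[1] - seg$tx_start[1])
    seg <- seg[-1, , drop = FALSE]
  }
  if (nrow(seg) > 0 && seg$kind[nrow(seg)] == "X") {
    e_end <- TRUE
    e_end_len <- e_end_len +
      (seg$tx_end[nrow(seg)] - seg$tx_start[nrow(seg)])
    seg <- seg[-nrow(seg), , drop = FALSE]
  }
  out <- fdm
  out$segments <- seg
  out$e_start <- e_start || fdm$e_start
  out$e_end <- e_end || fdm$e_end
  out$e_start_len <- e_start_len
  out$e_end_len <- e_end_len
  out$trimmed <- TRUE
  out
}

#' Number of internal flags of an FDM sequence
#' @param fdm An `fdm_seq`.
#' @return Integer count of internal `X` segments.
#' @export
fdm_flag_count <- function(fdm) {
  sum(fdm$segments$kind == "X")
}

#' Working sequence of an FDM (flags rendered as single `X` characters)
#' @param fdm An `fdm_seq`.
#' @return A single string.
#' @export
fdm_sequence <- function(fdm) {
  if (nrow(fdm$segments) == 0) return("")
  paste(ifelse(fdm$segments$kind == "X", "X", fdm$segments$seq),
        collapse = "")
}

#' @export
print.fdm_seq <- function(x, ...) {
  cat("<fdm_seq> gene", x$gene_id, paste0("(", x$strand, ")"),
      "threshold", x$threshold,
      if (x$trimmed) "[post-processed]" else "[raw]", "\n")
  cat("  segments:", nrow(x$segments),
      "| internal flags:", fdm_flag_count(x),
      "| terminal deviations:",
      paste0(if (x$e_start) "5'" else "", if (x$e_end) "3'" else ""), "\n")
  invisible(x)
}

#' Tidy the segments of an FDM sequence
#' @param x An `fdm_seq`.
#' @param ... Unused.
#' @return The segment tibble with `gene_id` prepended.
#' @method tidy fdm_seq
#' @export
tidy.fdm_seq <- function(x, ...) {
  mutate(x$segments, gene_id = x$gene_id, .before = 1)
}

#' Write FDM sequences as FASTA plus an anchor table
#'
#' Serializes a list of FDM sequences as FASTA (flags as `X` characters) with
#' a tab-separated sidecar giving each segment's scaffold anchor and kind
#' (`seq`, `X`, or `E` for noted terminal deviations).
#'
#' @param fdms List of `fdm_seq` objects.
#' @param fasta_path Output FASTA path.
#' @param anchors_path Output TSV path (default: `fasta_path` with
#'   `.anchors.tsv` appended).
#' @return `fasta_path`, invisibly.
#' @export
write_fdm <- function(fdms, fasta_path,
                      anchors_path = paste0(fasta_path, ".anchors.tsv")) {
  seqs <- tibble(id = map_chr(fdms, "gene_id"),
                 seq = map_chr(fdms, fdm_sequence))
  seqs <- seqs[nchar(seqs$seq) > 0, , drop = FALSE]
  write_sequences(seqs, fasta_path, format = "fasta")
  anchors <- bind_rows(lapply(fdms, function(f) {
    seg <- f$segments
    rows <- tibble(gene_id = f$gene_id,
                   segment = seq_len(nrow(seg)),
                   kind = seg$kind,
                   anchor_start = seg$anchor_start,
                   anchor_end = seg$anchor_end)
    if (f$e_start)
      rows <- bind_rows(tibble(gene_id = f$gene_id, segment = 0L,
                               kind = "E", anchor_start = NA_integer_,
                               anchor_end = NA_integer_), rows)
    if (f$e_end)
      rows <- bind_rows(rows, tibble(gene_id = f$gene_id,
                                     segment = nrow(seg) + 1L, kind = "E",
                                     anchor_start = NA_integer_,
                                     anchor_end = NA_integer_))
    rows
  }))
  write.table(anchors, anchors_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}
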