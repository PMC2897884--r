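#' Read sequences from FASTA or FASTQ
#'
#' Reads a sequence file into a tibble with one row per record. Lowercase
#' (soft-masked) bases are uppercased; FASTQ base qualities are discarded —
#' every downstream step in the package is quality-blind and works on
#' mismatch counts only. Record ids are the first whitespace-delimited token
#' of each header and must be unique within a file.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (default; guessed from the extension), `"fasta"`, or
#'   `"fastq"`.
#' @return A tibble with columns `id` and `seq` (uppercase, alphabet
#'   restricted to A, C, G, T, N).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtN"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0) return(tibble(id = character(), seq = character()))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) abort(paste0("parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    abort(paste0("record '", ids[which(bad)[1]],
                 "' contains characters outside {A,C,G,T,N}"))
  if (anyDuplicated(ids))
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  if (any(nchar(seqs) == 0))
    abort(paste0("record '", ids[nchar(seqs) == 0][1], "' is empty"))
  tibble(id = ids, seq = seqs)
}

#' Write sequences to FASTA or FASTQ
#'
#' The inverse of [read_sequences()]. Sequences may contain flag characters
#' (such as the `X` deviation flag), so records are written as plain text
#' strings. FASTQ output receives uniform dummy qualities.
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(vapply(nchar(x$seq), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  }
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' Vectorized reverse complement over the alphabet A, C, G, T, N (`N` maps to
#' `N`). An involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAN"))
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) abort("sequence contains characters outside {A,C,G,T,N}")
  out <- character(length(seq))
  nz <- nchar(seq) > 0
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz])))
  out
}

# ---- gene models ------------------------------------------------------------

#' Validate a gene-model exon table
#'
#' Gene models are tibbles with one row per exon: `gene_id`, `scaffold_id`,
#' `strand` (`+`/`-`), `exon_rank` (ascending scaffold order), `start`, `end`.
#' Coordinates are 0-based half-open throughout the package; the GFF3 reader
#' and writer apply the 1-based inclusive shift exactly once at the file
#' boundary. Exons of a gene must be non-overlapping and sorted with introns
#' of length >= 1.
#'
#' @param models Gene-model tibble.
#' @param genome Optional sequence tibble; when given, exon bounds are checked
#'   against scaffold lengths.
#' @return `models`, invisibly, or an error describing the violated invariant.
#' @export
validate_gene_models <- function(models, genome = NULL) {
  need <- c("gene_id", "scaffold_id", "strand", "exon_rank", "start", "end")
  miss <- setdiff(need, names(models))
  if (length(miss))
    abort(paste0("gene-model table lacks columns: ",
                 paste(miss, collapse = ", ")))
  if (!all(models$strand %in% c("+", "-")))
    abort("unknown strand symbol (must be '+' or '-')")
  if (any(models$end <= models$start))
    abort("exon with end <= start")
  by_gene <- split(models, models$gene_id)
  for (g in by_gene) {
    g <- g[order(g$exon_rank), , drop = FALSE]
    if (length(unique(g$scaffold_id)) != 1L)
      abort(paste0("gene '", g$gene_id[1], "' spans multiple scaffolds"))
    if (length(unique(g$strand)) != 1L)
      abort(paste0("gene '", g$gene_id[1], "' has mixed strands"))
    if (is.unsorted(g$start, strictly = TRUE) && nrow(g) > 1)
      abort(paste0("gene '", g$gene_id[1], "' exons not sorted"))
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)] + 1L))
      abort(paste0("gene '", g$gene_id[1],
                   "' has overlapping or abutting exons (intron length < 1)"))
  }
  if (!is.null(genome)) {
    len <- setNames(nchar(genome$seq), genome$id)
    if (!all(models$scaffold_id %in% names(len)))
      abort("gene model references a scaffold absent from the genome")
    if (any(models$start < 0L) ||
        any(models$end > len[models$scaffold_id]))
      abort("exon outside scaffold bounds")
  }
  invisible(models)
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`exon` features (exon `Parent` attributes resolve to the
#' gene) into the package's exon table. File coordinates are 1-based
#' inclusive per GFF3 and converted to the internal 0-based half-open
#' convention.
#'
#' @param path GFF3 file path.
#' @param genome Optional sequence tibble for bounds checking.
#' @return A gene-model tibble (see [validate_gene_models()]).
#' @export
read_gene_models <- function(path, genome = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("GFF3 parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0)
    return(tibble(gene_id = character(), scaffold_id = character(),
                  strand = character(), exon_rank = integer(),
                  start = integer(), end = integer()))
  parent <- as.character(BiocGenerics::unlist(ex$Parent))
  if (length(parent) != length(ex))
    abort("exon with zero or multiple Parent attributes")
  strand <- as.character(BiocGenerics::strand(ex))
  if (any(strand == "*")) abort("unknown strand symbol")
  models <- tibble(
    gene_id = parent,
    scaffold_id = as.character(GenomicRanges::seqnames(ex)),
    strand = strand,
    start = BiocGenerics::start(ex) - 1L,
    end = BiocGenerics::end(ex)
  ) |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(exon_rank = seq_len(n())) |>
    ungroup() |>
    select("gene_id", "scaffold_id", "strand", "exon_rank", "start", "end")
  validate_gene_models(models, genome)
  models
}

#' Write gene models to GFF3
#'
#' Emits `gene` and `exon` features (score `.`, `ID`/`Parent` attributes),
#' converting internal 0-based half-open coordinates to the 1-based inclusive
#' GFF3 convention. `read_gene_models(write_gene_models(m))` is the identity
#' for any valid model table.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, source = "rnarefine") {
  validate_gene_models(models)
  genes <- models |>
    group_by(.data$gene_id, .data$scaffold_id, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    arrange(.data$scaffold_id, .data$start, .data$gene_id)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id
  )
  ex <- models |> arrange(.data$scaffold_id, .data$gene_id, .data$exon_rank)
  exon_gr <- GenomicRanges::GRanges(
    seqnames = ex$scaffold_id,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand, type = "exon",
    ID = paste0(ex$gene_id, ".exon", ex$exon_rank)
  )
  gene_gr$Parent <- IRanges::CharacterList(vector("list",
                                                  length(gene_gr)))
  exon_gr$Parent <- IRanges::CharacterList(as.list(ex$gene_id))
  gr <- c(gene_gr, exon_gr)
  gr$source <- source
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- model geometry helpers -------------------------------------------------

#' Per-gene scaffold span of a model table
#' @param models Gene-model tibble.
#' @return Tibble with `gene_id`, `scaffold_id`, `strand`, `span_start`,
#'   `span_end` (0-based half-open).
#' @export
model_spans <- function(models) {
  models |>
    group_by(.data$gene_id, .data$scaffold_id, .data$strand) |>
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop")
}

#' Spliced transcript length of each model
#' @param models Gene-model tibble.
#' @return Tibble with `gene_id` and `transcript_len`.
#' @export
transcript_lengths <- function(models) {
  models |>
    group_by(.data$gene_id) |>
    summarise(transcript_len = sum(.data$end - .data$start),
              .groups = "drop")
}

# transcript-position -> scaffold-position map, in transcript (5'->3') order.
# Returns an integer vector p with p[t + 1] = scaffold position of transcript
# position t (both 0-based).
transcript_map <- function(exons) {
  exons <- exons[order(exons$exon_rank), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons$start[i], exons$end[i] - 1L)), use.names = FALSE)
  if (exons$strand[1] == "-") pos <- rev(pos)
  pos
}

#' Spliced transcript sequences of gene models
#'
#' Concatenates each model's exon sequence in transcript orientation
#' (reverse-complemented for minus-strand genes).
#'
#' @param models Gene-model tibble.
#' @param genome Sequence tibble holding the scaffolds.
#' @return Tibble with `id` (the gene id) and `seq`, suitable as an alignment
#'   reference set.
#' @export
transcript_sequences <- function(models, genome) {
  validate_gene_models(models, genome)
  scaff <- setNames(genome$seq, genome$id)
  by_gene <- split(models, models$gene_id)
  out <- lapply(by_gene, function(ex) {
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    s <- paste(substring(scaff[[ex$scaffold_id[1]]], ex$start + 1L, ex$end),
               collapse = "")
    if (ex$strand[1] == "-") s <- reverse_complement(s)
    s
  })
  tibble(id = names(out), seq = unlist(out, use.names = FALSE))
}
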