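#' Scoring scheme for the splice-aware realigner
#'
#' Defaults encode the asymmetric expectations of transcript-to-genome
#' alignment: gaps in the genomic window (a base present in the assembled
#' transcript but absent from the scaffold) are heavily penalized at -24 per
#' base, gaps in the transcript side are introns and cost only -1 per base,
#' window overhang beyond the transcript ends is free, `N` matches anything
#' at +4 (enough to avoid spurious gaps without over-rewarding runs of `N`),
#' and no aligned block shorter than `min_bes_block` transcript bases is
#' permitted anywhere in the optimum.
#'
#' @param match,mismatch,n_match Column scores (defaults 8, -12, 4).
#' @param gap_scaffold Per-base penalty for a gap in the scaffold (default
#'   -24).
#' @param gap_bes Per-base penalty for a gap in the transcript side, i.e. an
#'   intron (default -1).
#' @param bes_end_gap Penalty for window overhang at the transcript ends
#'   (fixed at 0; recorded for completeness).
#' @param min_bes_block Minimum aligned-block length (default 4).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 8, mismatch = -12, n_match = 4,
                           gap_scaffold = -24, gap_bes = -1,
                           bes_end_gap = 0, min_bes_block = 4) {
  stopifnot(min_bes_block >= 1)
  structure(list(match = match, mismatch = mismatch, n_match = n_match,
                 gap_scaffold = gap_scaffold, gap_bes = gap_bes,
                 bes_end_gap = bes_end_gap,
                 min_bes_block = as.integer(min_bes_block)),
            class = "scoring_scheme")
}

#' Trim a BES and select its genomic alignment window
#'
#' Five percent of each terminus extension (rounded down) is trimmed from
#' the outer end before realignment — the outermost consensus bases are the
#' least supported. The scaffold window offered to the aligner is the
#' original model span widened by three times each extension length
#' (placed on the correct scaffold side given the model's strand), clipped
#' to the scaffold bounds.
#'
#' @param bes A `bes` object.
#' @param model Exon tibble of the gene.
#' @param scaffold Single-row sequence tibble holding the gene's scaffold.
#' @param trim_frac Fraction of each extension to trim (default 0.05).
#' @param window_mult Window widening per extension base (default 3).
#' @return List with `bes_seq` (trimmed), `window` (list: `scaffold_id`,
#'   `start`, `end`, `seq`), and the trim amounts.
#' @export
prepare_bes <- function(bes, model, scaffold, trim_frac = 0.05,
                        window_mult = 3) {
  stopifnot(inherits(bes, "bes"))
  s <- bes$sequence
  trim_up <- floor(trim_frac * bes$upstream_extension_len)
  trim_down <- floor(trim_frac * bes$downstream_extension_len)
  if (trim_up + trim_down >= nchar(s))
    abort(paste0("BES of gene '", bes$gene_id, "' vanishes after trimming"))
  s <- substr(s, trim_up + 1L, nchar(s) - trim_down)
  span_start <- min(model$start)
  span_end <- max(model$end)
  up <- bes$upstream_extension_len
  down <- bes$downstream_extension_len
  if (model$strand[1] == "+") {
    left <- up; right <- down
  } else {
    left <- down; right <- up
  }
  w_start <- max(0L, span_start - window_mult * left)
  w_end <- min(nchar(scaffold$seq[1]), span_end + window_mult * right)
  if (w_end <= w_start)
    abort(paste0("empty alignment window for gene '", bes$gene_id, "'"))
  list(bes_seq = s,
       window = list(scaffold_id = scaffold$id[1], start = w_start,
                     end = w_end,
                     seq = substr(scaffold$seq[1], w_start + 1L, w_end)),
       trim_up = trim_up, trim_down = trim_down)
}

#' Splice-aware semi-global alignment of a transcript to a genomic window
#'
#' A Smith-Waterman variant with the asymmetric linear gap penalties of
#' [scoring_scheme()]: the transcript side is aligned end to end, window
#' overhang is free, window gaps inside the alignment are introns, and the
#' minimum aligned-block constraint is enforced inside the dynamic program
#' (via a capped run-length state), so the returned optimum is global under
#' the constraint rather than repaired afterwards. Tie-breaking is
#' deterministic.
#'
#' @param bes_seq Transcript-side sequence (may contain `N`).
#' @param window_seq Genomic window sequence.
#' @param scheme A [scoring_scheme()].
#' @return A `spliced_alignment`: `score`, `blocks` (tibble of paired
#'   `bes_start`/`bes_end`/`w_start`/`w_end`, 0-based half-open), `identity`
#'   (fraction of aligned non-`N` columns that match), `aligned_fraction`
#'   (fraction of non-`N` transcript bases in aligned columns).
#' @export
spliced_align <- function(bes_seq, window_seq, scheme = scoring_scheme()) {
  stopifnot(nchar(bes_seq) > 0, nchar(window_seq) > 0)
  res <- cpp_spliced_align(bes_seq, window_seq, scheme$match,
                           scheme$mismatch, scheme$n_match,
                           scheme$gap_scaffold, scheme$gap_bes,
                           scheme$min_bes_block)
  cols <- tibble(type = res$type, bi = res$bi, wj = res$wj)
  diag <- cols |> filter(.data$type == 0)
  blocks <- tibble(bes_start = integer(), bes_end = integer(),
                   w_start = integer(), w_end = integer())
  n_match_cols <- 0L; n_informative <- 0L
  if (nrow(diag) > 0) {
    brk <- cumsum(c(1L, as.integer(diff(diag$bi) != 1L |
                                     diff(diag$wj) != 1L)))
    blocks <- diag |>
      mutate(block = brk) |>
      group_by(.data$block) |>
      summarise(bes_start = min(.data$bi), bes_end = max(.data$bi) + 1L,
                w_start = min(.data$wj), w_end = max(.data$wj) + 1L,
                .groups = "drop") |>
      select(-"block")
    bb <- substring(bes_seq, diag$bi + 1L, diag$bi + 1L)
    wb <- substring(window_seq, diag$wj + 1L, diag$wj + 1L)
    informative <- bb != "N" & wb != "N"
    n_informative <- sum(informative)
    n_match_cols <- sum(informative & bb == wb)
  }
  bes_chars <- strsplit(bes_seq, "", fixed = TRUE)[[1]]
  non_n <- sum(bes_chars != "N")
  aligned_non_n <- if (nrow(diag))
    sum(substring(bes_seq, diag$bi + 1L, diag$bi + 1L) != "N") else 0L
  structure(list(score = res$score, blocks = blocks,
                 identity = if (n_informative > 0)
                   n_match_cols / n_informative else NA_real_,
                 aligned_fraction = if (non_n > 0)
                   aligned_non_n / non_n else NA_real_,
                 bes_len = nchar(bes_seq), window_len = nchar(window_seq)),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat("<spliced_alignment> score", x$score, "|", nrow(x$blocks), "blocks |",
      "identity", round(x$identity, 4), "| aligned",
      round(x$aligned_fraction, 4), "\n")
  invisible(x)
}

#' Tidy the blocks of a spliced alignment
#' @param x A `spliced_alignment`.
#' @param ... Unused.
#' @return The block tibble.
#' @method tidy spliced_alignment
#' @export
tidy.spliced_alignment <- function(x, ...) x$blocks

#' Recover a corrected gene structure from a BES
#'
#' Runs [prepare_bes()] and [spliced_align()]; when the alignment is not
#' acceptable (fewer than `min_aligned` of the non-`N` transcript bases in
#' aligned columns, or identity below `min_identity`), retries with the
#' reverse-complemented sequence. A successful alignment is converted to
#' exon blocks on the scaffold (aligned blocks separated only by
#' transcript-side insertions merge into one exon; window gaps become
#' introns) and the outcome is classified with [classify_outcome()]. A BES
#' with unresolved flags fails immediately without alignment.
#'
#' @param bes A `bes` object.
#' @param model The original exon tibble of the gene.
#' @param scaffold Single-row sequence tibble with the gene's scaffold.
#' @param scheme A [scoring_scheme()].
#' @param min_aligned,min_identity Acceptance thresholds for an alignment
#'   (defaults 0.90 and 0.95).
#' @param trim_frac,window_mult Passed to [prepare_bes()].
#' @return A `corrected_model` object.
#' @export
recover_structure <- function(bes, model, scaffold,
                              scheme = scoring_scheme(),
                              min_aligned = 0.90, min_identity = 0.95,
                              trim_frac = 0.05, window_mult = 3) {
  stopifnot(inherits(bes, "bes"))
  model <- model[order(model$exon_rank), , drop = FALSE]
  fail <- function(reason) {
    structure(list(gene_id = bes$gene_id, exons = NULL,
                   outcome = "failed", reason = reason,
                   orientation = NA_character_, alignment = NULL,
                   change_record = list(
                     bridged_flag_count = nrow(bes$bridged_flags),
                     exon_count_delta = NA_integer_,
                     size_change_fraction = NA_real_)),
              class = "corrected_model")
  }
  if (nrow(bes$unresolved_flags) > 0 ||
      grepl("X", bes$sequence, fixed = TRUE))
    return(fail("unresolved_flags"))
  if (nchar(bes$sequence) < scheme$min_bes_block)
    return(fail("no_sequence"))
  prep <- prepare_bes(bes, model, scaffold, trim_frac = trim_frac,
                      window_mult = window_mult)
  acceptable <- function(a) {
    !is.na(a$aligned_fraction) && a$aligned_fraction >= min_aligned &&
      !is.na(a$identity) && a$identity >= min_identity
  }
  aln <- spliced_align(prep$bes_seq, prep$window$seq, scheme)
  flipped <- FALSE
  if (!acceptable(aln)) {
    aln_rc <- spliced_align(reverse_complement(prep$bes_seq),
                            prep$window$seq, scheme)
    if (acceptable(aln_rc)) {
      aln <- aln_rc
      flipped <- TRUE
    } else {
      return(fail("no_alignment"))
    }
  }
  # orientation of the recovered gene on the scaffold: a plus-strand gene's
  # BES aligns directly; a minus-strand gene's aligns after
  # reverse-complementing
  orientation <- if (flipped) "-" else "+"
  w0 <- prep$window$start
  b <- aln$blocks |> arrange(.data$w_start)
  # merge blocks split only by transcript-side insertions (no scaffold gap)
  exon_start <- integer(0); exon_end <- integer(0)
  for (i in seq_len(nrow(b))) {
    ws <- b$w_start[i] + w0; we <- b$w_end[i] + w0
    if (length(exon_end) > 0 && ws <= exon_end[length(exon_end)]) {
      exon_end[length(exon_end)] <- max(exon_end[length(exon_end)], we)
    } else {
      exon_start <- c(exon_start, ws); exon_end <- c(exon_end, we)
    }
  }
  exons <- tibble(gene_id = bes$gene_id,
                  scaffold_id = model$scaffold_id[1],
                  strand = orientation,
                  exon_rank = seq_along(exon_start),
                  start = as.integer(exon_start),
                  end = as.integer(exon_end))
  old_len <- sum(model$end - model$start)
  new_len <- sum(exons$end - exons$start)
  change <- list(
    bridged_flag_count = nrow(bes$bridged_flags),
    exon_count_delta = nrow(exons) - nrow(model),
    size_change_fraction = (new_len - old_len) / old_len)
  out <- structure(list(gene_id = bes$gene_id, exons = exons,
                        outcome = NA_character_, reason = NA_character_,
                        orientation = orientation, alignment = aln,
                        change_record = change),
                   class = "corrected_model")
  out$outcome <- classify_outcome(model, out, bes)
  out
}

#' Classify a realigned gene model
#'
#' A model is `corrected` when evidence changed it: at least one flag was
#' successfully bridged, the exon count changed, or the expressed size
#' changed by more than `size_cut` in absolute value. Otherwise the original
#' annotation is `validated`. (Failure — unresolved flags or no acceptable
#' alignment — is decided upstream in [recover_structure()].)
#'
#' @param old Original exon tibble.
#' @param new A `corrected_model` with exons and change record filled in.
#' @param bes The `bes` the model was rebuilt from.
#' @param size_cut Absolute size-change fraction above which a model counts
#'   as changed (default 0.10).
#' @return `"corrected"` or `"validated"`.
#' @export
classify_outcome <- function(old, new, bes, size_cut = 0.10) {
  cr <- new$change_record
  if (cr$bridged_flag_count >= 1 ||
      (!is.na(cr$exon_count_delta) && cr$exon_count_delta != 0) ||
      (!is.na(cr$size_change_fraction) &&
         abs(cr$size_change_fraction) > size_cut))
    "corrected"
  else
    "validated"
}

#' @export
print.corrected_model <- function(x, ...) {
  cat("<corrected_model> gene", x$gene_id, "| outcome", x$outcome)
  if (!is.null(x$exons))
    cat(" |", nrow(x$exons), "exons | size change",
        sprintf("%+.1f%%", 100 * x$change_record$size_change_fraction))
  if (!is.na(x$reason) && x$outcome == "failed")
    cat(" |", x$reason)
  cat("\n")
  invisible(x)
}

#' Tidy a corrected model into its exon table
#' @param x A `corrected_model`.
#' @param ... Unused.
#' @return Exon tibble (empty when the model failed).
#' @method tidy corrected_model
#' @export
tidy.corrected_model <- function(x, ...) {
  if (is.null(x$exons))
    return(tibble(gene_id = character(), scaffold_id = character(),
                  strand = character(), exon_rank = integer(),
                  start = integer(), end = integer()))
  x$exons
}

#' One-row summary of a corrected model
#' @param x A `corrected_model`.
#' @param ... Unused.
#' @return Tibble with outcome and change record.
#' @method glance corrected_model
#' @export
glance.corrected_model <- function(x, ...) {
  cr <- x$change_record
  tibble(gene_id = x$gene_id, outcome = x$outcome,
         flags_bridged = cr$bridged_flag_count,
         exon_delta = cr$exon_count_delta,
         size_change = cr$size_change_fraction,
         reason = x$reason)
}
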