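#' Build an exact-substring probe index over a read set
#'
#' Indexes every probe-length window of every read and of its reverse
#' complement for exact lookup. This is the search structure behind
#' consensus assembly: probe matching is exact by design, and reads are
#' searched in both orientations because the cDNA reads carry no strand
#' information.
#'
#' @param reads Tibble with columns `id`, `seq`.
#' @param probe_len Probe length (default 18).
#' @return A `read_index` object.
#' @export
read_index <- function(reads, probe_len = 18) {
  stopifnot(nrow(reads) >= 0, probe_len >= 1)
  rc <- reverse_complement(reads$seq)
  ptr <- cpp_probe_index_build(reads$seq, rc, as.integer(probe_len))
  structure(list(ptr = ptr, probe_len = as.integer(probe_len),
                 n_reads = nrow(reads), read_ids = reads$id),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat("<read_index>", x$n_reads, "reads, probe length", x$probe_len, "\n")
  invisible(x)
}

#' Exact occurrences of a probe in an indexed read set
#' @param index A `read_index`.
#' @param probe Probe string of the index's probe length.
#' @return Tibble with `read_id`, `offset` (0-based within the read in the
#'   matching orientation), `orientation` (`+`/`-`).
#' @export
index_query <- function(index, probe) {
  stopifnot(inherits(index, "read_index"))
  hits <- cpp_probe_index_query(index$ptr, probe)
  tibble(read_id = index$read_ids[hits$read],
         offset = as.integer(hits$offset),
         orientation = c("+", "-")[hits$strand + 1L])
}

#' Consensus chunk following a probe in the read set
#'
#' Locates every exact occurrence of `probe` in the indexed reads (either
#' orientation) and tallies the bases observed at each of the `probe_len`
#' positions that follow. The consensus call at a position is the base
#' carried by a strict majority (> 50 percent) of that position's tally;
#' ties, sub-majority pluralities, and zero coverage give `N`. Probes
#' containing `N` (or any non-ACGT character) cannot match and return all
#' `N`.
#'
#' @param index A `read_index`.
#' @param probe Probe string of the index's probe length; must not contain
#'   the flag character `X`.
#' @return The next `probe_len` consensus bases as a single string.
#' @export
find_next_probe <- function(index, probe) {
  stopifnot(inherits(index, "read_index"))
  if (nchar(probe) != index$probe_len)
    abort(paste0("probe must have length ", index$probe_len))
  if (grepl("X", probe, fixed = TRUE))
    abort("probe contains the flag character 'X'")
  cpp_find_next_probe(index$ptr, probe)
}

#' Grow a consensus contig between (or beyond) probes
#'
#' The iterative assembly loop: starting from `start_probe`, repeatedly
#' appends the consensus chunk returned by [find_next_probe()] for the
#' growing contig's terminal probe. In bridging mode the loop succeeds as
#' soon as `end_probe` occurs as an exact substring of the contig (the
#' contig is truncated at the end of that occurrence); it gives up when the
#' cumulative count of `N` calls exceeds `max_n` or the iteration count
#' exceeds `max_look`. In extension mode (`end_probe = NULL`) the contig
#' simply grows until a budget is exhausted and is returned with its
#' trailing run of `N` stripped.
#'
#' @param index A `read_index`.
#' @param start_probe Seed probe (must be probe length, no `N`).
#' @param end_probe Target probe, or `NULL` for extension mode.
#' @param max_look Maximum iterations (default 27).
#' @param max_n Maximum cumulative `N` calls (default 6 for bridging; use 1
#'   for terminus extension).
#' @return A `bridge_result`: list with `sequence`, `status` (one of
#'   `end_probe_found`, `max_look_exceeded`, `max_n_exceeded`,
#'   `no_reads_matched`), `iterations_used`, `n_count`.
#' @export
bridge_probes <- function(index, start_probe, end_probe = NULL,
                          max_look = 27, max_n = 6) {
  k <- index$probe_len
  stopifnot(nchar(start_probe) == k)
  extension <- is.null(end_probe)
  if (!extension) stopifnot(nchar(end_probe) == k)
  contig <- start_probe
  n_count <- 0L
  iter <- 0L
  status <- NULL
  repeat {
    if (iter >= max_look) { status <- "max_look_exceeded"; break }
    iter <- iter + 1L
    query <- substr(contig, nchar(contig) - k + 1L, nchar(contig))
    chunk <- if (grepl("[^ACGT]", query)) strrep("N", k)
      else find_next_probe(index, query)
    contig <- paste0(contig, chunk)
    n_count <- n_count +
      nchar(gsub("[^N]", "", chunk, perl = TRUE))
    if (!extension) {
      hit <- regexpr(end_probe, contig, fixed = TRUE)
      if (hit > 0) {
        contig <- substr(contig, 1L, hit + k - 1L)
        status <- "end_probe_found"
        break
      }
    }
    if (n_count > max_n) { status <- "max_n_exceeded"; break }
  }
  if (iter == 1L && chunk == strrep("N", k) &&
      !identical(status, "end_probe_found") &&
      nrow(index_query(index, start_probe)) == 0)
    status <- "no_reads_matched"
  if (extension) contig <- sub("N+$", "", contig)
  structure(list(sequence = contig, status = status,
                 iterations_used = iter, n_count = n_count),
            class = "bridge_result")
}

#' @export
print.bridge_result <- function(x, ...) {
  cat("<bridge_result>", x$status, "| length", nchar(x$sequence),
      "| iterations", x$iterations_used, "| N calls", x$n_count, "\n")
  invisible(x)
}

#' Bridge one internal flag of a post-processed FDM
#'
#' Attempts to span the `flag_index`-th internal flag with read-assembled
#' consensus sequence. Probes are taken at increasing distances from the
#' flag — first 6, then 15, then 21 bases up- and downstream — so that a
#' read error or boundary misalignment corrupting one probe site does not
#' doom the bridge. The first offset whose bridge finds the end probe wins.
#' The returned spanning sequence runs from the start probe through the end
#' probe, so it replaces the flag plus the skipped flanking margin on each
#' side.
#'
#' @param fdm A post-processed `fdm_seq`.
#' @param flag_index Which internal flag (1-based among `X` segments).
#' @param index A `read_index`.
#' @param offsets Probe distances from the flag to try, in order.
#' @param max_look,max_n Budgets passed to [bridge_probes()].
#' @return On success, a list with `sequence`, `offset_used`, and the margins
#'   consumed on each side; on failure `NULL`.
#' @export
resolve_flag <- function(fdm, flag_index, index, offsets = c(6, 15, 21),
                         max_look = 27, max_n = 6) {
  stopifnot(inherits(fdm, "fdm_seq"), fdm$trimmed)
  k <- index$probe_len
  seg <- fdm$segments
  flags <- which(seg$kind == "X")
  stopifnot(flag_index >= 1, flag_index <= length(flags))
  i <- flags[flag_index]
  if (i == 1L || i == nrow(seg)) return(NULL)   # no flanking probe host
  up <- seg$seq[i - 1L]; down <- seg$seq[i + 1L]
  lu <- nchar(up); ld <- nchar(down)
  for (d in offsets) {
    if (lu < d + k || ld < d + k) next
    start_probe <- substr(up, lu - d - k + 1L, lu - d)
    end_probe <- substr(down, d + 1L, d + k)
    if (grepl("[^ACGT]", start_probe) || grepl("[^ACGT]", end_probe)) next
    res <- bridge_probes(index, start_probe, end_probe,
                         max_look = max_look, max_n = max_n)
    if (res$status == "end_probe_found") {
      return(list(sequence = res$sequence, offset_used = d,
                  up_margin = d + k, down_margin = d + k,
                  iterations_used = res$iterations_used,
                  n_count = res$n_count))
    }
  }
  NULL
}

#' Assemble the bridged-and-extended sequence (BES) of a gene
#'
#' Runs every internal flag of a post-processed FDM through
#' [resolve_flag()], splices the spanning sequences into the expressed
#' segments, and then extends both termini by consensus assembly in
#' extension mode (seeded with the FDM's first and last probe-length bases;
#' the upstream side is grown on the reverse complement and flipped back).
#' Unresolved flags stay in the sequence as single `X` characters and mark
#' the gene for eventual failure.
#'
#' @param fdm A post-processed `fdm_seq`.
#' @param index A `read_index`.
#' @param max_look,max_n Bridging budgets (defaults 27 and 6).
#' @param extension_max_n `N` budget in extension mode (default 1).
#' @param extension_max_look Iteration cap in extension mode (default 27; a
#'   hard cap prevents runaway extension through repeats).
#' @return A `bes` object: `sequence`, per-flag bridging records, extension
#'   lengths, and the originating FDM.
#' @export
assemble_bes <- function(fdm, index, max_look = 27, max_n = 6,
                         extension_max_n = 1, extension_max_look = 27) {
  stopifnot(inherits(fdm, "fdm_seq"), fdm$trimmed)
  k <- index$probe_len
  seg <- fdm$segments
  flags <- which(seg$kind == "X")
  pieces <- ifelse(seg$kind == "X", "X", seg$seq)
  orig <- pieces
  # bases already consumed from the left of each expressed piece by the
  # previous bridge; a short segment flanked by two bridged flags can be
  # consumed from both sides, in which case the overlap is trimmed off the
  # front of the second bridge (the overlap lies inside its exact probe, so
  # the emitted sequence stays a single copy of the truth)
  consumed_left <- integer(length(pieces))
  bridged <- list(); unresolved <- list()
  if (length(flags)) {
    for (fi in seq_along(flags)) {
      i <- flags[fi]
      res <- resolve_flag(fdm, fi, index, max_look = max_look,
                          max_n = max_n)
      if (is.null(res)) {
        unresolved[[length(unresolved) + 1L]] <-
          tibble(flag = fi, reason = "no_spanning_sequence")
        next
      }
      lu <- nchar(orig[i - 1L]); ld <- nchar(orig[i + 1L])
      keep_up <- lu - res$up_margin
      cl <- consumed_left[i - 1L]
      bridge_seq <- res$sequence
      if (cl > keep_up) {
        bridge_seq <- substr(bridge_seq, cl - keep_up + 1L,
                             nchar(bridge_seq))
        pieces[i - 1L] <- ""
      } else {
        pieces[i - 1L] <- substr(orig[i - 1L], cl + 1L, keep_up)
      }
      pieces[i] <- bridge_seq
      pieces[i + 1L] <- substr(orig[i + 1L], res$down_margin + 1L, ld)
      consumed_left[i + 1L] <- res$down_margin
      bridged[[length(bridged) + 1L]] <-
        tibble(flag = fi, offset_used = res$offset_used,
               spanning_len = nchar(res$sequence))
    }
  }
  core <- paste(pieces, collapse = "")
  up_ext <- 0L; down_ext <- 0L
  clean <- function(s) nchar(s) >= k && !grepl("[^ACGT]", s)
  if (nchar(core) >= k) {
    first <- substr(core, 1L, k)
    if (clean(first)) {
      grown <- bridge_probes(index, reverse_complement(first),
                             end_probe = NULL,
                             max_look = extension_max_look,
                             max_n = extension_max_n)
      ext <- nchar(grown$sequence) - k
      if (ext > 0) {
        core <- paste0(reverse_complement(grown$sequence),
                       substr(core, k + 1L, nchar(core)))
        up_ext <- ext
      }
    }
    last <- substr(core, nchar(core) - k + 1L, nchar(core))
    if (clean(last)) {
      grown <- bridge_probes(index, last, end_probe = NULL,
                             max_look = extension_max_look,
                             max_n = extension_max_n)
      ext <- nchar(grown$sequence) - k
      if (ext > 0) {
        core <- paste0(substr(core, 1L, nchar(core) - k),
                       grown$sequence)
        down_ext <- ext
      }
    }
  }
  structure(list(gene_id = fdm$gene_id, sequence = core,
                 bridged_flags = bind_rows(bridged),
                 unresolved_flags = bind_rows(unresolved),
                 upstream_extension_len = up_ext,
                 downstream_extension_len = down_ext,
                 fdm = fdm),
            class = "bes")
}

#' @export
print.bes <- function(x, ...) {
  cat("<bes> gene", x$gene_id, "| length", nchar(x$sequence),
      "| bridged", nrow(x$bridged_flags), "| unresolved",
      nrow(x$unresolved_flags), "| extensions",
      paste0("5':", x$upstream_extension_len, " 3':",
             x$downstream_extension_len), "\n")
  invisible(x)
}

#' Tidy the bridging record of a BES
#' @param x A `bes`.
#' @param ... Unused.
#' @return Tibble with one row per flag (bridged and unresolved).
#' @method tidy bes
#' @export
tidy.bes <- function(x, ...) {
  b <- x$bridged_flags
  u <- x$unresolved_flags
  rows <- list()
  if (nrow(b))
    rows[[1]] <- mutate(b, status = "bridged")
  if (nrow(u))
    rows[[2]] <- tibble(flag = u$flag, offset_used = NA_integer_,
                        spanning_len = NA_integer_, status = "unresolved")
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(flag = integer(), offset_used = integer(),
                  spanning_len = integer(), status = character())
  mutate(out, gene_id = x$gene_id, .before = 1) |> arrange(.data$flag)
}
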