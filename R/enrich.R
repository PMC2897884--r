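#' Cumulative binomial distribution
#'
#' `B(x; n, p)`: the probability of at most `x` successes in `n` trials with
#' per-trial success probability `p`. Enrichment p-values are reported as
#' `1 - B`, the probability of strictly more than `x` successes.
#'
#' @param x Number of successes observed (vectorized).
#' @param n Number of trials.
#' @param p Per-trial success probability.
#' @return `B(x; n, p)` in `[0, 1]`.
#' @examples
#' cumulative_binomial(2, 5, 0.5) # 16/32
#' @export
cumulative_binomial <- function(x, n, p) {
  if (any(x < 0) || any(x > n)) abort("x must satisfy 0 <= x <= n")
  if (any(p < 0) || any(p > 1)) abort("p must lie in [0, 1]")
  pbinom(x, n, p)
}

#' Annotation enrichment by the cumulative binomial
#'
#' For each annotation tally the p-value is `1 - B(x; n, p)` — the
#' probability of observing strictly more than the `x` models seen in the
#' selected set if annotations were drawn at the background fraction `p`.
#' Annotations pass when the p-value is below `p_cut` and the selected set
#' carries at least `min_models` models with the annotation.
#'
#' @param tallies Tibble with columns `annotation`, `x` (count in the
#'   selected set), `n` (selected-set size), `p` (background fraction
#'   carrying the annotation). See [tally_annotations()].
#' @param p_cut Significance cutoff (default 0.001).
#' @param min_models Minimum selected-set count (default 10).
#' @param inclusive When `TRUE`, use the conventional inclusive tail
#'   `P(X >= x)` instead of the stricter `P(X > x)`.
#' @return The enriched rows with a `p_value` column, sorted ascending by
#'   p-value.
#' @export
annotation_enrichment <- function(tallies, p_cut = 0.001, min_models = 10,
                                  inclusive = FALSE) {
  stopifnot(is.data.frame(tallies))
  if (nrow(tallies) == 0)
    return(tibble(annotation = character(), x = integer(), n = integer(),
                  p = double(), p_value = double()))
  q <- if (inclusive) tallies$x - 1 else tallies$x
  tallies |>
    mutate(p_value = pbinom(q, .data$n, .data$p, lower.tail = FALSE)) |>
    filter(.data$p_value < p_cut, .data$x >= min_models) |>
    arrange(.data$p_value)
}

#' Build enrichment tallies from gene-to-annotation tables
#'
#' @param set_annotations Two-column tibble (`gene_id`, `annotation`) for the
#'   selected gene set.
#' @param background_annotations Same layout for the background model set.
#' @param set_size Number of models in the selected set (default: distinct
#'   `gene_id` in `set_annotations`).
#' @param background_size Number of models in the background (default:
#'   distinct `gene_id` in `background_annotations`).
#' @return Tally tibble for [annotation_enrichment()].
#' @export
tally_annotations <- function(set_annotations, background_annotations,
                              set_size = NULL, background_size = NULL) {
  if (is.null(set_size))
    set_size <- length(unique(set_annotations$gene_id))
  if (is.null(background_size))
    background_size <- length(unique(background_annotations$gene_id))
  stopifnot(background_size > 0)
  bg <- background_annotations |>
    distinct(.data$gene_id, .data$annotation) |>
    count(.data$annotation, name = "bg_count")
  set_annotations |>
    distinct(.data$gene_id, .data$annotation) |>
    count(.data$annotation, name = "x") |>
    left_join(bg, by = "annotation") |>
    mutate(bg_count = coalesce(.data$bg_count, 0L),
           n = as.integer(set_size),
           p = .data$bg_count / background_size) |>
    select("annotation", "x", "n", "p")
}

#' Read a two-column gene-to-annotation table
#' @param path Tab-separated file with columns gene id and annotation (no
#'   header).
#' @return Tibble with `gene_id`, `annotation`.
#' @export
read_annotation_table <- function(path) {
  x <- read.delim(path, header = FALSE, col.names = c("gene_id",
                                                      "annotation"),
                  colClasses = "character")
  as_tibble(x)
}
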