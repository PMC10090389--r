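# Taxonomy frequency tables and PTM-site summaries.

#' Linker-class frequencies per taxon
#'
#' Tallies short/medium/long linker classes within each taxonomic group and
#' normalises to per-taxon frequencies. Sequences without a lineage row are
#' tallied under `"Unclassified"`. The result is invariant to the row order
#' of the lineage table.
#'
#' @param labels Tibble with columns `seqid` and `linker_class` (one of
#'   short/medium/long, from [classify_linker_lengths()]).
#' @param lineage Tibble with columns `seqid`, `phylum`, `class`.
#' @param rank Taxonomic rank to group by: `"class"` (default) or
#'   `"phylum"`.
#' @return Tibble of class `taxon_frequency` with columns `taxon`,
#'   `linker_class`, `n`, `freq`; taxa ordered by decreasing total count,
#'   and per-taxon frequencies summing to 1.
#' @export
taxonomy_frequency <- function(labels, lineage, rank = c("class", "phylum")) {
  rank <- match.arg(rank)
  lin <- dplyr::distinct(lineage, .data$seqid, .keep_all = TRUE)
  joined <- dplyr::left_join(labels, lin, by = "seqid")
  joined$taxon <- dplyr::coalesce(joined[[rank]], "Unclassified")
  counts <- dplyr::count(joined, .data$taxon, .data$linker_class)
  counts <- tidyr::complete(
    counts, taxon = unique(joined$taxon),
    linker_class = c("short", "medium", "long"),
    fill = list(n = 0L))
  counts <- dplyr::group_by(counts, .data$taxon)
  counts <- dplyr::mutate(counts, total = sum(.data$n),
                          freq = ifelse(.data$total > 0, .data$n / .data$total, 0))
  counts <- dplyr::ungroup(counts)
  counts <- dplyr::arrange(counts, dplyr::desc(.data$total), .data$taxon,
                           factor(.data$linker_class,
                                  levels = c("short", "medium", "long")))
  out <- dplyr::select(counts, "taxon", "linker_class", "n", "freq")
  class(out) <- c("taxon_frequency", class(out))
  out
}

#' Summarise predicted PTM sites in linker regions at score cutoffs
#'
#' Counts predicted post-translational modification sites per type at each
#' score cutoff, keeping only sites whose position falls inside the owning
#' sequence's linker span. A site is counted at cutoff `c` when its score
#' is `>= c` (inclusive, matching prediction-server cutoff semantics), so
#' counts are non-increasing in the cutoff.
#'
#' @param ptm Tibble with columns `seqid`, `position`, `ptm_type`, `score`
#'   (scores in `[0, 1]`).
#' @param segments Tibble with columns `seqid`, `linker_start`,
#'   `linker_end` (and optionally `sequence`, used to validate positions).
#' @param cutoffs Numeric cutoffs (default `c(0.8, 0.9)`).
#' @return Tibble of class `ptm_summary` with columns `ptm_type`, `cutoff`,
#'   `n_sites`, complete over all observed types at every cutoff.
#' @export
#' @examples
#' ptm <- tibble::tibble(seqid = "s1", position = c(5L, 6L),
#'                       ptm_type = "Phosphorylation", score = c(0.85, 0.95))
#' seg <- tibble::tibble(seqid = "s1", linker_start = 1L, linker_end = 10L)
#' summarize_ptms(ptm, seg)
summarize_ptms <- function(ptm, segments, cutoffs = c(0.8, 0.9)) {
  if (nrow(ptm) > 0 && (any(ptm$score < 0) || any(ptm$score > 1))) {
    abort("PTM scores must lie in [0, 1].")
  }
  seg <- dplyr::select(segments, "seqid", "linker_start", "linker_end",
                       dplyr::any_of("sequence"))
  joined <- dplyr::inner_join(ptm, seg, by = "seqid")
  if ("sequence" %in% names(joined) && nrow(joined) > 0) {
    bad <- which(joined$position > nchar(joined$sequence) | joined$position < 1)
    if (length(bad) > 0) {
      abort(sprintf("PTM site position %d is outside sequence %s (length %d).",
                    joined$position[bad[1]], joined$seqid[bad[1]],
                    nchar(joined$sequence[bad[1]])))
    }
  }
  in_linker <- dplyr::filter(joined, .data$position >= .data$linker_start,
                             .data$position <= .data$linker_end)
  types <- sort(unique(ptm$ptm_type))
  out <- tidyr::expand_grid(ptm_type = types, cutoff = sort(cutoffs))
  out$n_sites <- purrr::map2_int(out$ptm_type, out$cutoff, function(ty, co) {
    sum(in_linker$ptm_type == ty & in_linker$score >= co)
  })
  class(out) <- c("ptm_summary", class(out))
  out
}
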