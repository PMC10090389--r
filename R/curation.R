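# Homolog curation: parse hit and domain tables, apply the coverage/identity
# filters, classify domain architectures, and segment dual-LIM sequences
# into LIM1 / linker / LIM2.

#' Read a FASTA file of protein sequences
#'
#' Parses with `Biostrings` and additionally rejects duplicated sequence ids,
#' reporting the header line numbers of both occurrences.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `seqid` (first word of the header),
#'   `description` (rest of the header) and `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  hdr_lines <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr_lines]))
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    at <- hdr_lines[ids == d]
    abort(sprintf("Duplicated sequence id '%s' at lines %d and %d.",
                  d, at[1], at[2]))
  }
  aa <- Biostrings::readAAStringSet(path)
  full <- names(aa)
  tibble::tibble(
    seqid = sub("\\s.*$", "", full),
    description = ifelse(grepl("\\s", full),
                         sub("^\\S+\\s+", "", full), ""),
    sequence = as.character(aa, use.names = FALSE))
}

#' Read a homolog hit table
#'
#' BLAST-tabular-like TSV with a header; requires columns `qseqid`, `pident`
#' and `qcovs`. An optional `stitle` column provides the description used to
#' flag hypothetical entries: a hit is classed `hypothetical` when its
#' description contains "hypothetical" or "unnamed" (case-insensitive),
#' `annotated` otherwise.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `seqid`, `pident`, `qcov`,
#'   `annotation_status`, and `description` when present.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in c("qseqid", "pident", "qcovs")) {
    if (!col %in% names(raw)) {
      abort(paste0("Hit table is missing required column '", col, "'."))
    }
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) |
                   is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric %s value '%s' at line %d of %s.",
                    col, raw[[col]][bad[1]], bad[1] + 1L, path))
    }
    x
  }
  pident <- num("pident"); qcov <- num("qcovs")
  if (any(pident < 0 | pident > 100) || any(qcov < 0 | qcov > 100)) {
    abort("pident and qcovs must lie in [0, 100].")
  }
  desc <- raw[["stitle"]] %||% rep("", nrow(raw))
  out <- tibble::tibble(
    seqid = raw$qseqid, pident = pident, qcov = qcov,
    annotation_status = ifelse(
      grepl("hypothetical|unnamed", desc, ignore.case = TRUE),
      "hypothetical", "annotated"))
  if ("stitle" %in% names(raw)) out$description <- desc
  out
}

#' Filter hits on query coverage and percent identity
#'
#' Retains hits with `qcov > min_qcov` and `pident > min_pident` -- strictly
#' greater, so a hit at exactly 75% coverage is dropped. Idempotent; output
#' is always a subset of the input rows.
#'
#' @param hits Tibble from [read_hit_table()] (columns `qcov`, `pident`).
#' @param min_qcov Query-coverage threshold in percent (default 75).
#' @param min_pident Percent-identity threshold (default 30).
#' @return The retained rows.
#' @export
filter_hits <- function(hits, min_qcov = 75, min_pident = 30) {
  if (min_qcov < 0 || min_qcov > 100 || min_pident < 0 || min_pident > 100) {
    abort("Thresholds must lie in [0, 100].")
  }
  dplyr::filter(hits, .data$qcov > min_qcov, .data$pident > min_pident)
}

#' Read an HMMER3 per-domain table (domtblout)
#'
#' Whitespace-delimited hmmscan `--domtblout` layout: comment lines starting
#' with `#` are skipped; the alignment coordinate pair (columns 18-19) is
#' used as the domain span on the sequence.
#'
#' @param path Path to a domtblout file.
#' @return Tibble with columns `seqid`, `domain_name`, `ali_start`,
#'   `ali_end`, `score` (per-domain bit score), `seq_len` (query length).
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 19L) {
      abort(sprintf("Truncated domtblout row at line %d: %d columns, need >= 19.",
                    i, length(f)))
    }
    tibble::tibble(seqid = f[4], domain_name = f[1],
                   ali_start = as.integer(f[18]), ali_end = as.integer(f[19]),
                   score = as.numeric(f[14]), seq_len = as.integer(f[6]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(seqid = character(), domain_name = character(),
                          ali_start = integer(), ali_end = integer(),
                          score = numeric(), seq_len = integer())
  }
  out
}

# Greedy overlap resolution among LIM hits of one sequence: keep the higher
# bit-score hit whenever two spans share any residue.
resolve_lim_overlaps <- function(doms) {
  doms <- doms[order(-doms$score, doms$ali_start), ]
  kept <- doms[0, ]
  for (i in seq_len(nrow(doms))) {
    d <- doms[i, ]
    overlaps <- nrow(kept) > 0 &&
      any(d$ali_start <= kept$ali_end & d$ali_end >= kept$ali_start)
    if (!overlaps) kept <- dplyr::bind_rows(kept, d)
  }
  kept[order(kept$ali_start), ]
}

#' Classify domain architectures
#'
#' Per sequence: `dual-LIM` for exactly two non-overlapping LIM hits and no
#' other domain; `multi-LIM` for three or more LIM hits; `other` when any
#' non-LIM domain is present; `sub-threshold` otherwise (no surviving
#' domain hits). Overlapping LIM hits are resolved by keeping the higher
#' bit-score hit (greedy tiling), never by raising an error; the result is
#' invariant to the row order of the input.
#'
#' @param domains Tibble from [read_domtblout()].
#' @param seqids Optional character vector of all sequence ids to classify
#'   (sequences without any domain row classify as `sub-threshold`).
#' @param lim_pattern Regular expression identifying LIM domain names
#'   (default `"^LIM"`, case-insensitive).
#' @return Tibble with columns `seqid`, `architecture`, `n_lim`.
#' @export
classify_architecture <- function(domains, seqids = NULL,
                                  lim_pattern = "^LIM") {
  ids <- seqids %||% unique(domains$seqid)
  per <- function(id) {
    d <- dplyr::filter(domains, .data$seqid == id)
    is_lim <- grepl(lim_pattern, d$domain_name, ignore.case = TRUE)
    lim <- resolve_lim_overlaps(d[is_lim, , drop = FALSE])
    n_lim <- nrow(lim)
    arch <- if (any(!is_lim)) "other"
    else if (n_lim >= 3L) "multi-LIM"
    else if (n_lim == 2L) "dual-LIM"
    else "sub-threshold"
    tibble::tibble(seqid = id, architecture = arch, n_lim = n_lim)
  }
  if (length(ids) == 0L) {
    return(tibble::tibble(seqid = character(), architecture = character(),
                          n_lim = integer()))
  }
  purrr::map_dfr(ids, per)
}

#' Segment dual-LIM sequences into LIM1 / linker / LIM2
#'
#' The disordered linker is the span between the two LIM domain boundaries:
#' residues `lim1_end + 1` through `lim2_start - 1` (1-based inclusive
#' alignment coordinates), possibly empty when the domains abut. Terminal
#' tails outside LIM1..LIM2 are not part of any segment.
#'
#' @param sequences Tibble with columns `seqid`, `sequence` (from
#'   [read_fasta_tbl()] or a synthetic set).
#' @param domains Tibble from [read_domtblout()]; only sequences whose
#'   architecture is dual-LIM (see [classify_architecture()]) are segmented.
#' @param lim_pattern Regular expression for LIM domain names.
#' @return Tibble with one row per dual-LIM sequence: `seqid`, `sequence`,
#'   span columns `lim1_start`/`lim1_end`/`linker_start`/`linker_end`/
#'   `lim2_start`/`lim2_end`, extracted `lim1_seq`, `linker_seq`, `lim2_seq`
#'   and `linker_length`.
#' @export
segment_sequences <- function(sequences, domains, lim_pattern = "^LIM") {
  arch <- classify_architecture(domains, seqids = sequences$seqid,
                                lim_pattern = lim_pattern)
  dual <- arch$seqid[arch$architecture == "dual-LIM"]
  per <- function(id) {
    seq <- sequences$sequence[sequences$seqid == id]
    d <- dplyr::filter(domains, .data$seqid == id,
                       grepl(lim_pattern, .data$domain_name,
                             ignore.case = TRUE))
    d <- resolve_lim_overlaps(d)
    segment_one(id, seq, d$ali_start[1], d$ali_end[1],
                d$ali_start[2], d$ali_end[2])
  }
  if (length(dual) == 0L) {
    return(segment_one("", strrep("A", 20), 1L, 6L, 15L, 20L)[0, ])
  }
  purrr::map_dfr(dual, per)
}

# Segment one sequence given ordered LIM spans (1-based inclusive).
segment_one <- function(seqid, seq, l1s, l1e, l2s, l2e) {
  if (l1e >= l2s) {
    abort(sprintf("LIM domains out of order for %s: LIM1 ends at %d but LIM2 starts at %d.",
                  seqid, l1e, l2s))
  }
  if (l2e > nchar(seq)) {
    abort(sprintf("LIM2 span [%d,%d] exceeds sequence length %d for %s.",
                  l2s, l2e, nchar(seq), seqid))
  }
  ls <- l1e + 1L; le <- l2s - 1L
  tibble::tibble(
    seqid = seqid, sequence = seq,
    lim1_start = l1s, lim1_end = l1e,
    linker_start = ls, linker_end = le,
    lim2_start = l2s, lim2_end = l2e,
    lim1_seq = substr(seq, l1s, l1e),
    linker_seq = if (le >= ls) substr(seq, ls, le) else "",
    lim2_seq = substr(seq, l2s, l2e),
    linker_length = max(0L, le - ls + 1L))
}
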