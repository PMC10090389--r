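# Synthetic homolog sets: every input the sequence pipeline consumes,
# generated with known ground truth so all downstream stages are testable
# without database retrieval.

#' Specify a synthetic dual-LIM homolog set
#'
#' Describes the study conditions for a simulated set of CSRP-like homologs:
#' dual-LIM architectures whose linker lengths follow a three-component
#' (trimodal) Gaussian mixture, with configurable linker amino-acid
#' enrichment, decoy architectures, taxonomy labels and hit-table metadata.
#'
#' @param n_sequences Number of sequences to generate.
#' @param mixture_weights Length-3 vector of mixture proportions (must sum
#'   to 1). Default `c(0.2, 0.6, 0.2)`: medium linkers dominate, as in real
#'   homolog sets where the central mode is the highest peak.
#' @param mixture_means Length-3 vector of mean linker lengths in residues.
#'   Default `c(20, 52, 90)`: a short plant-like mode, a central mode near the
#'   53-residue human linker, and a long nematode-like mode.
#' @param mixture_sds Length-3 vector of linker-length standard deviations in
#'   residues (default 3 each; a zero gives an exact, degenerate component).
#' @param linker_enrichment Named vector of relative sampling weights per
#'   amino acid for linker residues; unnamed residues get weight 1. The
#'   default enriches the disorder-promoting residues P, Q, S, N and T
#'   threefold over background.
#' @param lim_length LIM domain length in residues (default 57, the typical
#'   LIM length in CSRP proteins; must be at least 8 to hold the zinc-binding
#'   anchor residues).
#' @param taxonomy_plan Optional tibble with columns `taxon`, `phylum`,
#'   `count` and `linker_class` (one of `"short"`, `"medium"`, `"long"`, or
#'   `NA` for free assignment). Counts must sum to `n_sequences`. When `NULL`,
#'   taxa are assigned from the true linker class (short -> Magnoliopsida /
#'   Streptophyta, medium -> Mammalia / Chordata, long -> Chromadorea /
#'   Nematoda).
#' @param decoy_fraction Fraction of sequences generated as non-dual-LIM
#'   decoys (multi-LIM, other-domain, and domain-free architectures in equal
#'   parts). Default 0.1.
#' @param subthreshold_fraction Fraction of hit-table rows drawn below the
#'   standard query-coverage/identity filter thresholds so that hit values
#'   straddle 75% coverage and 30% identity. Default 0.15.
#' @param hypothetical_fraction Fraction of hits described as "hypothetical
#'   protein" or "unnamed protein product". Default 0.1.
#' @param missing_lineage_fraction Fraction of sequences omitted from the
#'   lineage table (downstream they tally under "Unclassified"). Default 0.02.
#' @param seed Integer seed; the whole artifact set is deterministic given
#'   the spec and seed.
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [simulate_homolog_set()]
#' @export
synthetic_spec <- function(n_sequences,
                           mixture_weights = c(0.2, 0.6, 0.2),
                           mixture_means = c(20, 52, 90),
                           mixture_sds = c(3, 3, 3),
                           linker_enrichment = c(P = 3, Q = 3, S = 3, N = 3, T = 3),
                           lim_length = 57,
                           taxonomy_plan = NULL,
                           decoy_fraction = 0.1,
                           subthreshold_fraction = 0.15,
                           hypothetical_fraction = 0.1,
                           missing_lineage_fraction = 0.02,
                           seed = 1L) {
  if (length(mixture_weights) != 3 || length(mixture_means) != 3 ||
      length(mixture_sds) != 3) {
    abort("mixture_weights, mixture_means and mixture_sds must each have length 3.")
  }
  if (abs(sum(mixture_weights) - 1) > 1e-12) {
    abort("mixture_weights must sum to 1 (within 1e-12).")
  }
  if (any(mixture_weights < 0)) abort("mixture_weights must be non-negative.")
  if (any(mixture_means <= 0)) abort("mixture_means must be positive.")
  if (any(mixture_sds < 0)) abort("mixture_sds must be non-negative.")
  if (lim_length < 8) abort("lim_length must be at least 8 residues.")
  if (n_sequences < 1) abort("n_sequences must be at least 1.")
  for (p in c(decoy_fraction, subthreshold_fraction, hypothetical_fraction,
              missing_lineage_fraction)) {
    if (p < 0 || p > 1) abort("Fractions must lie in [0, 1].")
  }
  if (!is.null(taxonomy_plan)) {
    req <- c("taxon", "phylum", "count", "linker_class")
    if (!all(req %in% names(taxonomy_plan))) {
      abort("taxonomy_plan needs columns taxon, phylum, count, linker_class.")
    }
    if (sum(taxonomy_plan$count) != n_sequences) {
      abort("taxonomy_plan counts must sum to n_sequences.")
    }
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         mixture_weights = as.numeric(mixture_weights),
         mixture_means = as.numeric(mixture_means),
         mixture_sds = as.numeric(mixture_sds),
         linker_enrichment = linker_enrichment,
         lim_length = as.integer(lim_length),
         taxonomy_plan = taxonomy_plan,
         decoy_fraction = decoy_fraction,
         subthreshold_fraction = subthreshold_fraction,
         hypothetical_fraction = hypothetical_fraction,
         missing_lineage_fraction = missing_lineage_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Draw linker lengths from a trimodal mixture
#'
#' @param n Number of lengths.
#' @param weights,means,sds Length-3 mixture parameters (weights sum to 1,
#'   means ascending is not required; classes are labelled by sorted means).
#' @param seed Optional seed; when `NULL` the caller's RNG stream is used.
#' @return Tibble with columns `length` (integer residues, non-negative) and
#'   `class` (`"short"`, `"medium"`, `"long"` by ascending component mean).
#' @export
simulate_linker_lengths <- function(n, weights = c(0.2, 0.6, 0.2),
                                    means = c(20, 52, 90), sds = c(3, 3, 3),
                                    seed = NULL) {
  draw <- function() {
    comp <- sample.int(3L, n, replace = TRUE, prob = weights)
    len <- pmax(0L, as.integer(round(rnorm(n, means[comp], sds[comp]))))
    rank <- rank(means, ties.method = "first")
    cls <- c("short", "medium", "long")[rank[comp]]
    tibble::tibble(length = len, class = cls)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# A LIM-like segment: random residues seeded with the consensus zinc-binding
# anchor pattern (C..C...H..C twice). Domain boundaries are supplied through
# the domain table downstream, so profile fidelity is not needed.
make_lim_seq <- function(len) {
  s <- strsplit(sample_residues(len), "")[[1]]
  anchors <- unique(pmin(len, pmax(1L, round(len * c(0.04, 0.12, 0.42, 0.50,
                                                     0.56, 0.65, 0.88, 0.96)))))
  res <- rep(c("C", "C", "H", "C"), 2)[seq_along(anchors)]
  s[anchors] <- res
  paste(s, collapse = "")
}

#' Generate a synthetic homolog set with ground truth
#'
#' Produces every input the sequence pipeline consumes -- protein sequences,
#' a BLAST-tabular-like hit table, an HMMER domtblout-style domain table and
#' a taxonomy lineage table -- together with a truth table recording, for
#' every sequence, its architecture, whether its hit passes the standard
#' filters, its true linker length and class, and its taxonomy labels.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `homolog_set` with elements `sequences`, `hits`,
#'   `domains`, `lineage`, `truth` (tibbles) and `spec`.
#' @export
#' @examples
#' set <- simulate_homolog_set(synthetic_spec(25, seed = 42))
#' dplyr::count(set$truth, architecture)
simulate_homolog_set <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("spec must be created with synthetic_spec().")
  }
  with_seed(spec$seed, build_homolog_set(spec))
}

build_homolog_set <- function(spec) {
  n <- spec$n_sequences
  seqid <- sprintf("SYN%05d.1", seq_len(n))

  # architecture assignment: dual-LIM majority, decoys split evenly
  n_decoy <- round(spec$decoy_fraction * n)
  arch <- rep("dual-LIM", n)
  if (n_decoy > 0) {
    decoy_types <- rep(c("multi-LIM", "other", "sub-threshold"),
                       length.out = n_decoy)
    arch[sample.int(n, n_decoy)] <- sample(decoy_types)
  }

  # per-sequence linker class/length (dual-LIM only carries truth)
  if (is.null(spec$taxonomy_plan)) {
    ll <- simulate_linker_lengths(n, spec$mixture_weights, spec$mixture_means,
                                  spec$mixture_sds)
    lin_class <- ll$class
    lin_len <- ll$length
    taxon <- c(short = "Magnoliopsida", medium = "Mammalia",
               long = "Chromadorea")[lin_class]
    phylum <- c(short = "Streptophyta", medium = "Chordata",
                long = "Nematoda")[lin_class]
  } else {
    plan <- spec$taxonomy_plan
    idx <- rep(seq_len(nrow(plan)), plan$count)
    idx <- sample(idx)
    taxon <- plan$taxon[idx]
    phylum <- plan$phylum[idx]
    forced <- plan$linker_class[idx]
    free <- simulate_linker_lengths(n, spec$mixture_weights,
                                    spec$mixture_means, spec$mixture_sds)
    rank <- rank(spec$mixture_means, ties.method = "first")
    comp_of <- setNames(order(spec$mixture_means), c("short", "medium", "long"))
    lin_class <- ifelse(is.na(forced), free$class, forced)
    comp <- comp_of[lin_class]
    lin_len <- ifelse(is.na(forced), free$length,
                      pmax(0L, as.integer(round(rnorm(
                        n, spec$mixture_means[comp], spec$mixture_sds[comp])))))
  }

  L <- spec$lim_length
  seqs <- character(n)
  dom_rows <- vector("list", n)
  for (j in seq_len(n)) {
    tail_n <- sample.int(9L, 1L) - 1L   # 0..8 residue N-terminal tail
    tail_c <- sample.int(9L, 1L) - 1L
    a <- arch[j]
    if (a == "sub-threshold") {
      seqs[j] <- sample_residues(2L * L + lin_len[j] + tail_n + tail_c)
      dom_rows[[j]] <- NULL
      next
    }
    lim1 <- make_lim_seq(L)
    linker <- sample_residues(lin_len[j], spec$linker_enrichment)
    lim2 <- make_lim_seq(L)
    body <- paste0(lim1, linker, lim2)
    doms <- tibble::tibble(
      seqid = seqid[j],
      domain_name = "LIM",
      ali_start = c(tail_n + 1L, tail_n + L + lin_len[j] + 1L),
      ali_end = c(tail_n + L, tail_n + 2L * L + lin_len[j]),
      score = round(runif(2, 40, 80), 1))
    if (a == "multi-LIM") {
      gap2 <- sample(10:30, 1L)
      lim3 <- make_lim_seq(L)
      body <- paste0(body, sample_residues(gap2, spec$linker_enrichment), lim3)
      st <- tail_n + 2L * L + lin_len[j] + gap2 + 1L
      doms <- dplyr::bind_rows(doms, tibble::tibble(
        seqid = seqid[j], domain_name = "LIM",
        ali_start = st, ali_end = st + L - 1L,
        score = round(runif(1, 40, 80), 1)))
    } else if (a == "other") {
      pdz <- sample_residues(80L)
      body <- paste0(body, pdz)
      st <- tail_n + 2L * L + lin_len[j] + 1L
      doms <- dplyr::bind_rows(doms, tibble::tibble(
        seqid = seqid[j], domain_name = "PDZ",
        ali_start = st, ali_end = st + 79L,
        score = round(runif(1, 30, 60), 1)))
    }
    seqs[j] <- paste0(sample_residues(tail_n), body, sample_residues(tail_c))
    dom_rows[[j]] <- doms
  }
  domains <- dplyr::bind_rows(dom_rows)
  domains$seq_len <- nchar(seqs)[match(domains$seqid, seqid)]

  # hit table: values straddle the 75/30 filter thresholds
  below <- runif(n) < spec$subthreshold_fraction
  qcov <- ifelse(below, runif(n, 40, 75), runif(n, 75 + 1e-3, 100))
  pident <- runif(n, 30 + 1e-3, 95)
  flip <- below & (runif(n) < 0.5)   # half of the below rows fail on identity
  pident[flip] <- runif(sum(flip), 10, 30)
  qcov[flip] <- runif(sum(flip), 76, 100)
  qcov <- round(qcov, 1); pident <- round(pident, 2)
  hypo <- runif(n) < spec$hypothetical_fraction
  stitle <- ifelse(hypo,
                   sample(c("hypothetical protein", "unnamed protein product"),
                          n, replace = TRUE),
                   "cysteine and glycine-rich protein")
  hits <- tibble::tibble(qseqid = seqid, pident = pident, qcovs = qcov,
                         stitle = stitle)

  in_lineage <- runif(n) >= spec$missing_lineage_fraction
  lineage <- tibble::tibble(seqid = seqid, phylum = phylum, class = taxon)[in_lineage, ]

  truth <- tibble::tibble(
    seqid = seqid,
    architecture = arch,
    passes_filter = qcov > 75 & pident > 30,
    linker_length = ifelse(arch %in% c("dual-LIM", "multi-LIM", "other"),
                           lin_len, NA_integer_),
    linker_class = ifelse(arch == "dual-LIM", lin_class, NA_character_),
    taxon = taxon, phylum = phylum, in_lineage = in_lineage)

  structure(list(
    sequences = tibble::tibble(seqid = seqid, description = stitle,
                               sequence = seqs),
    hits = hits, domains = domains, lineage = lineage, truth = truth,
    spec = spec), class = "homolog_set")
}

#' Write a synthetic homolog set to disk
#'
#' Emits `homologs.fasta` (60-column wrapped), `hits.tsv`,
#' `domains.domtblout` (HMMER3 per-domain tabular layout) and `lineage.tsv`.
#' Output is byte-identical across runs for the same spec and seed.
#'
#' @param set A `homolog_set` from [simulate_homolog_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_homolog_set <- function(set, dir) {
  if (!inherits(set, "homolog_set")) abort("set must be a homolog_set.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "homologs.fasta"),
             hits = file.path(dir, "hits.tsv"),
             domains = file.path(dir, "domains.domtblout"),
             lineage = file.path(dir, "lineage.tsv"))
  aa <- Biostrings::AAStringSet(setNames(set$sequences$sequence,
                                         paste(set$sequences$seqid,
                                               set$sequences$description)))
  Biostrings::writeXStringSet(aa, paths[["fasta"]], width = 60L)
  readr::write_tsv(set$hits, paths[["hits"]])
  write_domtblout(set$domains, paths[["domains"]])
  readr::write_tsv(set$lineage, paths[["lineage"]])
  invisible(paths)
}

# HMMER 3.1 per-domain tabular output (domtblout), hmmscan orientation:
# target = domain model, query = sequence; ali coords in columns 18-19.
write_domtblout <- function(domains, path) {
  hdr <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- character(0)
  if (nrow(domains) > 0) {
    d <- domains
    ord <- order(d$seqid, d$ali_start)
    d <- d[ord, ]
    ndom <- stats::ave(seq_len(nrow(d)), d$seqid, FUN = seq_along)
    ntot <- stats::ave(seq_len(nrow(d)), d$seqid, FUN = length)
    dlen <- d$ali_end - d$ali_start + 1L
    qlen <- d$seq_len %||% (d$ali_end + 5L)
    rows <- sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
      d$domain_name, "-", dlen, d$seqid, "-", qlen,
      1e-20, d$score + 2, 0.1, ndom, ntot, 1e-18, 1e-15, d$score, 0.1,
      1L, dlen, d$ali_start, d$ali_end,
      pmax(1L, d$ali_start - 2L), pmin(qlen, d$ali_end + 2L),
      0.95, "synthetic domain hit")
  }
  writeLines(c(hdr, rows, "#"), path)
}

#' Generate a synthetic PTM prediction table with ground truth
#'
#' Emulates the tabular output of a PTM prediction server: one scored site
#' per row, with types drawn from a configurable mix and positions placed
#' inside linker spans. Truth counts per type at each cutoff are recorded at
#' generation time.
#'
#' @param n_sites Number of predicted sites (may be 0).
#' @param type_mix Named numeric vector of relative weights per PTM type.
#'   The default mix is dominated by phosphorylation, with glycosylation,
#'   methylation, SUMOylation, acetylation, hydroxylation and palmitoylation
#'   at decreasing rates, as observed for disordered-region predictions.
#' @param seed Integer seed.
#' @param segments Optional segment table (see [segment_sequences()]); site
#'   positions are sampled uniformly inside each chosen sequence's linker
#'   span. When `NULL`, a single synthetic sequence with a 1..100 linker span
#'   is used (returned in `$segments`).
#' @param score_fun Function `n -> n scores in [0, 1]`; default uniform.
#' @param cutoffs Score cutoffs at which truth counts are tabulated.
#' @return List with `ptm` (tibble: seqid, position, ptm_type, score),
#'   `truth` (tibble: ptm_type, cutoff, n_sites) and `segments`.
#' @export
simulate_ptm_table <- function(n_sites,
                               type_mix = c(Phosphorylation = 0.56,
                                            Glycosylation = 0.15,
                                            Methylation = 0.10,
                                            SUMOylation = 0.09,
                                            Acetylation = 0.07,
                                            Hydroxylation = 0.028,
                                            Palmitoylation = 0.002),
                               seed = 1L, segments = NULL, score_fun = NULL,
                               cutoffs = c(0.8, 0.9)) {
  if (n_sites < 0) abort("n_sites must be non-negative.")
  score_fun <- score_fun %||% stats::runif
  if (is.null(segments)) {
    segments <- tibble::tibble(seqid = "SYNPTM1", linker_start = 1L,
                               linker_end = 100L)
  }
  with_seed(seed, {
    types <- names(type_mix)
    if (n_sites == 0) {
      ptm <- tibble::tibble(seqid = character(), position = integer(),
                            ptm_type = character(), score = numeric())
    } else {
      i <- sample.int(nrow(segments), n_sites, replace = TRUE)
      pos <- segments$linker_start[i] +
        floor(runif(n_sites) * (segments$linker_end[i] -
                                  segments$linker_start[i] + 1L))
      score <- pmin(1, pmax(0, score_fun(n_sites)))
      ptm <- tibble::tibble(
        seqid = segments$seqid[i],
        position = as.integer(pos),
        ptm_type = sample(types, n_sites, replace = TRUE,
                          prob = type_mix / sum(type_mix)),
        score = score)
    }
    truth <- tidyr::expand_grid(ptm_type = types, cutoff = cutoffs)
    truth$n_sites <- purrr::map2_int(truth$ptm_type, truth$cutoff,
                                     ~ sum(ptm$ptm_type == .x & ptm$score >= .y))
    list(ptm = ptm, truth = truth, segments = segments)
  })
}
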