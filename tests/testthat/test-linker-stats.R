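# Length distributions, propensity statistic, taxonomy and PTM summaries.

test_that("length histogram counts sum to the segment count with a modal bin", {
  segs <- tibble::tibble(linker_length = rep(20L, 10),
                         lim1_start = 1L, lim1_end = 57L,
                         lim2_start = 78L, lim2_end = 134L)
  h <- region_length_distribution(segs, "linker", bin_width = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n, 10L)
  expect_equal(attr(h, "modal_bin"), 20)
  expect_error(region_length_distribution(segs[0, ]), "No segments")
})

test_that("trimodal sets show local maxima near the generator modes", {
  set <- simulate_homolog_set(synthetic_spec(400, decoy_fraction = 0,
                                             seed = 31))
  segs <- segment_sequences(set$sequences, set$domains)
  h <- region_length_distribution(segs, "linker", bin_width = 5)
  mass <- function(lo, hi) sum(h$n[h$bin_start >= lo & h$bin_start <= hi])
  # each mode window outweighs both inter-mode valleys: three local maxima
  valleys <- max(mass(30, 40), mass(65, 80))
  expect_gt(mass(15, 25), valleys)
  expect_gt(mass(45, 55), valleys)
  expect_gt(mass(85, 95), valleys)
  hl <- region_length_distribution(segs, "LIM1")
  expect_equal(attr(hl, "modal_bin"), 57)
  expect_equal(sum(hl$n), nrow(segs))
})

test_that("hand-counted worked example: P enriched threefold, A absent", {
  seg <- tibble::tibble(lim1_seq = "AC", linker_seq = "PP", lim2_seq = "AC",
                        linker_length = 2L)
  p <- compute_propensity(seg)
  expect_equal(p$propensity[p$aa == "P"], 3)
  expect_equal(p$propensity[p$aa == "A"], 0)
  expect_equal(p$f_linker[p$aa == "P"], 1)
  expect_equal(p$f_total[p$aa == "P"], 2 / 6)
  expect_true(is.na(p$propensity[p$aa == "W"]))  # absent everywhere
})

test_that("a linker matching the overall composition has unit propensity", {
  seg <- tibble::tibble(lim1_seq = "ACDE", linker_seq = "ACDE",
                        lim2_seq = "ACDE", linker_length = 4L)
  p <- compute_propensity(seg)
  defined <- !is.na(p$propensity) & p$f_linker > 0
  expect_true(all(abs(p$propensity[defined] - 1) < 1e-12))
})

test_that("propensity matches the naive counting oracle to 1e-12", {
  for (s in c(101, 202, 303)) {
    set <- simulate_homolog_set(synthetic_spec(sample(5:40, 1), seed = s))
    segs <- segment_sequences(set$sequences, set$domains)
    p <- compute_propensity(segs)
    o <- oracle_propensity(segs)
    expect_equal(p$propensity, o$propensity, tolerance = 1e-12)
    expect_lt(abs(sum(p$propensity * p$f_total, na.rm = TRUE) - 1), 1e-9)
  }
})

test_that("zero total linker length is an error", {
  seg <- tibble::tibble(lim1_seq = "AC", linker_seq = "", lim2_seq = "AC",
                        linker_length = 0L)
  expect_error(compute_propensity(seg), "linker length is zero")
})

test_that("enriched disorder-promoting residues rank highest in propensity", {
  set <- simulate_homolog_set(synthetic_spec(150, decoy_fraction = 0,
                                             seed = 44))
  segs <- segment_sequences(set$sequences, set$domains)
  p <- compute_propensity(segs)
  top5 <- p$aa[order(-p$propensity)][1:5]
  expect_setequal(top5, c("P", "Q", "S", "N", "T"))
})

test_that("taxonomy frequencies normalise per taxon and honour Unclassified", {
  labels <- tibble::tibble(seqid = c("a", "b", "c", "d", "e"),
                           linker_class = c("short", "short", "long", "long",
                                            "medium"))
  lineage <- tibble::tibble(seqid = c("a", "b", "c", "d"),
                            phylum = "Chordata", class = "Mammalia")
  tf <- taxonomy_frequency(labels, lineage, rank = "class")
  mam <- tf[tf$taxon == "Mammalia", ]
  expect_equal(setNames(mam$freq, mam$linker_class),
               c(short = 0.5, medium = 0, long = 0.5))
  expect_true("Unclassified" %in% tf$taxon)
  sums <- tapply(tf$freq, tf$taxon, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("taxonomy frequencies are invariant to lineage row order", {
  set <- small_set(50, seed = 13)
  segs <- segment_sequences(set$sequences, set$domains)
  labels <- tibble::tibble(
    seqid = segs$seqid,
    linker_class = classify_linker_lengths(segs$linker_length))
  t1 <- taxonomy_frequency(labels, set$lineage)
  t2 <- taxonomy_frequency(labels, set$lineage[sample(nrow(set$lineage)), ])
  expect_equal(t1, t2)
})

test_that("PTM counting is inclusive at the cutoff and span-filtered", {
  seg <- tibble::tibble(seqid = "s1", sequence = paste(rep("A", 200),
                                                       collapse = ""),
                        linker_start = 58L, linker_end = 110L)
  ptm <- tibble::tibble(seqid = "s1",
                        position = c(60L, 70L, 20L, 90L),
                        ptm_type = "Phosphorylation",
                        score = c(0.85, 0.95, 0.99, 0.9))
  s <- summarize_ptms(ptm, seg)
  expect_equal(s$n_sites[s$cutoff == 0.8], 3L)   # position 20 is in LIM1
  expect_equal(s$n_sites[s$cutoff == 0.9], 2L)   # 0.9 counts inclusively
  expect_error(
    summarize_ptms(dplyr::mutate(ptm, position = c(60L, 70L, 20L, 300L)),
                   seg),
    "outside sequence")
  expect_error(summarize_ptms(dplyr::mutate(ptm, score = score + 1), seg),
               "\\[0, 1\\]")
})

test_that("PTM counts never increase with the cutoff", {
  for (s in 1:5) {
    out <- simulate_ptm_table(300, seed = s)
    tab <- summarize_ptms(out$ptm, out$segments, cutoffs = c(0.5, 0.8, 0.9))
    wide <- tidyr::pivot_wider(tab, names_from = "cutoff",
                               values_from = "n_sites")
    expect_true(all(wide$`0.9` <= wide$`0.8`))
    expect_true(all(wide$`0.8` <= wide$`0.5`))
  }
})
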