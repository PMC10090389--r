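# Synthetic-data generators: validation, determinism, ground-truth
# consistency and composition control.

test_that("spec validation rejects malformed mixtures and fractions", {
  expect_error(synthetic_spec(10, mixture_weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(10, mixture_means = c(-5, 52, 90)), "positive")
  expect_error(synthetic_spec(10, lim_length = 5), "at least 8")
  expect_error(synthetic_spec(10, decoy_fraction = 1.5), "\\[0, 1\\]")
})

test_that("a zero-variance component yields exact linker lengths", {
  spec <- synthetic_spec(10, mixture_weights = c(1, 0, 0),
                         mixture_means = c(20, 52, 90),
                         mixture_sds = c(0, 3, 3),
                         decoy_fraction = 0, seed = 5)
  set <- simulate_homolog_set(spec)
  expect_true(all(set$truth$linker_length == 20L))
  segs <- segment_sequences(set$sequences, set$domains)
  expect_equal(nrow(segs), 10L)
  expect_true(all(segs$linker_length == 20L))
  expect_true(all(nchar(segs$linker_seq) == 20L))
})

test_that("empirical class proportions match mixture weights at n = 1000", {
  ll <- simulate_linker_lengths(1000, weights = c(0.2, 0.6, 0.2),
                                means = c(20, 52, 90), sds = c(3, 3, 3),
                                seed = 1)
  props <- as.numeric(table(factor(ll$class,
                                   c("short", "medium", "long"))) / 1000)
  expect_true(all(abs(props - c(0.2, 0.6, 0.2)) < 0.04))
})

test_that("the same spec and seed give byte-identical artifacts", {
  spec <- synthetic_spec(25, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_homolog_set(simulate_homolog_set(spec), d1)
  p2 <- write_homolog_set(simulate_homolog_set(spec), d2)
  for (k in names(p1)) expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("domain-table coordinates delimit the constructed LIM segments", {
  set <- small_set(40, seed = 3)
  segs <- segment_sequences(set$sequences, set$domains)
  truth <- set$truth[match(segs$seqid, set$truth$seqid), ]
  expect_equal(segs$linker_length, as.integer(truth$linker_length))
  # LIM spans carry the anchor cysteine pattern start
  expect_true(all(nchar(segs$lim1_seq) == set$spec$lim_length))
  expect_true(all(nchar(segs$lim2_seq) == set$spec$lim_length))
})

test_that("linker residue enrichment is proportional to its weights", {
  spec <- synthetic_spec(60, mixture_means = c(30, 52, 90),
                         linker_enrichment = c(P = 4), decoy_fraction = 0,
                         seed = 8)
  set <- simulate_homolog_set(spec)
  segs <- segment_sequences(set$sequences, set$domains)
  linker <- paste(segs$linker_seq, collapse = "")
  n <- nchar(linker)
  expect_gt(n, 1000)
  p_expected <- 4 / (19 + 4)
  p_hat <- lengths(regmatches(linker, gregexpr("P", linker))) / n
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(p_hat - p_expected), 3 * se)
})

test_that("hit-table values straddle the filter thresholds and flag truth", {
  set <- small_set(200, seed = 21)
  expect_true(any(set$hits$qcovs <= 75 | set$hits$pident <= 30))
  expect_true(any(set$hits$qcovs > 75 & set$hits$pident > 30))
  expect_equal(set$truth$passes_filter,
               set$hits$qcovs > 75 & set$hits$pident > 30)
})

test_that("a taxonomy plan forces linker classes per taxon", {
  plan <- tibble::tibble(
    taxon = c("Magnoliopsida", "Mammalia", "Chromadorea"),
    phylum = c("Streptophyta", "Chordata", "Nematoda"),
    count = c(10L, 20L, 10L),
    linker_class = c("short", "medium", "long"))
  set <- simulate_homolog_set(
    synthetic_spec(40, taxonomy_plan = plan, decoy_fraction = 0, seed = 2))
  tr <- set$truth
  expect_equal(sort(unique(tr$taxon)), sort(plan$taxon))
  expect_true(all(tr$linker_class[tr$taxon == "Chromadorea"] == "long"))
  expect_true(all(tr$linker_class[tr$taxon == "Magnoliopsida"] == "short"))
})

test_that("trajectory truth distances are recoverable from the PDB text", {
  sim <- simulate_trajectory(50, collapse_frame = 25, seed = 17)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim, f)
  traj <- read_multimodel_pdb(f)
  expect_equal(n_frames(traj), 50L)
  ds <- interdomain_distance_series(traj, sim$markers$res_i,
                                    sim$markers$res_j)
  # PDB coordinates carry 3 decimals, so recomputed distances agree to ~1e-3
  expect_lt(max(abs(ds$distance - sim$truth$distance)), 0.01)
  expect_lt(abs(ds$distance[1] - 120), 2 + 0.01)
  expect_lt(abs(ds$distance[50] - 35), 2 + 0.01)
})

test_that("trajectory backbone has physical bond lengths", {
  sim <- simulate_trajectory(3, collapse_frame = 2, seed = 1)
  x <- sim$trajectory$coords[, , 2]
  a <- sim$trajectory$atoms
  n_ca <- sqrt(rowSums((x[which(a$atom == "N"), ] -
                          x[which(a$atom == "CA"), ])^2))
  ca_c <- sqrt(rowSums((x[which(a$atom == "CA"), ] -
                          x[which(a$atom == "C"), ])^2))
  expect_true(all(abs(n_ca - 1.458) < 1e-6))
  expect_true(all(abs(ca_c - 1.525) < 1e-6))
})

test_that("single-frame trajectory has truth distance exactly at start", {
  sim <- simulate_trajectory(1, collapse_frame = 1, seed = 9)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$distance, 120)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim, f)
  expect_equal(n_frames(read_multimodel_pdb(f)), 1L)
})

test_that("trajectory generation is deterministic and validates inputs", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(simulate_trajectory(5, 3, seed = 4), f1)
  write_pdb(simulate_trajectory(5, 3, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_trajectory(5, 9, seed = 1), "collapse_frame")
  expect_error(simulate_trajectory(5, 2, start_distance = -1), "positive")
})

test_that("PTM generator truth counts match the summariser exactly", {
  out <- simulate_ptm_table(500, seed = 7)
  s <- summarize_ptms(out$ptm, out$segments)
  joined <- dplyr::left_join(out$truth, s, by = c("ptm_type", "cutoff"))
  joined$n_sites.y[is.na(joined$n_sites.y)] <- 0L
  expect_equal(joined$n_sites.x, joined$n_sites.y)
})

test_that("degenerate PTM tables behave: empty input and saturated scores", {
  empty <- simulate_ptm_table(0, seed = 1)
  expect_equal(nrow(empty$ptm), 0L)
  expect_true(all(empty$truth$n_sites == 0L))
  hi <- simulate_ptm_table(100, seed = 2,
                           score_fun = function(n) runif(n, 0.95, 1))
  t8 <- hi$truth$n_sites[hi$truth$cutoff == 0.8]
  t9 <- hi$truth$n_sites[hi$truth$cutoff == 0.9]
  expect_equal(t8, t9)
  expect_equal(sum(t8), 100L)
})
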