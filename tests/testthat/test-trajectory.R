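# Trajectory reading and geometric summaries.

# tiny hand-built trajectory: nres residues on a line, one frame per column
toy_traj <- function(coords_list, atoms = NULL) {
  n <- nrow(coords_list[[1]])
  if (is.null(atoms)) {
    atoms <- tibble::tibble(
      serial = seq_len(n), atom = rep(c("N", "CA", "C", "O"), n / 4),
      resname = "GLY", chain = "A", resno = rep(seq_len(n / 4), each = 4))
  }
  arr <- array(unlist(coords_list), c(n, 3, length(coords_list)))
  new_trajectory(atoms, arr)
}

# non-degenerate 2-residue backbone scaffold
scaffold <- function() {
  matrix(c(0, 0, 0,   1.5, 0, 0,   2, 1.4, 0,   2, 2, 1,
           3, 1.5, 1,  4.2, 2, 1,  5, 3, 0.5,  5.5, 4, 1), ncol = 3,
         byrow = TRUE)
}

test_that("multi-model PDB files round-trip and degenerate files are caught", {
  sim <- simulate_trajectory(3, 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim, f)
  traj <- read_multimodel_pdb(f)
  expect_equal(n_frames(traj), 3L)
  expect_equal(traj$atoms$resno, sim$trajectory$atoms$resno)

  lines <- readLines(f)
  drop <- which(grepl("^ATOM", lines))[nrow(sim$trajectory$atoms) + 5L]
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-drop], f2)
  expect_error(read_multimodel_pdb(f2), "model 2")

  # no MODEL records: whole file is one frame
  one <- lines[grepl("^ATOM", lines)][seq_len(nrow(sim$trajectory$atoms))]
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(one, "END"), f3)
  expect_equal(n_frames(read_multimodel_pdb(f3)), 1L)
})

test_that("rmsd is zero at the reference and for identical frames", {
  s <- scaffold()
  traj <- toy_traj(list(s, s, s))
  r <- rmsd_series(traj)
  expect_equal(r$rmsd, c(0, 0, 0), tolerance = 1e-9)
  sim <- simulate_trajectory(5, 3, seed = 2)
  r2 <- rmsd_series(sim$trajectory)
  expect_equal(r2$rmsd[1], 0)
  expect_true(all(r2$rmsd >= 0))
})

test_that("rmsd equals the direct formula after oracle superposition", {
  sim <- simulate_trajectory(6, 3, seed = 8)
  traj <- sim$trajectory
  idx <- which(traj$atoms$atom %in% c("N", "CA", "C", "O"))
  ref <- traj$coords[idx, , 1]
  r <- rmsd_series(traj)
  for (f in c(2L, 5L)) {
    k <- kabsch_superpose(traj$coords[idx, , f], ref)
    direct <- sqrt(mean(rowSums((k$transformed - ref)^2)))
    expect_equal(r$rmsd[f], direct, tolerance = 1e-6)
  }
})

test_that("rmsf reproduces the closed form for one oscillating residue", {
  s <- scaffold()
  # 80 static residues pin the superposition; two extra residues oscillate
  base <- do.call(rbind, lapply(0:39, function(k) sweep(s, 2, c(0, 0, 3 * k), `+`)))
  d <- 0.75
  up <- rbind(base, sweep(s, 2, c(10, 0, d), `+`))
  dn <- rbind(base, sweep(s, 2, c(10, 0, -d), `+`))
  traj <- toy_traj(list(up, dn, up, dn))
  rf <- rmsf_per_residue(traj)
  osc <- rf$rmsf[rf$resno %in% c(81, 82)]
  static <- rf$rmsf[rf$resno <= 80]
  expect_equal(osc, rep(d, 2), tolerance = 0.05)
  expect_true(all(static < 0.05))
  expect_error(rmsf_per_residue(toy_traj(list(s))), "at least 2")
})

test_that("linker residues fluctuate more than the anchored domain core", {
  sim <- simulate_trajectory(20, 10, start_distance = 60, end_distance = 60,
                             seed = 5)
  rf <- rmsf_per_residue(sim$trajectory)
  dom1 <- mean(rf$rmsf[rf$resno <= 47])        # core of the anchored domain
  linker <- mean(rf$rmsf[rf$resno %in% 58:110])
  expect_gt(linker, dom1)
})

test_that("radius of gyration has its closed forms and rigid invariance", {
  one <- tibble::tibble(serial = 1L, atom = "CA", resname = "GLY",
                        chain = "A", resno = 1L)
  t1 <- new_trajectory(one, array(c(4, 5, 6), c(1, 3, 1)))
  expect_equal(rog_series(t1)$rog, 0)
  two <- tibble::tibble(serial = 1:2, atom = "CA", resname = "GLY",
                        chain = "A", resno = 1:2)
  d <- 7.3
  t2 <- new_trajectory(two, array(c(0, d, 0, 0, 0, 0), c(2, 3, 1)))
  expect_equal(rog_series(t2)$rog, d / 2)
  s <- scaffold()
  tr <- toy_traj(list(s, sweep(s, 2, c(11, -4, 9), `+`)))
  g <- rog_series(tr)
  expect_equal(g$rog[1], g$rog[2], tolerance = 1e-10)
})

test_that("interdomain distances: 3-4-5 triangle, self-distance, collapse truth", {
  two <- tibble::tibble(serial = 1:2, atom = "CA", resname = "GLY",
                        chain = "A", resno = 1:2)
  t2 <- new_trajectory(two, array(c(0, 3, 0, 4, 0, 0), c(2, 3, 1)))
  expect_equal(interdomain_distance_series(t2, 1, 2)$distance, 5)
  expect_equal(interdomain_distance_series(t2, 1, 1)$distance, 0)
  expect_error(interdomain_distance_series(t2, 1, 9), "residue 9")

  sim <- simulate_trajectory(50, 25, seed = 33)
  ds <- interdomain_distance_series(sim$trajectory, sim$markers$res_i,
                                    sim$markers$res_j)
  expect_true(all(abs(ds$distance - sim$truth$distance) < 2))
})

test_that("distance density counts frames and locates the collapse bin", {
  sim <- simulate_trajectory(50, 25, seed = 12)
  ds <- interdomain_distance_series(sim$trajectory, sim$markers$res_i,
                                    sim$markers$res_j)
  dens <- distance_time_density(ds, time_bins = 10, distance_bins = 15)
  expect_equal(sum(dens$n), 50L)
  const <- ds; const$distance <- rep(42, 50)
  dc <- distance_time_density(const, 5, 8)
  expect_equal(length(unique(dc$distance_bin)), 1L)
  found <- detect_collapse(ds, time_bins = 10)
  truth_bin <- 1L + ((sim$collapse_frame - 1L) * 10L) %/% 50L
  expect_lte(abs(found$collapse_bin - truth_bin), 2L)
  expect_error(distance_time_density(ds, time_bins = 0), "positive")
})

test_that("phi/psi terminal values are undefined and rigid-motion invariant", {
  sim <- simulate_trajectory(2, 1, seed = 3)
  dh <- compute_phi_psi(sim$trajectory, frames = 1L)
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[nrow(dh)]))
  expect_true(all(dh$phi[-1] >= -180 & dh$phi[-1] < 180))
  traj <- sim$trajectory
  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- traj
  moved$coords[, , 1] <- traj$coords[, , 1] %*% rot +
    matrix(rep(c(3, -2, 8), each = nrow(traj$atoms)), ncol = 3)
  dh2 <- compute_phi_psi(moved, frames = 1L)
  expect_equal(dh$phi, dh2$phi, tolerance = 1e-6)
  expect_equal(dh$psi, dh2$psi, tolerance = 1e-6)
})

test_that("arrow maps wrap deltas and vanish for identical frames", {
  dh <- tibble::tibble(frame = rep(1:2, each = 2), resno = rep(1:2, 2),
                       phi = c(170, 10, -170, 10), psi = c(0, 20, 0, 20))
  am <- dihedral_arrow_map(dh, 1, 2)
  expect_equal(am$dphi, c(20, 0))
  sim <- simulate_trajectory(3, 2, seed = 6)
  d <- compute_phi_psi(sim$trajectory, frames = c(1, 3))
  same <- dihedral_arrow_map(d, 3, 3)
  expect_true(all(same$dphi == 0, na.rm = TRUE))
  drift <- dihedral_arrow_map(d, 1, 3, residues = 58:110)
  expect_true(all(abs(drift$dphi) <= 180, na.rm = TRUE))
  expect_error(dihedral_arrow_map(d, 1, 3, residues = 900:950), "outside")
})

test_that("secondary structure boxes and minimum run lengths are enforced", {
  mk <- function(phi, psi) tibble::tibble(frame = 1L,
                                          resno = seq_along(phi),
                                          phi = phi, psi = psi)
  helix6 <- mk(rep(-60, 6), rep(-45, 6))
  expect_equal(assign_secondary_structure(helix6)$sse, rep("H", 6))
  short_h <- mk(c(0, -60, -60, 0, 0), c(100, -45, -45, 100, 100))
  expect_equal(assign_secondary_structure(short_h)$sse[2:3], c("C", "C"))
  strand4 <- mk(rep(-120, 4), rep(130, 4))
  expect_equal(assign_secondary_structure(strand4)$sse, rep("E", 4))
  sim <- simulate_trajectory(2, 1, seed = 10)
  sse <- assign_secondary_structure(compute_phi_psi(sim$trajectory))
  expect_true(all(sse$sse %in% c("H", "E", "C")))
  runs <- vapply(split(sse$sse, sse$frame), function(sv) {
    r <- rle(sv)
    all(r$lengths[r$values == "H"] >= 4) && all(r$lengths[r$values == "E"] >= 3)
  }, logical(1))
  expect_true(all(runs))
})
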