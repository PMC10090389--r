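# Trajectory container, multi-model PDB I/O and geometric summaries.

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing one atom table.
#'
#' @param atoms Tibble with columns `serial`, `atom`, `resname`, `chain`,
#'   `resno` (one row per atom, identical across frames).
#' @param coords Numeric array `n_atoms x 3 x n_frames` of coordinates in
#'   Angstrom.
#' @param frame_interval Nanoseconds per frame (default 0.2; 1000 frames
#'   span 200 ns).
#' @return Object of class `trajectory`.
#' @export
new_trajectory <- function(atoms, coords, frame_interval = 0.2) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3L) {
    abort("coords must be an n_atoms x 3 x n_frames array matching atoms.")
  }
  if (!all(is.finite(coords))) abort("Coordinates must be finite.")
  structure(list(atoms = tibble::as_tibble(atoms), coords = coords,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %d residues, %.3g ns/frame\n",
              n_frames(x), nrow(x$atoms), length(unique(x$atoms$resno)),
              x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory][new_trajectory()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @method as_tibble trajectory
#' @export
as_tibble.trajectory <- function(x, ...) {
  nf <- n_frames(x)
  out <- tidyr::expand_grid(frame = seq_len(nf), x$atoms)
  m <- aperm(x$coords, c(1, 3, 2))
  out <- out[order(out$frame), ]
  out$x <- as.vector(m[, , 1]); out$y <- as.vector(m[, , 2])
  out$z <- as.vector(m[, , 3])
  out$time_ns <- (out$frame - 1) * x$frame_interval
  tibble::as_tibble(out)
}

# frame coordinates as an n_atoms x 3 matrix
frame_coords <- function(traj, frame) {
  matrix(traj$coords[, , frame, drop = FALSE], ncol = 3L)
}

# atom row indices for a named selection
atom_selection <- function(traj, selection = "backbone") {
  idx <- switch(selection,
                backbone = which(traj$atoms$atom %in% c("N", "CA", "C", "O")),
                CA = which(traj$atoms$atom == "CA"),
                all = seq_len(nrow(traj$atoms)),
                which(traj$atoms$atom %in% selection))
  if (length(idx) == 0L) abort(paste0("Empty atom selection: ", selection))
  idx
}

#' Read a multi-model PDB file as a trajectory
#'
#' Fixed-column PDB parsing of ATOM records; frames are delimited by
#' MODEL/ENDMDL and kept in file order. A file without MODEL records is
#' treated as a single-frame trajectory. Models with differing atom counts
#' are a format error naming the offending model.
#'
#' @param path Path to a PDB file.
#' @param frame_interval Nanoseconds per frame (default 0.2).
#' @return A [trajectory][new_trajectory()] object.
#' @export
read_multimodel_pdb <- function(path, frame_interval = 0.2) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(startsWith(rec, "MODEL"))
  atom_line <- rec == "ATOM  "
  if (length(model_starts) == 0L) {
    groups <- list(which(atom_line))
  } else {
    model_of <- findInterval(seq_along(lines), model_starts)
    groups <- split(which(atom_line), model_of[atom_line])
  }
  counts <- lengths(groups)
  if (any(counts == 0L)) abort("Model with no ATOM records.")
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    abort(sprintf("Unequal atom counts across models: model %d has %d atoms, model 1 has %d.",
                  bad, counts[bad], counts[1]))
  }
  parse_block <- function(ix) {
    ln <- lines[ix]
    list(atoms = tibble::tibble(
      serial = as.integer(substr(ln, 7, 11)),
      atom = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      resno = as.integer(substr(ln, 23, 26))),
      xyz = cbind(as.numeric(substr(ln, 31, 38)),
                  as.numeric(substr(ln, 39, 46)),
                  as.numeric(substr(ln, 47, 54))))
  }
  blocks <- lapply(groups, parse_block)
  ref <- blocks[[1]]$atoms
  for (m in seq_along(blocks)[-1]) {
    b <- blocks[[m]]$atoms
    if (!identical(b$atom, ref$atom) || !identical(b$resno, ref$resno)) {
      abort(sprintf("Atom ordering differs in model %d.", m))
    }
  }
  coords <- array(NA_real_, c(nrow(ref), 3L, length(blocks)))
  for (m in seq_along(blocks)) coords[, , m] <- blocks[[m]]$xyz
  new_trajectory(ref, coords, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory][new_trajectory()] object or a
#'   `synthetic_trajectory` from [simulate_trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "synthetic_trajectory")) traj <- traj$trajectory
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
      a$serial, a$atom, a$resname, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(a$atom, 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is Kabsch-superposed onto the reference frame over the chosen
#' atom selection before the RMSD is taken, mirroring the standard
#' trajectory-alignment protocol (reference = first frame).
#'
#' @param traj A trajectory.
#' @param ref_frame 1-based reference frame index (default 1).
#' @param selection `"backbone"` (N, CA, C, O; default), `"CA"`, `"all"`, or
#'   a character vector of atom names.
#' @return Tibble with columns `frame`, `time_ns`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, ref_frame = 1L, selection = "backbone") {
  idx <- atom_selection(traj, selection)
  ref <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    if (f == ref_frame) return(0)
    kabsch_superpose(frame_coords(traj, f)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time_ns = (seq_len(n_frames(traj)) - 1) * traj$frame_interval,
                 rmsd = rmsd)
}

#' Per-residue RMSF
#'
#' Frames are superposed onto the reference frame over `fit_selection`,
#' then the root-mean-square fluctuation of each residue's chosen atom about
#' its mean position is computed.
#'
#' @param traj A trajectory with at least 2 frames.
#' @param atom Atom name tracked per residue (default `"CA"`).
#' @param ref_frame Reference frame for superposition (default 1).
#' @param fit_selection Selection used for superposition (default backbone).
#' @return Tibble with columns `resno`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, atom = "CA", ref_frame = 1L,
                             fit_selection = "backbone") {
  nf <- n_frames(traj)
  if (nf < 2L) abort("RMSF needs at least 2 frames.")
  fit_idx <- atom_selection(traj, fit_selection)
  trk_idx <- which(traj$atoms$atom == atom)
  if (length(trk_idx) == 0L) abort(paste0("No atoms named ", atom, "."))
  ref <- frame_coords(traj, ref_frame)[fit_idx, , drop = FALSE]
  fitted <- array(NA_real_, c(length(trk_idx), 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    k <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref)
    fitted[, , f] <- sweep(xyz[trk_idx, , drop = FALSE] %*% k$rotation, 2,
                           k$translation, `+`)
  }
  mean_pos <- matrix(apply(fitted, c(1, 2), mean), ncol = 3L)
  dev2 <- vapply(seq_len(nf),
                 function(f) rowSums((matrix(fitted[, , f], ncol = 3L) -
                                        mean_pos)^2),
                 numeric(length(trk_idx)))
  dev2 <- matrix(dev2, nrow = length(trk_idx))
  tibble::tibble(resno = traj$atoms$resno[trk_idx],
                 rmsf = sqrt(rowMeans(dev2)))
}

#' Per-frame radius of gyration
#'
#' `Rg = sqrt(sum(m_i |x_i - xbar|^2) / sum(m_i))`; unit masses by default
#' (appropriate for CA/backbone selections).
#'
#' @param traj A trajectory.
#' @param selection Atom selection (default `"all"`).
#' @param masses Optional per-selected-atom masses; default unit.
#' @return Tibble with columns `frame`, `time_ns`, `rog` (Angstrom).
#' @export
rog_series <- function(traj, selection = "all", masses = NULL) {
  idx <- atom_selection(traj, selection)
  m <- masses %||% rep(1, length(idx))
  if (length(m) != length(idx)) abort("masses must match the selection size.")
  rog <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)[idx, , drop = FALSE]
    ctr <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time_ns = (seq_len(n_frames(traj)) - 1) * traj$frame_interval,
                 rog = rog)
}

#' Interdomain marker-atom distance series
#'
#' Euclidean distance between one named atom of each marker residue in every
#' frame, without superposition (the standard proxy for LIM1-LIM2 approach,
#' e.g. the Cys10-Phe176 alpha-carbon distance in human CSRP3).
#'
#' @param traj A trajectory.
#' @param res_i,res_j Residue numbers of the two markers.
#' @param atom Atom name (default `"CA"`).
#' @return Tibble with columns `frame`, `time_ns`, `distance` (Angstrom).
#' @export
interdomain_distance_series <- function(traj, res_i, res_j, atom = "CA") {
  pick <- function(r) {
    i <- which(traj$atoms$resno == r & traj$atoms$atom == atom)
    if (length(i) != 1L) {
      abort(sprintf("Atom %s of residue %d missing (all frames share one atom table).",
                    atom, r))
    }
    i
  }
  i <- pick(res_i); j <- pick(res_j)
  dd <- traj$coords[i, , , drop = FALSE] - traj$coords[j, , , drop = FALSE]
  d <- sqrt(apply(dd^2, 3, sum))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time_ns = (seq_len(n_frames(traj)) - 1) * traj$frame_interval,
                 distance = as.numeric(d))
}

#' Two-dimensional time-distance density map
#'
#' Bins a distance series over time and distance; counts sum to the number
#' of frames.
#'
#' @param series Tibble from [interdomain_distance_series()] (columns
#'   `frame`, `time_ns`, `distance`).
#' @param time_bins,distance_bins Positive bin counts.
#' @return Tibble of class `distance_density` with columns `time_bin`,
#'   `distance_bin`, `time_mid` (ns), `distance_mid` (Angstrom), `n`.
#' @export
distance_time_density <- function(series, time_bins = 10L,
                                  distance_bins = 20L) {
  if (nrow(series) == 0L) abort("Empty distance series.")
  if (time_bins < 1 || distance_bins < 1) abort("Bin counts must be positive.")
  tb <- seq(min(series$time_ns), max(series$time_ns), length.out = time_bins + 1L)
  db <- seq(min(series$distance), max(series$distance),
            length.out = distance_bins + 1L)
  # widen degenerate ranges so cut() has nonzero-width bins
  if (diff(range(tb)) == 0) tb <- tb[1] + seq(-0.5, 0.5, length.out = time_bins + 1L)
  if (diff(range(db)) == 0) db <- db[1] + seq(-0.5, 0.5, length.out = distance_bins + 1L)
  ti <- pmin(time_bins, pmax(1L, findInterval(series$time_ns, tb,
                                              rightmost.closed = TRUE)))
  di <- pmin(distance_bins, pmax(1L, findInterval(series$distance, db,
                                                  rightmost.closed = TRUE)))
  out <- dplyr::count(tibble::tibble(time_bin = ti, distance_bin = di),
                      .data$time_bin, .data$distance_bin)
  out$time_mid <- (tb[out$time_bin] + tb[out$time_bin + 1L]) / 2
  out$distance_mid <- (db[out$distance_bin] + db[out$distance_bin + 1L]) / 2
  attr(out, "time_breaks") <- tb
  attr(out, "distance_breaks") <- db
  class(out) <- c("distance_density", class(out))
  out
}

#' Detect the collapse time bin of a distance series
#'
#' Splits the series into `time_bins` equal windows and returns the first
#' bin whose mean distance drops below the midpoint of the start and end
#' levels (estimated from the first and last bin means unless given).
#'
#' @param series Tibble with columns `frame` and `distance`.
#' @param time_bins Number of time windows (default 10).
#' @param threshold Optional explicit distance threshold (Angstrom).
#' @return Tibble with one row: `collapse_bin`, `collapse_frame` (first
#'   frame of that bin), `threshold`; `collapse_bin` is `NA` if no bin
#'   crosses the threshold.
#' @export
detect_collapse <- function(series, time_bins = 10L, threshold = NULL) {
  n <- nrow(series)
  bin <- pmin(time_bins, 1L + ((seq_len(n) - 1L) * time_bins) %/% n)
  mu <- tapply(series$distance, bin, mean)
  thr <- threshold %||% ((mu[1] + mu[length(mu)]) / 2)
  hit <- which(mu < thr)
  cb <- if (length(hit) == 0L) NA_integer_ else as.integer(names(mu)[hit[1]])
  cf <- if (is.na(cb)) NA_integer_ else which(bin == cb)[1]
  tibble::tibble(collapse_bin = cb, collapse_frame = cf,
                 threshold = as.numeric(thr))
}

#' Backbone phi/psi dihedrals per residue and frame
#'
#' Standard IUPAC torsions from N, CA, C backbone atoms, wrapped to
#' `[-180, 180)`. The first residue's phi and the last residue's psi are
#' undefined (`NA`), as are residues with missing backbone atoms.
#'
#' @param traj A trajectory.
#' @param frames Frame indices (default all).
#' @return Tibble with columns `frame`, `resno`, `phi`, `psi` (degrees).
#' @export
compute_phi_psi <- function(traj, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  a <- traj$atoms
  resnos <- sort(unique(a$resno))
  idx_of <- function(nm) {
    i <- match(paste(resnos, nm), paste(a$resno, a$atom))
    i
  }
  iN <- idx_of("N"); iCA <- idx_of("CA"); iC <- idx_of("C")
  missing_bb <- is.na(iN) | is.na(iCA) | is.na(iC)
  if (any(missing_bb)) {
    warn(sprintf("%d residue(s) lack N/CA/C backbone atoms; dihedrals set NA.",
                 sum(missing_bb)))
  }
  nr <- length(resnos)
  purrr::map_dfr(frames, function(f) {
    xyz <- frame_coords(traj, f)
    get <- function(i) {
      out <- matrix(NA_real_, length(i), 3L)
      ok <- !is.na(i)
      out[ok, ] <- xyz[i[ok], , drop = FALSE]
      out
    }
    N <- get(iN); CA <- get(iCA); C <- get(iC)
    phi <- rep(NA_real_, nr); psi <- rep(NA_real_, nr)
    if (nr >= 2L) {
      ii <- 2:nr
      phi[ii] <- torsion_angle(C[ii - 1L, , drop = FALSE],
                               N[ii, , drop = FALSE],
                               CA[ii, , drop = FALSE],
                               C[ii, , drop = FALSE])
      jj <- 1:(nr - 1L)
      psi[jj] <- torsion_angle(N[jj, , drop = FALSE],
                               CA[jj, , drop = FALSE],
                               C[jj, , drop = FALSE],
                               N[jj + 1L, , drop = FALSE])
    }
    tibble::tibble(frame = f, resno = resnos, phi = phi, psi = psi)
  })
}

#' Phi/psi arrow map between two frames
#'
#' For each residue, the starting dihedrals at `frame_a` and the wrapped
#' change to `frame_b` (deltas in `(-180, 180]`, so magnitudes never exceed
#' 180 degrees). Used to visualise conformational drift of the linker, e.g.
#' between the start, middle and end of a simulation.
#'
#' @param dihedrals Tibble from [compute_phi_psi()].
#' @param frame_a,frame_b Frame indices present in `dihedrals`.
#' @param residues Optional residue-number span to keep (e.g. the linker).
#' @return Tibble with columns `resno`, `phi_a`, `psi_a`, `dphi`, `dpsi`.
#' @export
dihedral_arrow_map <- function(dihedrals, frame_a, frame_b, residues = NULL) {
  da <- dplyr::filter(dihedrals, .data$frame == frame_a)
  db <- dplyr::filter(dihedrals, .data$frame == frame_b)
  if (nrow(da) == 0L || nrow(db) == 0L) {
    abort("Both frames must be present in the dihedral series.")
  }
  if (!is.null(residues)) {
    if (!any(da$resno %in% residues)) abort("Residue span outside the chain.")
    da <- dplyr::filter(da, .data$resno %in% residues)
    db <- dplyr::filter(db, .data$resno %in% residues)
  }
  out <- dplyr::inner_join(
    dplyr::select(da, "resno", phi_a = "phi", psi_a = "psi"),
    dplyr::select(db, "resno", phi_b = "phi", psi_b = "psi"),
    by = "resno")
  out$dphi <- wrap_delta(out$phi_b - out$phi_a)
  out$dpsi <- wrap_delta(out$psi_b - out$psi_a)
  dplyr::select(out, "resno", "phi_a", "psi_a", "dphi", "dpsi")
}

#' Dihedral-region secondary-structure timeline
#'
#' Assigns H (helix), E (strand) or C (coil) per residue and frame from
#' backbone dihedral regions: H for phi in `[-100, -30]` and psi in
#' `[-80, -5]`; E for phi in `[-170, -70]` and psi in `[90, 180)` or
#' `[-180, -170)`; C otherwise. Runs shorter than 4 (H) or 3 (E) residues
#' are relabelled C. This is a geometric assignment from dihedral basins,
#' not a hydrogen-bond-based method; it distinguishes intact domains from
#' coil, which is what the timeline is consumed for.
#'
#' @param dihedrals Tibble from [compute_phi_psi()].
#' @return Tibble with columns `frame`, `resno`, `sse` (one of H/E/C).
#' @export
assign_secondary_structure <- function(dihedrals) {
  phi <- dihedrals$phi; psi <- dihedrals$psi
  h <- !is.na(phi) & !is.na(psi) & phi >= -100 & phi <= -30 &
    psi >= -80 & psi <= -5
  e <- !is.na(phi) & !is.na(psi) & phi >= -170 & phi <= -70 &
    ((psi >= 90 & psi < 180) | (psi >= -180 & psi < -170))
  lab <- ifelse(h, "H", ifelse(e, "E", "C"))
  out <- dplyr::mutate(dihedrals[, c("frame", "resno")], sse = lab)
  out <- dplyr::arrange(out, .data$frame, .data$resno)
  smooth_one <- function(s) {
    r <- rle(s)
    drop <- (r$values == "H" & r$lengths < 4L) |
      (r$values == "E" & r$lengths < 3L)
    r$values[drop] <- "C"
    inverse.rle(r)
  }
  out <- dplyr::group_by(out, .data$frame)
  out <- dplyr::mutate(out, sse = smooth_one(.data$sse))
  dplyr::ungroup(out)
}
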