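# Synthetic two-domain collapse trajectories: two rigid backbone clusters
# joined by a flexible linker whose dihedrals are resampled every frame,
# with a programmed domain-approach (collapse) event.

# idealised backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

# Build backbone coordinates (N, CA, C, O per residue) from per-residue
# phi/psi (degrees), omega fixed trans. Returns a (4*n) x 3 matrix ordered
# N1 CA1 C1 O1 N2 ... with a fixed anchor at the origin.
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  g <- BB_GEOM
  xyz <- matrix(NA_real_, 4L * n, 3L)
  rowN <- function(i) 4L * (i - 1L) + 1L
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$n_ca, 0, 0)
  xyz[3, ] <- place_atom(c(0, 1, 0), xyz[1, ], xyz[2, ], g$ca_c,
                         g$ang_n_ca_c, ifelse(is.finite(phi[1]), phi[1], -120))
  for (i in seq_len(n)) {
    rN <- rowN(i)
    if (i > 1L) {
      prev <- rowN(i - 1L)
      xyz[rN, ] <- place_atom(xyz[prev, ], xyz[prev + 1L, ], xyz[prev + 2L, ],
                              g$c_n, g$ang_ca_c_n, psi[i - 1L])
      xyz[rN + 1L, ] <- place_atom(xyz[prev + 1L, ], xyz[prev + 2L, ], xyz[rN, ],
                                   g$n_ca, g$ang_c_n_ca, 180)
      xyz[rN + 2L, ] <- place_atom(xyz[prev + 2L, ], xyz[rN, ], xyz[rN + 1L, ],
                                   g$ca_c, g$ang_n_ca_c, phi[i])
    }
    psi_i <- if (i < n) psi[i] else 120
    xyz[rN + 3L, ] <- place_atom(xyz[rN, ], xyz[rN + 1L, ], xyz[rN + 2L, ],
                                 g$c_o, g$ang_ca_c_o, wrap_angle(psi_i + 180))
  }
  xyz
}

# once-sampled rigid-domain dihedrals: helical blocks broken by extended
# steps so the cluster is not a single long helix
domain_dihedrals <- function(n) {
  block <- ((seq_len(n) - 1L) %/% 9L) %% 2L == 0L
  phi <- ifelse(block, -60, -120) + rnorm(n, 0, 5)
  psi <- ifelse(block, -45, 130) + rnorm(n, 0, 5)
  list(phi = phi, psi = psi)
}

# coil-basin linker dihedrals, resampled per frame
coil_dihedrals <- function(n) {
  basin <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  phi <- c(-75, -120, -70)[basin] + rnorm(n, 0, 15)
  psi <- c(145, 130, -30)[basin] + rnorm(n, 0, 15)
  list(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

#' Simulate a two-domain collapse trajectory
#'
#' Generates a multi-frame backbone trajectory of a dual-domain protein:
#' two rigid clusters (fixed internal dihedrals) joined by a flexible linker
#' whose dihedrals are resampled every frame. The marker-atom distance
#' between the two domains follows a logistic schedule from `start_distance`
#' to `end_distance` centred on `collapse_frame`, with Gaussian noise
#' (sd 1 Angstrom, clamped positive); the second domain is rigidly
#' translated along the marker axis to realise each frame's scheduled
#' distance, so the recorded truth distance is exact by construction.
#'
#' @param n_frames Number of frames (>= 1).
#' @param collapse_frame 1-based frame index at which the scheduled distance
#'   crosses the midpoint of start and end. Must lie in `[1, n_frames]`.
#' @param start_distance,end_distance Marker distances (Angstrom) before and
#'   after the collapse; defaults 120 and 35.
#' @param linker_length Linker length in residues (default 53, the human
#'   linker length).
#' @param lim_length Length of each rigid domain in residues (default 57).
#' @param seed Integer seed; output is deterministic.
#' @param frame_interval Nanoseconds per frame (default 0.2, i.e. 1000
#'   frames span 200 ns).
#' @param noise_sd Standard deviation of the per-frame distance noise in
#'   Angstrom (default 1; a single-frame trajectory uses no noise).
#' @return List of class `synthetic_trajectory`: `trajectory` (a
#'   [trajectory] object), `truth` (tibble: frame, time_ns, distance),
#'   `markers` (list: res_i, res_j, atom) and `collapse_frame`.
#' @export
#' @examples
#' sim <- simulate_trajectory(10, collapse_frame = 5, seed = 1)
#' sim$truth
simulate_trajectory <- function(n_frames, collapse_frame,
                                start_distance = 120, end_distance = 35,
                                linker_length = 53, lim_length = 57,
                                seed = 1L, frame_interval = 0.2,
                                noise_sd = 1) {
  if (n_frames < 1) abort("n_frames must be at least 1.")
  if (collapse_frame < 1 || collapse_frame > n_frames) {
    abort("collapse_frame must lie between 1 and n_frames.")
  }
  if (start_distance <= 0 || end_distance <= 0) {
    abort("Distances must be positive.")
  }
  with_seed(seed, {
    n_res <- 2L * lim_length + linker_length
    idx1 <- seq_len(lim_length)
    idxL <- lim_length + seq_len(linker_length)
    idx2 <- lim_length + linker_length + seq_len(lim_length)
    res_i <- min(10L, lim_length)
    res_j <- n_res - min(18L, lim_length - 1L)
    d1 <- domain_dihedrals(lim_length)
    d2 <- domain_dihedrals(lim_length)

    w <- max(1, n_frames / 16)
    t <- seq_len(n_frames)
    sched <- end_distance + (start_distance - end_distance) /
      (1 + exp((t - collapse_frame) / w))
    if (n_frames == 1L) {
      target <- start_distance
    } else {
      target <- pmax(1, sched + rnorm(n_frames, 0, noise_sd))
    }

    resname <- rep("GLY", n_res)
    resname[c(res_i, res_j)] <- c("CYS", "PHE")
    atoms <- tibble::tibble(
      serial = seq_len(4L * n_res),
      atom = rep(c("N", "CA", "C", "O"), n_res),
      resname = rep(resname, each = 4L),
      chain = "A",
      resno = rep(seq_len(n_res), each = 4L))

    coords <- array(NA_real_, c(4L * n_res, 3L, n_frames))
    row_ca <- function(r) 4L * (r - 1L) + 2L
    dom2_rows <- as.vector(vapply(idx2, function(r) 4L * (r - 1L) + 1:4,
                                  numeric(4)))
    for (f in seq_len(n_frames)) {
      lk <- coil_dihedrals(linker_length)
      phi <- c(d1$phi, lk$phi, d2$phi)
      psi <- c(d1$psi, lk$psi, d2$psi)
      xyz <- build_backbone(phi, psi)
      ca_i <- xyz[row_ca(res_i), ]
      ca_j <- xyz[row_ca(res_j), ]
      u <- ca_j - ca_i
      d0 <- sqrt(sum(u^2))
      shift <- (target[f] - d0) * u / d0
      xyz[dom2_rows, ] <- sweep(xyz[dom2_rows, , drop = FALSE], 2, shift, `+`)
      coords[, , f] <- xyz
    }
    traj <- new_trajectory(atoms, coords, frame_interval)
    truth <- tibble::tibble(frame = t, time_ns = (t - 1) * frame_interval,
                            distance = target)
    structure(list(trajectory = traj, truth = truth,
                   markers = list(res_i = res_i, res_j = res_j, atom = "CA"),
                   collapse_frame = as.integer(collapse_frame)),
              class = "synthetic_trajectory")
  })
}
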