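# Independent oracles used across tests.

# Naive per-residue propensity oracle: count residue-by-residue with nested
# loops, never sharing code with compute_propensity().
oracle_propensity <- function(segments) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  link_n <- setNames(rep(0, 20), aas)
  tot_n <- setNames(rep(0, 20), aas)
  link_len <- 0
  tot_len <- 0
  for (j in seq_len(nrow(segments))) {
    d <- segments$linker_seq[j]
    whole <- c(strsplit(segments$lim1_seq[j], "")[[1]],
               strsplit(d, "")[[1]],
               strsplit(segments$lim2_seq[j], "")[[1]])
    for (ch in strsplit(d, "")[[1]]) link_n[ch] <- link_n[ch] + 1
    for (ch in whole) tot_n[ch] <- tot_n[ch] + 1
    link_len <- link_len + nchar(d)
    tot_len <- tot_len + length(whole)
  }
  f_link <- link_n / link_len
  f_tot <- tot_n / tot_len
  p <- rep(NA_real_, 20)
  for (i in 1:20) {
    if (f_tot[i] > 0) p[i] <- if (f_link[i] == 0) 0 else f_link[i] / f_tot[i]
  }
  tibble::tibble(aa = aas, propensity = p)
}

# Brute-force minimum RMSD over proper rotations: coarse Euler-angle grid
# followed by Nelder-Mead refinement. Centres both point sets first.
oracle_min_rmsd <- function(mobile, reference, grid_step = 20) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((m0 %*% t(rotmat(a)) - r0)^2)))
  step <- grid_step * pi / 180
  angles <- seq(0, 2 * pi - step / 2, by = step)
  best <- Inf; best_a <- c(0, 0, 0)
  for (az in angles) for (ay in angles) for (ax in angles) {
    v <- f(c(az, ay, ax))
    if (v < best) { best <- v; best_a <- c(az, ay, ax) }
  }
  opt <- stats::optim(best_a, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# small dual-LIM synthetic set used by several files
small_set <- function(n = 30, seed = 1, ...) {
  limlinker::simulate_homolog_set(
    limlinker::synthetic_spec(n, seed = seed, ...))
}
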