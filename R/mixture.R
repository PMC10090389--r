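# Trimodal classification of linker lengths: 1-D Gaussian mixture fitted by
# EM, plus fixed-threshold classification.

#' Fit a Gaussian mixture to linker lengths
#'
#' Expectation-maximisation on a one-dimensional Gaussian mixture,
#' formalising the trimodal (short / medium / long) structure of linker
#' length distributions. Initialisation is deterministic: component means at
#' the 1/6, 1/2 and 5/6 quantiles (evenly spaced quantiles for general `k`),
#' equal weights, pooled standard deviation. Component standard deviations
#' are floored at `sd_min` so degenerate inputs (all lengths equal) cannot
#' collapse a component. Components are reported sorted by ascending mean.
#'
#' @param lengths Numeric vector of linker lengths (residues); at least
#'   `3 * k` observations.
#' @param k Number of components (default 3).
#' @param seed Seed governing random tie-breaking (the fit itself is
#'   deterministic given the data).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param sd_min Standard-deviation floor in residues (default 0.5).
#' @return Object of class `linker_mixture`: list with `weights`, `means`,
#'   `sds` (sorted by mean), `responsibilities` (n x k matrix, rows sum
#'   to 1), `class_boundaries` (k-1 lengths where the posterior argmax
#'   switches between adjacent components), `loglik` (per-iteration trace,
#'   non-decreasing), `n`, `converged`.
#' @export
fit_length_mixture <- function(lengths, k = 3L, seed = 1L, max_iter = 500L,
                               tol = 1e-8, sd_min = 0.5) {
  x <- as.numeric(lengths)
  n <- length(x)
  if (n < 3L * k) abort(sprintf("Need at least %d observations for k = %d.", 3L * k, k))
  probs <- (2 * seq_len(k) - 1) / (2 * k)   # 1/6, 1/2, 5/6 for k = 3
  mu <- as.numeric(quantile(x, probs, names = FALSE, type = 7))
  if (anyDuplicated(mu)) {
    mu <- mu + with_seed(seed, runif(k, -1e-6, 1e-6))  # tie-break identical quantiles
  }
  sig <- rep(max(sd(x), sd_min), k)
  w <- rep(1 / k, k)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sig[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    r <- dens / rowsum_d
    nk <- colSums(r)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(r * x) / nk
    sig <- pmax(sd_min,
                sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk))
  }
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sig <- sig[ord]
  dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sig[j]),
                 numeric(n))
  resp <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  boundaries <- mixture_boundaries(w, mu, sig)
  structure(list(weights = w, means = mu, sds = sig,
                 responsibilities = resp,
                 class_boundaries = boundaries,
                 loglik = loglik, n = n, k = k,
                 converged = converged),
            class = "linker_mixture")
}

# Lengths at which the posterior argmax switches between adjacent (sorted)
# components, found on a fine grid across the data range of the fit.
mixture_boundaries <- function(w, mu, sig) {
  k <- length(mu)
  if (k < 2L) return(numeric(0))
  grid <- seq(min(mu) - 4 * max(sig), max(mu) + 4 * max(sig), length.out = 4000L)
  post <- vapply(seq_len(k), function(j) w[j] * dnorm(grid, mu[j], sig[j]),
                 numeric(length(grid)))
  amax <- max.col(post, ties.method = "first")
  vapply(seq_len(k - 1L), function(j) {
    sw <- which(amax[-1] > j & amax[-length(amax)] <= j)
    if (length(sw) == 0L) return((mu[j] + mu[j + 1L]) / 2)
    (grid[sw[1]] + grid[sw[1] + 1L]) / 2
  }, numeric(1))
}

#' @export
print.linker_mixture <- function(x, ...) {
  cat(sprintf("<linker_mixture> k = %d, n = %d, %s after %d EM iterations\n",
              x$k, x$n, if (x$converged) "converged" else "not converged",
              length(x$loglik)))
  cat(sprintf("  weights: %s\n", paste(signif(x$weights, 3), collapse = ", ")))
  cat(sprintf("  means:   %s\n", paste(signif(x$means, 4), collapse = ", ")))
  cat(sprintf("  sds:     %s\n", paste(signif(x$sds, 3), collapse = ", ")))
  if (length(x$class_boundaries)) {
    cat(sprintf("  boundaries: %s\n",
                paste(signif(x$class_boundaries, 4), collapse = ", ")))
  }
  invisible(x)
}

#' @method tidy linker_mixture
#' @export
tidy.linker_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 class = if (x$k == 3L) c("short", "medium", "long")
                 else paste0("component", seq_len(x$k)),
                 weight = x$weights, mean = x$means, sd = x$sds)
}

#' @method glance linker_mixture
#' @export
glance.linker_mixture <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, loglik = tail(x$loglik, 1),
                 iterations = length(x$loglik), converged = x$converged)
}

#' Classify linker lengths as short / medium / long
#'
#' Either by fixed length thresholds (half-open bins: short `< 40`, medium
#' `[40, 70)`, long `>= 70`) or, when a fitted [fit_length_mixture()] model
#' is supplied, by posterior argmax under the mixture. The default
#' thresholds separate the field's exemplars: Arabidopsis-like short
#' linkers, the 53-residue human linker (medium) and nematode-like long
#' linkers.
#'
#' @param lengths Numeric vector of linker lengths.
#' @param mixture Optional `linker_mixture`; when given, thresholds are
#'   ignored and posterior classification is used.
#' @param thresholds Length-2 increasing vector `c(short_max, long_min)`
#'   (default `c(40, 70)`).
#' @return Character vector of labels `"short"`, `"medium"`, `"long"`.
#' @export
#' @examples
#' classify_linker_lengths(c(20, 52, 90))
classify_linker_lengths <- function(lengths, mixture = NULL,
                                    thresholds = c(40, 70)) {
  if (!is.null(mixture)) {
    if (!inherits(mixture, "linker_mixture") || mixture$k != 3L) {
      abort("mixture must be a 3-component linker_mixture.")
    }
    x <- as.numeric(lengths)
    post <- vapply(1:3, function(j) {
      mixture$weights[j] * dnorm(x, mixture$means[j], mixture$sds[j])
    }, numeric(length(x)))
    post <- matrix(post, ncol = 3L)
    return(c("short", "medium", "long")[max.col(post, ties.method = "first")])
  }
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
    abort("thresholds must be two increasing lengths c(short_max, long_min).")
  }
  ifelse(lengths < thresholds[1], "short",
         ifelse(lengths < thresholds[2], "medium", "long"))
}
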