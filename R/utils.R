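# Shared constants and small numeric helpers.

# The 20 standard amino acids, one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Wrap an angle into [-180, 180)
#'
#' Canonical representation for backbone dihedral values: 180 maps to -180.
#'
#' @param x Angle(s) in degrees.
#' @return Numeric vector in `[-180, 180)`.
#' @export
#' @examples
#' wrap_angle(c(180, -180, 360, 190))
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w >= 180, w - 360, w)
}

#' Wrap an angular difference into (-180, 180]
#'
#' Differences keep the opposite half-open convention from [wrap_angle()] so
#' that a delta and its negation have the same magnitude; a change from 170 to
#' -170 degrees is reported as +20.
#'
#' @param x Angular difference(s) in degrees.
#' @return Numeric vector in `(-180, 180]`.
#' @export
#' @examples
#' wrap_delta(-170 - 170) # +20
wrap_delta <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

# Count amino-acid occurrences in a character vector of sequences,
# returned as a named vector over AA_ALPHABET.
aa_counts <- function(seqs) {
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0L) {
    return(setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET))
  }
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab), AA_ALPHABET)
}

# Sample n residues from a weighted amino-acid distribution.
sample_residues <- function(n, weights = NULL) {
  w <- rep(1, length(AA_ALPHABET))
  names(w) <- AA_ALPHABET
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), AA_ALPHABET)
    if (length(bad) > 0) {
      abort(paste0("Unknown amino acid(s) in enrichment weights: ",
                   paste(bad, collapse = ", ")))
    }
    w[names(weights)] <- weights
  }
  if (n == 0L) return("")
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

# Evaluate an expression with a local RNG seed, restoring the caller's
# RNG state afterwards (keeps generators deterministic and side-effect free).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
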