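# Linker length distributions and the amino-acid propensity statistic.

#' Length distribution of a segment region
#'
#' Histogram of LIM1, linker or LIM2 lengths across segmented sequences.
#'
#' @param segments Tibble from [segment_sequences()].
#' @param region One of `"linker"` (default), `"LIM1"`, `"LIM2"`.
#' @param bin_width Bin width in residues (default 1).
#' @return Tibble of class `length_distribution` with columns `bin_start`,
#'   `bin_mid`, `n`; the modal bin is stored in attribute `modal_bin` and
#'   the region in `region`. Bin counts sum to the number of segments.
#' @export
region_length_distribution <- function(segments, region = "linker",
                                       bin_width = 1) {
  if (nrow(segments) == 0L) abort("No segments to summarise.")
  len <- switch(region,
                linker = segments$linker_length,
                LIM1 = segments$lim1_end - segments$lim1_start + 1L,
                LIM2 = segments$lim2_end - segments$lim2_start + 1L,
                abort("region must be one of linker, LIM1, LIM2."))
  bin_start <- floor(len / bin_width) * bin_width
  out <- dplyr::count(tibble::tibble(bin_start = bin_start), .data$bin_start)
  out$bin_mid <- out$bin_start + bin_width / 2
  out <- dplyr::relocate(out, "bin_start", "bin_mid", "n")
  attr(out, "modal_bin") <- out$bin_start[which.max(out$n)]
  attr(out, "region") <- region
  attr(out, "bin_width") <- bin_width
  class(out) <- c("length_distribution", class(out))
  out
}

#' Linker amino-acid propensity
#'
#' For each amino acid `i`, the propensity is the pooled linker frequency
#' divided by the pooled frequency over the whole LIM1 + linker + LIM2
#' region across the `N` segmented sequences:
#'
#' `P_i = (sum_j count_i(D_j) / sum_j |D_j|) /
#'        (sum_j count_i(L1_j + D_j + L2_j) / sum_j |L1_j + D_j + L2_j|)`
#'
#' where `D_j` is the linker and `L1_j`, `L2_j` are the LIM domains of the
#' j-th sequence. A value of 1 means no enrichment; `P_i` is 0 when the
#' residue never occurs in any linker, and `NA` (undefined) when it never
#' occurs in the pooled region at all. Terminal tails outside LIM1..LIM2
#' enter neither numerator nor denominator.
#'
#' @param segments Tibble from [segment_sequences()] (columns `lim1_seq`,
#'   `linker_seq`, `lim2_seq`).
#' @return Tibble of class `propensity_table` with columns `aa`,
#'   `propensity`, `f_linker`, `f_total`; attributes `n_sequences`,
#'   `total_linker_length`, `total_region_length`.
#' @export
#' @examples
#' seg <- tibble::tibble(lim1_seq = "AC", linker_seq = "PP", lim2_seq = "AC")
#' p <- compute_propensity(seg)
#' p$propensity[p$aa == "P"]  # 3
compute_propensity <- function(segments) {
  if (nrow(segments) == 0L) abort("No segments to summarise.")
  linker_counts <- aa_counts(segments$linker_seq)
  total_counts <- linker_counts + aa_counts(segments$lim1_seq) +
    aa_counts(segments$lim2_seq)
  tl <- sum(nchar(segments$linker_seq))
  tr <- sum(nchar(segments$lim1_seq)) + tl + sum(nchar(segments$lim2_seq))
  if (tl == 0) abort("Total linker length is zero; propensity is undefined.")
  f_linker <- linker_counts / tl
  f_total <- total_counts / tr
  p <- ifelse(f_total == 0, NA_real_,
              ifelse(f_linker == 0, 0, f_linker / f_total))
  out <- tibble::tibble(aa = AA_ALPHABET, propensity = as.numeric(p),
                        f_linker = as.numeric(f_linker),
                        f_total = as.numeric(f_total))
  attr(out, "n_sequences") <- nrow(segments)
  attr(out, "total_linker_length") <- tl
  attr(out, "total_region_length") <- tr
  class(out) <- c("propensity_table", class(out))
  out
}
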