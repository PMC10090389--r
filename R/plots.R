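# ggplot2 convenience plots; tables remain the contract, plots are views.

#' @method autoplot length_distribution
#' @export
autoplot.length_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$n)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::labs(x = paste(attr(object, "region"), "length (residues)"),
                  y = "sequences") +
    ggplot2::theme_minimal()
}

#' @method autoplot propensity_table
#' @export
autoplot.propensity_table <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$propensity))
  df$aa <- factor(df$aa, levels = df$aa)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$propensity)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "amino acid", y = "linker propensity") +
    ggplot2::theme_minimal()
}

#' @method autoplot linker_mixture
#' @export
autoplot.linker_mixture <- function(object, lengths = NULL, ...) {
  grid <- seq(min(object$means) - 4 * max(object$sds),
              max(object$means) + 4 * max(object$sds), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(length = grid, component = factor(j),
                   density = object$weights[j] *
                     dnorm(grid, object$means[j], object$sds[j]))
  })
  p <- ggplot2::ggplot()
  if (!is.null(lengths)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(length = lengths),
      ggplot2::aes(x = .data$length, y = ggplot2::after_stat(.data$density)),
      binwidth = 2, fill = "grey80", colour = "grey60")
  }
  p + ggplot2::geom_line(data = dens,
                         ggplot2::aes(x = .data$length, y = .data$density,
                                      colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$class_boundaries, linetype = 3) +
    ggplot2::labs(x = "linker length (residues)", y = "density") +
    ggplot2::theme_minimal()
}

#' @method autoplot distance_density
#' @export
autoplot.distance_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_mid,
                                       y = .data$distance_mid,
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (ns)", y = "interdomain distance (Å)",
                  fill = "frames") +
    ggplot2::theme_minimal()
}

#' Arrow map of phi/psi drift between two frames
#'
#' @param arrow_map Tibble from [dihedral_arrow_map()].
#' @return A ggplot object: one arrow per residue from its (phi, psi) at the
#'   first frame towards its value at the second.
#' @export
plot_arrow_map <- function(arrow_map) {
  df <- dplyr::filter(arrow_map, !is.na(.data$phi_a), !is.na(.data$dphi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi_a, y = .data$psi_a)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$phi_a + .data$dphi,
                                       yend = .data$psi_a + .data$dpsi),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick", alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = "phi (degrees)", y = "psi (degrees)") +
    ggplot2::theme_minimal()
}

#' Secondary-structure timeline heat map
#'
#' @param sse Tibble from [assign_secondary_structure()].
#' @return A ggplot object: residues against frames, coloured by H/E/C.
#' @export
plot_sse_timeline <- function(sse) {
  ggplot2::ggplot(sse, ggplot2::aes(x = .data$frame, y = .data$resno,
                                    fill = .data$sse)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(H = "firebrick", E = "gold",
                                          C = "grey85")) +
    ggplot2::labs(x = "frame", y = "residue", fill = "SSE") +
    ggplot2::theme_minimal()
}

#' Normalised linker-class frequencies per taxon
#'
#' @param tf Tibble from [taxonomy_frequency()].
#' @return A stacked-bar ggplot of per-taxon class frequencies.
#' @export
plot_taxon_frequency <- function(tf) {
  tf$linker_class <- factor(tf$linker_class,
                            levels = c("short", "medium", "long"))
  tf$taxon <- factor(tf$taxon, levels = unique(tf$taxon))
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$taxon, y = .data$freq,
                                   fill = .data$linker_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "normalised frequency", fill = "linker") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
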