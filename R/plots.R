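#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_tile
#'   geom_hline labs theme_minimal scale_fill_manual annotate
#' @export
ggplot2::autoplot

#' Plot sliding-window nucleotide diversity
#'
#' Pi along the alignment with the four conservation-class thresholds
#' (0.012, 0.024, 0.038) as reference lines.
#'
#' @param object a [sliding_pi()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pi_windows <- function(object, ...) {
  ggplot(object, aes(x = .data$midpoint, y = .data$pi)) +
    geom_hline(yintercept = c(0.012, 0.024, 0.038),
               linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2c7fb8") +
    labs(x = "Alignment position (window midpoint)",
         y = expression(pi),
         title = "Sliding-window nucleotide diversity") +
    theme_minimal()
}

#' Plot an SSR summary
#'
#' Locus counts by unit size, stacked by region.
#'
#' @param object an [ssr_summary()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ssr_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$by_region[, c("region", paste0("p", 1:6))],
    -"region", names_to = "unit_size", values_to = "n")
  long$unit_size <- factor(as.integer(sub("p", "", long$unit_size)))
  ggplot(long, aes(x = .data$unit_size, y = .data$n, fill = .data$region)) +
    geom_col() +
    labs(x = "Motif unit size (bp)", y = "SSR loci", fill = "Region",
         title = "SSR loci by unit size and region") +
    theme_minimal()
}

#' Plot a motif presence/absence matrix
#'
#' Species-by-motif tile map, motifs ordered by decreasing balance index
#' so the most informative motifs come first.
#'
#' @param object a [build_motif_matrix()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.motif_matrix <- function(object, ...) {
  ord <- balance_index(object)$motif
  long <- tidy.motif_matrix(object)
  long$motif <- factor(long$motif, levels = ord)
  long$present <- factor(long$present, levels = c(0, 1),
                         labels = c("absent", "present"))
  ggplot(long, aes(x = .data$motif, y = .data$species,
                   fill = .data$present)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(absent = "grey90", present = "#225ea8")) +
    labs(x = "Motif", y = NULL, fill = NULL,
         title = "cpSSR motif presence/absence") +
    theme_minimal()
}
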