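## ggplot2 graphics for the main result types.

#' @import ggplot2
NULL

#' Plot a mutation spectrum
#'
#' Bar chart of the six strand-symmetric substitution classes; the
#' C:G->T:A bar dominating is the visual RIP hallmark.
#'
#' @param object a [mutation_spectrum()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mutation_spectrum <- function(object, ...) {
  d <- object$counts
  ggplot(d, aes(x = .data$class, y = .data$fraction,
                fill = .data$class == "CG>TA")) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey55")) +
    labs(x = "substitution class", y = "fraction of events",
         title = "Repeat-family mutation spectrum") +
    theme_minimal()
}

#' Plot a TE silencing cross-tabulation
#'
#' @param object a [crosstab()] object.
#' @param ... unused.
#' @return a ggplot (heatmap of percentages per superfamily).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.te_crosstab <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$superfamily,
                y = interaction(.data$te_set, .data$expressed, sep = " / "),
                fill = .data$pct)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#2166ac",
                        name = "% of TEs") +
    labs(x = NULL, y = "TE set / expressed",
         title = "TE expression by RIP and methylation status") +
    theme_minimal()
}

#' Plot sliding-window genome-defense tracks
#'
#' Stacked panels of GC fraction, CRI, RIP-site and methylated-cytosine
#' counts along each chromosome -- the moving-window view in which
#' RIP/methylation-rich regions appear as joint dips in GC and peaks in
#' the other tracks.
#'
#' @param tracks tibble from [windowed_tracks()].
#' @param chrom optional single chromosome to display.
#' @return a ggplot.
#' @export
plot_window_tracks <- function(tracks, chrom = NULL) {
  if (!is.null(chrom)) tracks <- tracks[tracks$chrom == chrom, ]
  d <- tracks |>
    tidyr::pivot_longer(cols = c("gc_fraction", "cri", "rip_site_count",
                                 "mc_count"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric,
                           levels = c("gc_fraction", "cri",
                                      "rip_site_count", "mc_count")))
  ggplot(d, aes(x = (.data$start + .data$end) / 2, y = .data$value)) +
    geom_line(na.rm = TRUE, linewidth = 0.3) +
    facet_grid(metric ~ chrom, scales = "free_y") +
    labs(x = "position (bp)", y = NULL,
         title = "Sliding-window genome-defense tracks") +
    theme_minimal()
}

#' Plot 5'-terminal nucleotide bias
#'
#' @param bias tibble from [five_prime_bias()] or a named list of them
#'   (one element per library).
#' @return a ggplot.
#' @export
plot_five_prime_bias <- function(bias) {
  if (!is.data.frame(bias)) {
    bias <- bind_rows(bias, .id = "library")
  } else {
    bias$library <- "library"
  }
  ggplot(bias, aes(x = .data$nt, y = .data$fraction, fill = .data$library)) +
    geom_col(position = "dodge") +
    labs(x = "5' nucleotide", y = "fraction of reads",
         title = "5'-terminal nucleotide bias") +
    theme_minimal()
}
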