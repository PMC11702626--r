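#' Plot per-cutoff conservation counts
#'
#' Qualifying sites, source genes and target genes against the window
#' cutoff -- the monotone funnel a rising cutoff produces.
#'
#' @param summary Summary tibble from [summarize_conservation()].
#' @return A ggplot object.
#' @export
plot_conservation_summary <- function(summary) {
  long <- tidyr::pivot_longer(
    summary, dplyr::all_of(c("n_sites", "n_source_genes", "n_target_genes")),
    names_to = "count", values_to = "n"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cutoff, y = .data$n, colour = .data$count
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$cutoff)) +
    ggplot2::labs(
      x = "minimum conserved window length (aa)",
      y = "qualifying count", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object A `crossphos_run`.
#' @export
autoplot.crossphos_run <- function(object, ...) {
  plot_conservation_summary(object$summary)
}

#' Plot an alignment's identity track
#'
#' Per-column identity of a pairwise alignment, with gap columns marked --
#' a quick visual of where an epitope window can fit.
#'
#' @param object A `protein_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_alignment <- function(object, ...) {
  td <- tidy(object)
  td$state <- dplyr::case_when(
    td$source == "-" | td$target == "-" ~ "gap",
    td$match ~ "identical",
    .default = "mismatch"
  )
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$column, y = 1, fill = .data$state
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      identical = "#2166ac", mismatch = "#fddbc7", gap = "grey70"
    )) +
    ggplot2::labs(x = "alignment column", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
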