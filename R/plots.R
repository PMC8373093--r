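# ggplot2 sits in Suggests: autoplot methods are registered lazily and all
# plot helpers fail softly if ggplot2 is unavailable.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("plotting requires the ggplot2 package")
}

#' Plot a CATS correlation vector profile
#'
#' @param x an `npd_cats` vector
#' @param ... unused
#' @return a ggplot: distance-bin profiles faceted by pharmacophore pair type
#' @exportS3Method ggplot2::autoplot
autoplot.npd_cats <- function(x, ...) {
  .need_ggplot()
  df <- tibble(
    pair = rep(.cats_pairs, each = 10L),
    bin = rep(0:9, times = 15L),
    value = as.numeric(x)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pair, nrow = 3) +
    ggplot2::labs(x = "topological distance (bonds)",
                  y = paste0("pair count (", attr(x, "scaling"), " scaling)"),
                  title = "CATS pharmacophore correlation vector") +
    ggplot2::theme_minimal()
}

#' Plot the candidate landscape of a design run
#'
#' @param x an `npd_design` from [run_design()]
#' @param ... unused
#' @return a ggplot: CATS distance against rank, colored by route depth
#' @exportS3Method ggplot2::autoplot
autoplot.npd_design <- function(x, ...) {
  .need_ggplot()
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$rank, y = .data$cats_distance,
                               colour = factor(.data$n_steps))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "CATS distance to template",
                  colour = "synthesis steps",
                  title = "De novo design candidates") +
    ggplot2::theme_minimal()
}

#' Plot the training curve of a self-organizing map
#'
#' @param x an `npd_som`
#' @param ... unused
#' @return a ggplot of quantization error per epoch
#' @exportS3Method ggplot2::autoplot
autoplot.npd_som <- function(x, ...) {
  .need_ggplot()
  ggplot2::ggplot(tibble(epoch = seq_along(x$qe), qe = x$qe),
                  ggplot2::aes(x = .data$epoch, y = .data$qe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean quantization error",
                  title = "SOM training curve") +
    ggplot2::theme_minimal()
}

#' Plot scaffold frequency statistics
#'
#' @param stats a tibble from [scaffold_stats()]
#' @param top_n scaffolds to display
#' @return a ggplot bar chart of scaffold fractions
#' @export
plot_scaffold_stats <- function(stats, top_n = 10L) {
  .need_ggplot()
  df <- utils::head(stats, top_n)
  df$scaffold <- factor(df$scaffold_key, levels = rev(df$scaffold_key))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$scaffold)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fraction of designs", y = NULL,
                  title = "Murcko scaffold frequencies") +
    ggplot2::theme_minimal()
}
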