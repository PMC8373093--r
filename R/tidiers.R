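#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a design run
#'
#' @param x an `npd_design` from [run_design()]
#' @param ... unused
#' @return a tibble without the list-columns: one row per candidate with
#'   rank, canonical key, fitness, CATS distance, step count and the
#'   scheme-id sequence of its best route
#' @export
tidy.npd_design <- function(x, ...) {
  out <- as_tibble(x)[, c("rank", "canonical_key", "fitness",
                          "cats_distance", "n_steps")]
  out$route_schemes <- vapply(x$route, function(r)
    paste(vapply(r, `[[`, "", "scheme"), collapse = ">"), "")
  out
}

#' One-row summary of a design run
#'
#' @param x an `npd_design`
#' @param ... unused
#' @return tibble: candidate count, best/median CATS distance, number of
#'   unique Murcko scaffolds, deepest route
#' @export
glance.npd_design <- function(x, ...) {
  sc <- if (nrow(x) > 0L) scaffold_stats(x) else NULL
  tibble(
    n_candidates = nrow(x),
    best_cats_distance = if (nrow(x)) min(x$cats_distance) else NA_real_,
    median_cats_distance = if (nrow(x)) stats::median(x$cats_distance)
      else NA_real_,
    n_unique_scaffolds = if (!is.null(sc))
      attr(sc, "n_unique_scaffolds") else 0L,
    max_route_steps = if (nrow(x)) max(x$n_steps) else 0L
  )
}

#' Tidy a trained self-organizing map
#'
#' @param x an `npd_som`
#' @param ... unused
#' @return tibble with one row per neuron: `neuron`, lattice `x`, `y`, and
#'   the weight-vector norm
#' @export
tidy.npd_som <- function(x, ...) {
  grid_x <- x$gx; grid_y <- x$gy
  wnorm <- sqrt(rowSums(x$weights^2))
  tibble(neuron = seq_len(nrow(x$weights)), x = grid_x, y = grid_y,
         weight_norm = wnorm)
}

#' One-row summary of a trained self-organizing map
#'
#' @param x an `npd_som`
#' @param ... unused
#' @return tibble: grid size, epochs, first/final quantization error
#' @export
glance.npd_som <- function(x, ...) {
  tibble(width = x$grid[[1]], height = x$grid[[2]], epochs = x$epochs,
         qe_first = x$qe[[1]], qe_final = utils::tail(x$qe, 1))
}

#' Tidy a cascaded target predictor
#'
#' @param x an `npd_spider`
#' @param ... unused
#' @return tibble with one row per target: reference-compound count and the
#'   mean background consensus score
#' @export
tidy.npd_spider <- function(x, ...) {
  tibble(
    target = x$targets,
    n_reference = colSums(x$memb),
    mean_background_score = colMeans(x$ref_scores)
  )
}
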