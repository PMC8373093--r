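# Forward-synthetic de novo design: deterministic breadth-first construction
# from building blocks through reaction schemes, bounded at three linear
# steps, scored by similarity to the template. The only stochastic element
# is the seeded sampling of start fragments; everything downstream is
# totally ordered (score, route length, canonical key), so a config + seed
# fully determines the output.

#' Design-run configuration
#'
#' @param template template molecule (`npd_mol` or structure string)
#' @param blocks building-block library: tibble from [read_library()], list
#'   of molecules, or character vector
#' @param schemes scheme registry list from [load_scheme_registry()]
#' @param n_start number of randomly selected start fragments (default 200,
#'   capped at the library size)
#' @param max_steps maximum linear synthesis steps, at most 3
#' @param beam_width intermediates kept per depth (default 50; `Inf` for
#'   exhaustive enumeration)
#' @param scaling,metric CATS parameterization used for fitness and ranking
#' @param seed integer seed for start-fragment sampling
#' @return a `design_config` list
#' @export
design_config <- function(template, blocks, schemes,
                          n_start = 200L, max_steps = 3L, beam_width = 50,
                          scaling = "occurrence", metric = "euclidean",
                          seed = 1L) {
  if (is.character(template)) template <- parse_structure(template)
  if (max_steps > 3L) abort("max_steps cannot exceed 3")
  if (max_steps < 1L) abort("max_steps must be at least 1")
  structure(list(template = template, blocks = .as_mol_table(blocks),
                 schemes = schemes, n_start = as.integer(n_start),
                 max_steps = as.integer(max_steps), beam_width = beam_width,
                 scaling = scaling, metric = metric, seed = as.integer(seed)),
            class = "design_config")
}

#' Graph-similarity fitness of a molecule against the template
#'
#' The default kernel maps the CATS pharmacophore-correlation distance into
#' `(0, 1]` as `1 / (1 + d)`: identical correlation vectors give 1. Any
#' alternative symmetric kernel can be supplied as a function of two
#' molecules.
#'
#' @param m,template molecules (`npd_mol` or structure strings)
#' @param scaling,metric CATS parameterization
#' @param kernel optional `function(m, template) -> numeric` overriding the
#'   default
#' @return similarity in `[0, 1]`
#' @export
fitness <- function(m, template, scaling = "occurrence",
                    metric = "euclidean", kernel = NULL) {
  if (is.character(m)) m <- parse_structure(m)
  if (is.character(template)) template <- parse_structure(template)
  if (!is.null(kernel)) return(kernel(m, template))
  d <- cats_distance(cats_vector(m, scaling), cats_vector(template, scaling),
                     metric)
  1 / (1 + d)
}

#' Run the breadth-first forward-synthetic design
#'
#' At each depth every surviving intermediate is combined, under every
#' scheme slot it can fill, with every applicable building block filling the
#' remaining slots; products are deduplicated by canonical key and the top
#' `beam_width` by fitness (ties: shorter route, then canonical key) seed
#' the next depth. All products of all depths are candidates; a depth-1
#' product can itself be a final design.
#'
#' @param cfg a [design_config()]
#' @return a tibble of class `npd_design`: `rank`, `canonical_key`,
#'   `fitness`, `cats_distance`, `n_steps`, `route` (list-column of step
#'   lists), `mol` (list-column), ranked by ascending CATS distance
#' @export
run_design <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  blocks <- cfg$blocks
  if (nrow(blocks) == 0L) abort("building-block library is empty")
  if (length(cfg$schemes) == 0L) abort("scheme registry is empty")
  tvec <- cats_vector(cfg$template, cfg$scaling)
  score <- function(m) 1 / (1 + cats_distance(cats_vector(m, cfg$scaling),
                                              tvec, cfg$metric))
  # per scheme x slot: building blocks that can fill the slot
  slot_fillers <- lapply(cfg$schemes, function(s)
    lapply(seq_len(s$arity), function(i)
      which(vapply(blocks$mol, function(b)
        has_substructure(b, s$slots[[i]]), TRUE))))

  n_start <- min(cfg$n_start, nrow(blocks))
  start_idx <- local_seed(cfg$seed, sample.int(nrow(blocks), n_start))
  frontier <- lapply(sort(start_idx), function(i)
    list(mol = blocks$mol[[i]], key = blocks$canonical_key[[i]],
         route = list()))

  candidates <- list()   # key -> list(mol, fit, route)
  consider <- function(cand) {
    k <- cand$key
    old <- candidates[[k]]
    if (is.null(old) ||
        cand$fit > old$fit + 1e-12 ||
        (abs(cand$fit - old$fit) <= 1e-12 &&
           length(cand$route) < length(old$route))) {
      candidates[[k]] <<- cand
    }
  }

  for (depth in seq_len(cfg$max_steps)) {
    produced <- list()   # key -> candidate (dedup within depth)
    for (f in frontier) {
      for (si in seq_along(cfg$schemes)) {
        s <- cfg$schemes[[si]]
        open <- match_slots(s, f$mol)
        for (slot in open) {
          others <- setdiff(seq_len(s$arity), slot)
          fill_sets <- lapply(others, function(i) slot_fillers[[si]][[i]])
          if (any(vapply(fill_sets, length, 1L) == 0L)) next
          combos <- if (length(others) == 0L) list(integer(0)) else
            asplit(as.matrix(expand.grid(fill_sets)), 1)
          for (cmb in combos) {
            reactants <- vector("list", s$arity)
            rkeys <- character(s$arity)
            reactants[[slot]] <- f$mol; rkeys[[slot]] <- f$key
            for (j in seq_along(others)) {
              reactants[[others[[j]]]] <- blocks$mol[[cmb[[j]]]]
              rkeys[[others[[j]]]] <- blocks$canonical_key[[cmb[[j]]]]
            }
            prods <- tryCatch(apply_scheme(s, reactants),
                              error = function(e) list())
            for (p in prods) {
              k <- mol_key(p)
              step <- list(scheme = s$id, reactants = rkeys, product = k)
              cand <- list(mol = p, key = k, fit = score(p),
                           route = c(f$route, list(step)))
              old <- produced[[k]]
              if (is.null(old) || cand$fit > old$fit) produced[[k]] <- cand
              consider(cand)
            }
          }
        }
      }
    }
    if (length(produced) == 0L) break
    # survivors to next depth: top beam_width by (fitness desc, route asc, key)
    ord <- order(-vapply(produced, `[[`, 0, "fit"),
                 vapply(produced, function(x) length(x$route), 1L),
                 vapply(produced, `[[`, "", "key"))
    keepn <- if (is.finite(cfg$beam_width)) min(cfg$beam_width, length(ord))
      else length(ord)
    frontier <- unname(produced[ord[seq_len(keepn)]])
  }

  if (length(candidates) == 0L) {
    warn("design run produced no candidates")
    out <- tibble(rank = integer(), canonical_key = character(),
                  fitness = numeric(), cats_distance = numeric(),
                  n_steps = integer(), route = list(), mol = list())
    class(out) <- c("npd_design", class(out))
    return(out)
  }
  out <- tibble(
    canonical_key = unname(vapply(candidates, `[[`, "", "key")),
    fitness = unname(vapply(candidates, `[[`, 0, "fit")),
    n_steps = unname(vapply(candidates, function(x) length(x$route), 1L)),
    route = unname(lapply(candidates, `[[`, "route")),
    mol = unname(lapply(candidates, `[[`, "mol"))
  )
  out$cats_distance <- 1 / out$fitness - 1
  out <- dplyr::arrange(out, .data$cats_distance, .data$canonical_key)
  out$rank <- seq_len(nrow(out))
  out <- dplyr::select(out, "rank", "canonical_key", "fitness",
                       "cats_distance", "n_steps", "route", "mol")
  class(out) <- c("npd_design", class(out))
  attr(out, "config") <- cfg[c("n_start", "max_steps", "beam_width",
                               "scaling", "metric", "seed")]
  out
}

#' Select the top-ranking designs
#'
#' @param candidates an `npd_design` tibble (or any tibble with
#'   `cats_distance`)
#' @param k number of designs to keep (all if `k` exceeds the count)
#' @param distance_cutoff optional strict upper bound: only candidates with
#'   `cats_distance < distance_cutoff` survive
#' @return the ranked subset, re-ranked from 1
#' @export
select_top <- function(candidates, k = 100L, distance_cutoff = NULL) {
  stopifnot(is.data.frame(candidates), "cats_distance" %in% names(candidates))
  out <- dplyr::arrange(candidates, .data$cats_distance, .data$canonical_key)
  if (!is.null(distance_cutoff))
    out <- dplyr::filter(out, .data$cats_distance < distance_cutoff)
  out <- utils::head(out, k)
  out$rank <- seq_len(nrow(out))
  out
}

# Evaluate an expression under a temporary RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
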