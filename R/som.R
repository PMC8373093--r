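# Self-organizing maps and the two-grid target-prediction cascade.
#
# Classical online SOM: per-sample best-matching-unit updates with an
# exponentially decaying learning rate and Gaussian lattice neighborhood.
# The cascade maps a query into a physicochemical grid and a pharmacophore
# (CATS) grid trained on an annotated reference library; targets are scored
# by their frequency among reference compounds co-located in the BMU
# neighborhood of each grid (consensus = mean of the two frequencies), and
# significance comes from a seeded empirical background with the add-one
# permutation estimator, so p > 0 always.

#' Train a self-organizing map
#'
#' @param data numeric matrix (observations x descriptor dimensions)
#' @param grid integer c(width, height) of the neuron lattice
#' @param epochs training epochs (full passes over the data)
#' @param alpha0 initial learning rate
#' @param sigma0 initial Gaussian neighborhood radius (defaults to half the
#'   larger grid side)
#' @param seed integer seed: weight initialization and the per-epoch
#'   presentation order are fully determined by it
#' @return an `npd_som` with fields `weights` (neurons x dims), `grid`,
#'   `epochs`, `qe` (per-epoch quantization error), `trained`
#' @export
train_som <- function(data, grid = c(6L, 6L), epochs = 50L, alpha0 = 0.5,
                      sigma0 = NULL, seed = 1L) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) abort("descriptor matrix contains non-finite values")
  w <- as.integer(grid[[1]]); h <- as.integer(grid[[2]])
  n_neuron <- w * h
  if (is.null(sigma0)) sigma0 <- max(w, h) / 2
  gx <- rep(seq_len(w), times = h); gy <- rep(seq_len(h), each = w)
  # squared lattice distances between neurons
  lat2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  local_seed(seed, {
    init_idx <- sample.int(nrow(data), n_neuron, replace = nrow(data) < n_neuron)
    weights <- data[init_idx, , drop = FALSE] +
      matrix(stats::rnorm(n_neuron * ncol(data), sd = 0.01), n_neuron)
    qe <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      alpha <- alpha0 * exp(-(ep - 1) / epochs)
      sigma <- max(0.5, sigma0 * exp(-(ep - 1) / epochs))
      ord <- sample.int(nrow(data))
      err <- 0
      for (i in ord) {
        x <- data[i, ]
        d2 <- rowSums(sweep(weights, 2, x, "-")^2)
        bmu <- which.min(d2)
        err <- err + sqrt(d2[[bmu]])
        hfac <- alpha * exp(-lat2[, bmu] / (2 * sigma^2))
        weights <- weights + hfac * sweep(-weights, 2, x, "+")
      }
      qe[[ep]] <- err / nrow(data)
    }
    structure(list(weights = weights, grid = c(w, h), gx = gx, gy = gy,
                   epochs = epochs, alpha0 = alpha0, sigma0 = sigma0,
                   seed = seed, qe = qe, dim = ncol(data), trained = TRUE),
              class = "npd_som")
  })
}

#' @export
print.npd_som <- function(x, ...) {
  cat("<npd_som> ", x$grid[[1]], "x", x$grid[[2]], " lattice, ", x$dim,
      "-dim weights, ", x$epochs, " epochs (QE ",
      sprintf("%.3f", utils::tail(x$qe, 1)), ")\n", sep = "")
  invisible(x)
}

#' Best-matching units for a descriptor matrix
#'
#' @param som a trained `npd_som`
#' @param data matrix (or single vector) in the som's descriptor space
#' @return integer vector of neuron indices
#' @export
som_bmu <- function(som, data) {
  stopifnot(inherits(som, "npd_som"), isTRUE(som$trained))
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (ncol(data) != som$dim)
    abort(sprintf("descriptor dimension %d does not match SOM dimension %d",
                  ncol(data), som$dim))
  apply(data, 1, function(x)
    which.min(colSums((t(som$weights) - x)^2)))
}

#' Build the cascaded SOM target predictor
#'
#' Trains one SOM on z-scaled physicochemical descriptors and one on CATS
#' pharmacophore vectors of an annotated reference library.
#'
#' @param refs reference library: tibble with a `mol` list-column and a
#'   `targets` column (character `;`-separated labels or list-column), e.g.
#'   from [read_reference_library()]
#' @param grid lattice size used for both grids
#' @param epochs,alpha0 SOM training schedule
#' @param neighborhood Chebyshev lattice radius of the scoring neighborhood
#'   (default 1: BMU plus its 8-connected neighbors)
#' @param seed integer seed (derived seeds train the two grids)
#' @return an `npd_spider` predictor object
#' @export
build_target_predictor <- function(refs, grid = c(8L, 8L), epochs = 50L,
                                   alpha0 = 0.5, neighborhood = 1L,
                                   seed = 1L) {
  stopifnot(is.data.frame(refs), "mol" %in% names(refs),
            "targets" %in% names(refs))
  targets <- refs$targets
  if (!is.list(targets))
    targets <- strsplit(as.character(targets), ";", fixed = TRUE)
  targets <- lapply(targets, function(t) unique(trimws(t[nzchar(trimws(t))])))
  if (any(vapply(targets, length, 1L) == 0L))
    abort("every reference compound needs at least one target label")
  all_targets <- sort(unique(unlist(targets)))

  phys <- descriptor_matrix(refs, "physchem")
  phar <- descriptor_matrix(refs, "pharmacophore")
  zs_phys <- .zscale_fit(phys); zs_phar <- .zscale_fit(phar)
  phys_z <- .zscale_apply(phys, zs_phys)
  phar_z <- .zscale_apply(phar, zs_phar)
  som_phys <- train_som(phys_z, grid, epochs, alpha0, seed = seed)
  som_phar <- train_som(phar_z, grid, epochs, alpha0, seed = seed + 1L)

  # reference target membership matrix
  memb <- matrix(0, nrow(refs), length(all_targets),
                 dimnames = list(NULL, all_targets))
  for (i in seq_along(targets)) memb[i, targets[[i]]] <- 1

  obj <- structure(list(
    som_phys = som_phys, som_phar = som_phar,
    zs_phys = zs_phys, zs_phar = zs_phar,
    memb = memb, targets = all_targets,
    neighborhood = as.integer(neighborhood),
    ref_keys = vapply(refs$mol, mol_key, ""),
    seed = seed
  ), class = "npd_spider")
  obj$bmu_phys <- som_bmu(som_phys, phys_z)
  obj$bmu_phar <- som_bmu(som_phar, phar_z)
  # per-neuron target frequency tables for each grid
  obj$freq_phys <- .neuron_freqs(som_phys, obj$bmu_phys, memb, neighborhood)
  obj$freq_phar <- .neuron_freqs(som_phar, obj$bmu_phar, memb, neighborhood)
  # per-reference consensus scores (used for the empirical background)
  obj$ref_scores <- (obj$freq_phys[obj$bmu_phys, , drop = FALSE] +
                       obj$freq_phar[obj$bmu_phar, , drop = FALSE]) / 2
  obj
}

# target frequencies among reference compounds co-located with each neuron's
# Chebyshev neighborhood
.neuron_freqs <- function(som, bmus, memb, radius) {
  n_neuron <- nrow(som$weights)
  freq <- matrix(0, n_neuron, ncol(memb), dimnames = list(NULL, colnames(memb)))
  cheb <- pmax(abs(outer(som$gx, som$gx, "-")), abs(outer(som$gy, som$gy, "-")))
  for (nu in seq_len(n_neuron)) {
    hood <- which(cheb[nu, ] <= radius)
    idx <- which(bmus %in% hood)
    if (length(idx) > 0L)
      freq[nu, ] <- colMeans(memb[idx, , drop = FALSE])
  }
  freq
}

#' @export
print.npd_spider <- function(x, ...) {
  cat("<npd_spider> cascade of two ", x$som_phys$grid[[1]], "x",
      x$som_phys$grid[[2]], " SOMs over ", length(x$ref_keys),
      " reference compounds, ", length(x$targets), " targets\n", sep = "")
  invisible(x)
}

# consensus scores (vector over predictor targets) for descriptor rows
.consensus_scores <- function(predictor, phys_z, phar_z) {
  b1 <- som_bmu(predictor$som_phys, phys_z)
  b2 <- som_bmu(predictor$som_phar, phar_z)
  (predictor$freq_phys[b1, , drop = FALSE] +
     predictor$freq_phar[b2, , drop = FALSE]) / 2
}

#' Predict macromolecular targets of a query molecule
#'
#' The query is mapped to its best-matching-unit neighborhood in both grids;
#' each target is scored by the mean of its frequencies among co-located
#' reference compounds in the two grids. Empirical significance: a seeded
#' background of reference compounds is resampled and
#' `p = (1 + #\{background >= observed\}) / (1 + n_background)`.
#'
#' @param predictor an `npd_spider` from [build_target_predictor()]
#' @param query an `npd_mol` or structure string
#' @param n_background background resamples (default 1000)
#' @param p_max report only predictions with `p <= p_max`
#'   (default 0.05; `filter = FALSE` disables)
#' @param filter logical: apply the `p_max` cutoff
#' @param seed integer seed for the background resampling
#' @return tibble (`target`, `score`, `p_value`) sorted by ascending p, then
#'   descending score
#' @export
predict_targets <- function(predictor, query, n_background = 1000L,
                            p_max = 0.05, filter = TRUE, seed = 1L) {
  stopifnot(inherits(predictor, "npd_spider"))
  if (is.character(query)) query <- parse_structure(query)
  phys <- matrix(physchem_descriptors(query), nrow = 1)
  phar <- matrix(as.numeric(cats_vector(query, "occurrence")), nrow = 1)
  phys_z <- .zscale_apply(phys, predictor$zs_phys)
  phar_z <- .zscale_apply(phar, predictor$zs_phar)
  obs <- .consensus_scores(predictor, phys_z, phar_z)[1, ]

  n_ref <- length(predictor$ref_keys)
  bg_idx <- local_seed(seed,
                       sample.int(n_ref, n_background, replace = TRUE))
  bg <- predictor$ref_scores[bg_idx, , drop = FALSE]
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(bg[, j] >= obs[[j]])) / (1 + n_background), 0)
  out <- tibble(target = predictor$targets, score = unname(obs),
                p_value = p)
  out <- dplyr::filter(out, .data$score > 0)
  if (filter) out <- dplyr::filter(out, .data$p_value <= p_max)
  dplyr::arrange(out, .data$p_value, dplyr::desc(.data$score), .data$target)
}
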