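# Seeded synthetic-fixture generators: a building-block library emulating a
# (tiny) purchasable-reagent catalog around the chemistry the bundled
# schemes cover, and an annotated reference library with planted,
# separation-controlled target classes for the SOM cascade.

#' Fixture generation specification
#'
#' @param seed integer seed; spec + seed fully determine the fixture files
#' @param n_building_blocks total library size (the six literature blocks
#'   are always included; decoys fill the remainder)
#' @param fractions named fractions (summing to 1) of decoy categories
#'   `diketone`, `aldehyde`, `acid`, `phenol`, `inert`
#' @param n_reference_targets planted target classes
#' @param compounds_per_target reference compounds per class
#' @param separation descriptor class-separation effect size (shift of the
#'   class mean, in feature-count units, along each class's axis); 0 makes
#'   all classes exchangeable
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L, n_building_blocks = 40L,
                         fractions = c(diketone = 0.15, aldehyde = 0.20,
                                       acid = 0.20, phenol = 0.20,
                                       inert = 0.25),
                         n_reference_targets = 5L,
                         compounds_per_target = 40L,
                         separation = 2.0) {
  fractions <- fractions[c("diketone", "aldehyde", "acid", "phenol", "inert")]
  if (any(is.na(fractions)) || abs(sum(fractions) - 1) > 1e-9)
    abort("fractions must cover the five decoy categories and sum to 1")
  if (n_building_blocks < 6L)
    abort("n_building_blocks must be at least 6 (the literature blocks)")
  structure(list(seed = as.integer(seed),
                 n_building_blocks = as.integer(n_building_blocks),
                 fractions = fractions,
                 n_reference_targets = as.integer(n_reference_targets),
                 compounds_per_target = as.integer(compounds_per_target),
                 separation = separation),
            class = "fixture_spec")
}

# the six always-included literature building blocks
.paper_blocks <- function() {
  c(block_5_diketone = "O=C(c1ccccc1Cl)C(=O)c1ccccc1Cl",
    block_6_aldehyde = "C=CCc1cccc(C=O)c1O",
    block_7_aldehyde = "CCOc1cc(C=O)ccc1O",
    glycolic_acid = "OCC(=O)O",
    methoxyacetic_acid = "COCC(=O)O",
    acetic_acid = "CC(=O)O")
}

.decoy_pool <- list(
  diketone = c("O=C(c1ccccc1)C(=O)c1ccccc1",
               "O=C(c1ccc(C)cc1)C(=O)c1ccc(C)cc1",
               "O=C(c1ccc(Cl)cc1)C(=O)c1ccc(Cl)cc1",
               "O=C(c1ccc(OC)cc1)C(=O)c1ccc(OC)cc1",
               "O=C(c1ccc(F)cc1)C(=O)c1ccc(F)cc1",
               "CC(=O)C(C)=O"),
  aldehyde = c("O=Cc1ccccc1", "O=Cc1ccc(C)cc1", "O=Cc1ccc(Cl)cc1",
               "O=Cc1ccc(OC)cc1", "CCC=O", "CCCC=O", "O=Cc1ccc(O)cc1",
               "O=Cc1cccc(O)c1"),
  acid = c("CCC(=O)O", "CCCC(=O)O", "OC(=O)c1ccccc1", "CC(C)C(=O)O",
           "OC(=O)CCl", "OC(=O)c1ccc(C)cc1", "OCCC(=O)O"),
  phenol = c("Oc1ccccc1", "Oc1ccc(C)cc1", "Oc1ccc(Cl)cc1", "Oc1ccc(CC)cc1",
             "Oc1ccc(OC)cc1", "Cc1cccc(O)c1"),
  inert = c("CCCCC", "CCCCCC", "CCOCC", "Cc1ccccc1", "COc1ccccc1",
            "CCc1ccccc1", "CCCOC", "CC(C)CC")
)

#' Generate a seeded building-block library
#'
#' Always contains the six literature blocks (the two aryl diketone/aldehyde
#' pairs of the published routes and the three ester acids); the remainder is
#' filled with decoys drawn category-by-category to match the spec fractions
#' (deterministic largest-remainder allocation, seeded sampling with
#' replacement within each category pool, duplicates de-duplicated by
#' appending nothing - the pools are cycled).
#'
#' @param spec a [fixture_spec()]
#' @param path optional output path (tab-separated `structure<TAB>id`)
#' @return tibble (`structure`, `id`, `category`); written to `path` if given
#' @export
generate_blocks <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  base <- .paper_blocks()
  n_decoy <- spec$n_building_blocks - length(base)
  cats <- names(spec$fractions)
  alloc <- diff(c(0, floor(cumsum(spec$fractions) * n_decoy + 1e-9)))
  names(alloc) <- cats
  alloc[[length(alloc)]] <- n_decoy - sum(alloc[-length(alloc)])
  rows <- tibble(structure = unname(base), id = names(base),
                 category = c("diketone", "aldehyde", "aldehyde",
                              "acid", "acid", "acid"))
  decoys <- local_seed(spec$seed, {
    out <- list()
    for (cat in cats) {
      k <- alloc[[cat]]
      if (k == 0L) next
      pool <- .decoy_pool[[cat]]
      pick <- pool[(sample.int(length(pool), 1L) + seq_len(k) - 2L) %%
                     length(pool) + 1L]
      out[[cat]] <- tibble(structure = pick,
                           id = sprintf("%s_%02d", cat, seq_len(k)),
                           category = cat)
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows, decoys)
  # every emitted structure must parse; canonical duplicates are allowed
  # (catalogs contain them) but parse failures are a generator bug
  invisible(lapply(out$structure, parse_structure))
  if (!is.null(path)) {
    writeLines(paste(out$structure, out$id, sep = "\t"), path)
  }
  out
}

# class axes: each planted class is shifted along one substituent feature
.ref_axes <- c("ome", "oh", "cl", "ring", "amine")

#' Generate a seeded annotated reference library with planted target classes
#'
#' Compounds are assembled from a carbon backbone carrying methoxy,
#' hydroxyl, chloro, phenyl and dimethylamino substituents; class `k` has
#' its mean count along one substituent axis shifted by `separation`, which
#' separates the classes in both descriptor spaces of the prediction
#' cascade (chain length is a shared noise dimension). With
#' `separation = 0` the classes are exchangeable and recovery falls to
#' chance.
#'
#' @param spec a [fixture_spec()]
#' @param path optional output path (`structure<TAB>id<TAB>targets`)
#' @return tibble (`structure`, `id`, `targets`, `mol`)
#' @export
generate_reference_library <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  K <- spec$n_reference_targets
  n_per <- spec$compounds_per_target
  base <- c(chain = 3, ome = 0, oh = 0, cl = 0, ring = 0, amine = 0)
  caps <- c(chain = 8, ome = 4, oh = 4, cl = 4, ring = 3, amine = 3)
  sds <- c(chain = 0.8, ome = 0.25, oh = 0.25, cl = 0.25, ring = 0.25, amine = 0.25)
  rows <- local_seed(spec$seed, {
    out <- list()
    for (k in seq_len(K)) {
      axis <- .ref_axes[[(k - 1L) %% length(.ref_axes) + 1L]]
      mu <- base
      mu[[axis]] <- mu[[axis]] + spec$separation * (1 + (k - 1L) %/%
                                                      length(.ref_axes))
      for (i in seq_len(n_per)) {
        counts <- pmin(caps, pmax(0, round(stats::rnorm(6, mu, sds))))
        names(counts) <- names(base)
        counts[["chain"]] <- max(1, counts[["chain"]])
        smi <- .assemble_chain_molecule(counts)
        out[[length(out) + 1L]] <- tibble(
          structure = smi,
          id = sprintf("T%d_%03d", k, i),
          targets = paste0("T", k))
      }
    }
    dplyr::bind_rows(out)
  })
  rows$mol <- lapply(rows$structure, parse_structure)
  if (!is.null(path))
    writeLines(paste(rows$structure, rows$id, rows$targets, sep = "\t"), path)
  rows
}

# backbone of L carbons, substituents distributed round-robin (at most two
# per backbone atom by construction)
.assemble_chain_molecule <- function(counts) {
  subs <- c(rep("OC", counts[["ome"]]), rep("O", counts[["oh"]]),
            rep("Cl", counts[["cl"]]), rep("c1ccccc1", counts[["ring"]]),
            rep("N(C)C", counts[["amine"]]))
  L <- max(counts[["chain"]], ceiling(length(subs) / 2))
  at <- rep("", L)
  for (j in seq_along(subs)) {
    pos <- (j - 1L) %% L + 1L
    at[[pos]] <- paste0(at[[pos]], "(", subs[[j]], ")")
  }
  paste0("C", at, collapse = "")
}

#' Read an annotated reference library file
#'
#' Format: `structure<TAB>id<TAB>targets` with `;`-separated target labels.
#'
#' @param path file path
#' @return tibble (`id`, `targets`, `canonical_key`, `mol`)
#' @export
read_reference_library <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read reference library: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) abort("reference library lines need structure, id, targets")
  mols <- lapply(parts, function(p) parse_structure(p[[1]]))
  tibble(
    id = vapply(parts, `[[`, "", 2L),
    targets = vapply(parts, `[[`, "", 3L),
    canonical_key = vapply(mols, mol_key, ""),
    mol = mols
  )
}

#' Bundled structures of the marinopyrrole design study
#'
#' The design template Marinopyrrole A, the published de novo designs
#' (2, 2a, 2b, 3), the imidazole intermediate 4, the building blocks 5-7,
#' the three ester acids, and the lophine scaffold, as a library tibble.
#'
#' @return tibble (`id`, `input`, `canonical_key`, `mol`)
#' @export
marinopyrrole_compounds <- function() {
  read_library(system.file("extdata", "marinopyrrole_set.tsv",
                           package = "npdesign", mustWork = TRUE))
}
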