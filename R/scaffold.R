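# Bemis-Murcko scaffolds: ring systems plus the linkers that connect them.
# Side chains are pruned by iteratively deleting terminal atoms attached
# through a plain single bond; atoms held by a double/triple bond (e.g. an
# exocyclic carbonyl oxygen) are retained. The generic framework abstracts
# every atom to carbon and every bond to a single bond.

#' Murcko scaffold of a molecule
#'
#' @param m an `npd_mol` (or structure string)
#' @return an `npd_scaffold`: list with `scaffold_key` (canonical SMILES of
#'   the pruned graph, `""` for acyclic molecules), `framework_key` (generic
#'   carbon framework), and `mol` (the scaffold molecule or `NULL`)
#' @export
murcko_scaffold <- function(m) {
  if (is.character(m)) m <- parse_structure(m)
  stopifnot(is_mol(m))
  # phase 1: peel terminal atoms until only rings + inter-ring linkers remain
  keep <- rep(TRUE, m$n)
  repeat {
    deg <- integer(m$n)
    for (k in seq_along(m$bond_a1)) {
      a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
      if (!keep[[a]] || !keep[[b]]) next
      deg[[a]] <- deg[[a]] + 1L; deg[[b]] <- deg[[b]] + 1L
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # phase 2: re-attach atoms bound to the core by a double/triple bond
  # (exocyclic carbonyls and the like stay part of the scaffold)
  if (any(keep)) {
    add <- logical(m$n)
    for (k in seq_along(m$bond_a1)) {
      a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
      if (m$bond_arom[[k]] || m$bond_order[[k]] < 2L) next
      if (keep[[a]] && !keep[[b]]) add[[b]] <- TRUE
      if (keep[[b]] && !keep[[a]]) add[[a]] <- TRUE
    }
    keep <- keep | add
  }
  if (!any(keep))
    return(structure(list(scaffold_key = "", framework_key = "", mol = NULL),
                     class = "npd_scaffold"))
  sm <- .subset_mol(m, which(keep))
  sm <- sanitize_mol(sm)
  fw <- sm
  fw$element <- rep("C", fw$n)
  fw$aromatic <- rep(FALSE, fw$n)
  fw$charge <- rep(0L, fw$n)
  fw$hcount <- rep(0L, fw$n); fw$hfixed <- rep(FALSE, fw$n)
  fw$hspec <- rep(FALSE, fw$n)
  fw$bond_order <- rep(1L, length(fw$bond_a1))
  fw$bond_arom <- rep(FALSE, length(fw$bond_a1))
  fw <- sanitize_mol(fw)
  structure(list(scaffold_key = mol_key(sm), framework_key = mol_key(fw),
                 mol = sm), class = "npd_scaffold")
}

#' @export
print.npd_scaffold <- function(x, ...) {
  cat("<npd_scaffold> ", if (nzchar(x$scaffold_key)) x$scaffold_key
      else "(empty: acyclic molecule)", "\n", sep = "")
  invisible(x)
}

# Subset atoms; implicit hydrogens are recomputed at the cut points, except
# that a pyrrole-type aromatic N-H keeps its hydrogen (it was never part of
# a side chain).
.subset_mol <- function(m, keep) {
  idx <- integer(m$n); idx[keep] <- seq_along(keep)
  bkeep <- m$bond_a1 %in% keep & m$bond_a2 %in% keep
  hfix <- m$aromatic[keep] & m$element[keep] == "N" & m$hcount[keep] > 0L
  new_mol(m$element[keep], m$charge[keep], m$aromatic[keep],
          ifelse(hfix, m$hcount[keep], 0L), hfix, m$map[keep],
          idx[m$bond_a1[bkeep]], idx[m$bond_a2[bkeep]],
          m$bond_order[bkeep], m$bond_arom[bkeep],
          hspec = hfix)
}

#' Scaffold frequency statistics over a design set
#'
#' @param designs a tibble with a `mol` list-column, a list of molecules, or
#'   a character vector of structure strings
#' @param by group by `"scaffold"` (Murcko, default) or `"framework"`
#'   (generic carbon framework)
#' @return a tibble (`scaffold_key`, `framework_key`, `n`, `fraction`) sorted
#'   by descending count (ties by key); fractions sum to one. Attributes
#'   `n_unique_scaffolds` and `n_unique_frameworks` carry the unique counts,
#'   also available via [glance()][generics::glance].
#' @export
scaffold_stats <- function(designs, by = c("scaffold", "framework")) {
  by <- match.arg(by)
  tab <- .as_mol_table(designs)
  if (nrow(tab) == 0L) abort("scaffold_stats needs at least one design")
  sc <- lapply(tab$mol, murcko_scaffold)
  df <- tibble(
    scaffold_key = vapply(sc, `[[`, "", "scaffold_key"),
    framework_key = vapply(sc, `[[`, "", "framework_key")
  )
  key <- if (by == "scaffold") "scaffold_key" else "framework_key"
  out <- df |>
    dplyr::count(.data[[key]], name = "n") |>
    dplyr::left_join(dplyr::distinct(df, .data[[key]], .keep_all = TRUE),
                     by = key) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data[[key]]) |>
    dplyr::select("scaffold_key", "framework_key", "n", "fraction")
  attr(out, "n_unique_scaffolds") <- dplyr::n_distinct(df$scaffold_key)
  attr(out, "n_unique_frameworks") <- dplyr::n_distinct(df$framework_key)
  out
}

#' Count library members containing a substructure
#'
#' @param library a tibble with a `mol` list-column, list of molecules, or
#'   character vector
#' @param query an `npd_query`, molecule or query string
#' @return list with `count` (integer) and `ids` (character vector of
#'   matching library ids, in library order)
#' @export
substructure_count <- function(library, query) {
  tab <- .as_mol_table(library)
  q <- .as_query(query)
  hits <- vapply(tab$mol, function(m) has_substructure(m, q), TRUE)
  list(count = sum(hits), ids = tab$id[hits])
}
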