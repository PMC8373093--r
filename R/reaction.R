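# Virtual reaction schemes: mapped-substructure transforms over 1-3 reactant
# slots. A transform string reads
#
#   slot1_pattern.slot2_pattern>>product_pattern
#
# Atom maps ([C:1]) tie reactant-pattern atoms to product-pattern atoms.
# Mapped atoms keep the substituents they carry in the reactant outside the
# pattern; unmapped reactant-pattern atoms are leaving atoms and are deleted
# (with anything that thereby disconnects); unmapped product-pattern atoms
# are introduced fresh (e.g. the two ring nitrogens the ammonia source
# contributes in an imidazole condensation). Hydrogen counts on mapped
# product atoms are recomputed from the final valence unless the product
# pattern states them explicitly (e.g. [nH]).

#' Define a reaction scheme
#'
#' @param id short identifier
#' @param name human-readable name
#' @param transform mapped transform string (see Details in the vignette)
#' @param example_reactants worked-example reactants, dot-separated structure
#'   string
#' @param example_product worked-example product structure
#' @param lit_tag free-text literature tag
#' @return an `npd_scheme`
#' @export
reaction_scheme <- function(id, name, transform, example_reactants = NULL,
                            example_product = NULL, lit_tag = "") {
  sides <- strsplit(transform, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    abort(sprintf("scheme '%s': transform must contain one '>>'", id))
  slot_strs <- strsplit(sides[[1]], ".", fixed = TRUE)[[1]]
  if (length(slot_strs) < 1L || length(slot_strs) > 3L)
    abort(sprintf("scheme '%s': 1-3 reactant slots required", id))
  slots <- lapply(slot_strs, parse_query)
  prod <- parse_query(sides[[2]])
  rmaps <- unlist(lapply(slots, function(s) s$map[s$map > 0L]))
  if (anyDuplicated(rmaps))
    abort(sprintf("scheme '%s': duplicated atom map on reactant side", id))
  pmaps <- prod$map[prod$map > 0L]
  if (anyDuplicated(pmaps))
    abort(sprintf("scheme '%s': duplicated atom map on product side", id))
  if (!all(pmaps %in% rmaps))
    abort(sprintf("scheme '%s': product maps %s missing from reactant side",
                  id, paste(setdiff(pmaps, rmaps), collapse = ",")))
  structure(list(
    id = id, name = name, arity = length(slots), slots = slots,
    slot_strings = slot_strs, product = prod, transform = transform,
    example_reactants = example_reactants, example_product = example_product,
    lit_tag = lit_tag
  ), class = "npd_scheme")
}

#' @export
print.npd_scheme <- function(x, ...) {
  cat("<npd_scheme> ", x$id, " (", x$name, "), arity ", x$arity, "\n  ",
      x$transform, "\n", sep = "")
  invisible(x)
}

#' Which slots of a scheme can a molecule fill?
#'
#' @param scheme an `npd_scheme`
#' @param m an `npd_mol`
#' @return integer vector of slot indices whose substructure query matches
#' @export
match_slots <- function(scheme, m) {
  stopifnot(inherits(scheme, "npd_scheme"), is_mol(m))
  which(vapply(scheme$slots, function(q) has_substructure(m, q), TRUE))
}

#' Apply a reaction scheme to an ordered list of reactants
#'
#' Every combination of slot matches is enumerated; all chemically valid,
#' distinct products are returned (deduplicated by canonical key). A
#' transform whose rewrite yields no valid molecule returns an empty list
#' with the reasons attached as the `reasons` attribute.
#'
#' @param scheme an `npd_scheme`
#' @param reactants list of `npd_mol` (or structure strings), one per slot
#' @return list of product `npd_mol`
#' @export
apply_scheme <- function(scheme, reactants) {
  stopifnot(inherits(scheme, "npd_scheme"))
  if (!is.list(reactants)) reactants <- as.list(reactants)
  reactants <- lapply(reactants, function(r)
    if (is.character(r)) parse_structure(r) else r)
  if (length(reactants) != scheme$arity)
    abort(sprintf("scheme '%s' needs %d reactants, got %d",
                  scheme$id, scheme$arity, length(reactants)))
  match_sets <- vector("list", scheme$arity)
  for (i in seq_len(scheme$arity)) {
    mm <- match_substructure(reactants[[i]], scheme$slots[[i]])
    if (length(mm) == 0L)
      abort(sprintf("reactant %d does not match slot %d (%s) of scheme '%s'",
                    i, i, scheme$slot_strings[[i]], scheme$id),
            class = "npd_slot_error")
    match_sets[[i]] <- mm
  }
  combos <- expand.grid(lapply(match_sets, seq_along))
  out <- list(); seen <- character(); reasons <- character()
  for (r in seq_len(nrow(combos))) {
    sel <- lapply(seq_len(scheme$arity), function(i)
      match_sets[[i]][[combos[r, i]]])
    p <- tryCatch(.rewrite_product(scheme, reactants, sel),
                  error = function(e) conditionMessage(e))
    if (is_mol(p)) {
      k <- mol_key(p)
      if (!k %in% seen) { seen <- c(seen, k); out[[length(out) + 1L]] <- p }
    } else {
      reasons <- c(reasons, p)
    }
  }
  attr(out, "reasons") <- unique(reasons)
  out
}

# Build one product molecule for a specific match of every slot.
.rewrite_product <- function(scheme, reactants, matches) {
  pp <- scheme$product
  n_pp <- pp$n
  element <- pp$element; charge <- pp$charge; aromatic <- pp$aromatic
  hcount <- pp$hcount; hfixed <- pp$hspec   # only explicit H survives
  b1 <- pp$bond_a1; b2 <- pp$bond_a2
  bord <- pp$bond_order; barom <- pp$bond_arom

  # map value -> (slot, reactant atom)
  src_slot <- integer(0); src_atom <- integer(0); src_map <- integer(0)
  for (i in seq_along(scheme$slots)) {
    q <- scheme$slots[[i]]
    for (qa in which(q$map > 0L)) {
      src_map <- c(src_map, q$map[[qa]])
      src_slot <- c(src_slot, i)
      src_atom <- c(src_atom, matches[[i]][[qa]])
    }
  }
  # product-pattern atom index for each map value
  prod_of_map <- stats::setNames(
    which(pp$map > 0L), pp$map[pp$map > 0L])

  # append external (unmatched) reactant atoms
  offset <- integer(length(reactants))
  ext_index <- vector("list", length(reactants))  # reactant atom -> new index
  for (i in seq_along(reactants)) {
    rm <- reactants[[i]]
    matched <- matches[[i]]
    keep <- setdiff(seq_len(rm$n), matched)
    idx <- integer(rm$n)
    if (length(keep) > 0L) {
      idx[keep] <- n_pp + length(element) - n_pp + seq_along(keep)
      element <- c(element, rm$element[keep])
      charge <- c(charge, rm$charge[keep])
      aromatic <- c(aromatic, rm$aromatic[keep])
      hcount <- c(hcount, rm$hcount[keep])
      hfixed <- c(hfixed, rep(TRUE, length(keep)))
    }
    ext_index[[i]] <- idx
    # reactant bonds
    qmatched <- matches[[i]]
    mapped_new <- integer(rm$n)   # reactant atom -> product atom (if mapped)
    q <- scheme$slots[[i]]
    for (qa in seq_len(q$n)) {
      ra <- qmatched[[qa]]
      mv <- q$map[[qa]]
      if (mv > 0L) mapped_new[[ra]] <- prod_of_map[[as.character(mv)]]
    }
    for (k in seq_along(rm$bond_a1)) {
      u <- rm$bond_a1[[k]]; v <- rm$bond_a2[[k]]
      u_in <- u %in% matched; v_in <- v %in% matched
      if (u_in && v_in) next                 # governed by the pattern
      if (!u_in && !v_in) {
        b1 <- c(b1, idx[[u]]); b2 <- c(b2, idx[[v]])
        bord <- c(bord, rm$bond_order[[k]]); barom <- c(barom, rm$bond_arom[[k]])
      } else {
        inn <- if (u_in) u else v; outn <- if (u_in) v else u
        tgt <- mapped_new[[inn]]
        if (tgt == 0L) next                  # bond to a leaving atom
        b1 <- c(b1, tgt); b2 <- c(b2, idx[[outn]])
        bord <- c(bord, rm$bond_order[[k]]); barom <- c(barom, rm$bond_arom[[k]])
      }
    }
  }
  m <- new_mol(element, as.integer(charge), aromatic, as.integer(hcount),
               hfixed, integer(length(element)),
               as.integer(b1), as.integer(b2), as.integer(bord), barom)
  m <- .keep_component_of(m, seq_len(n_pp))
  sanitize_mol(m)
}

# Restrict a molecule to the connected component(s) containing `core` atoms;
# errors if the core itself is split.
.keep_component_of <- function(m, core) {
  comp <- igraph::components(mol_graph(m))$membership
  keep_comp <- unique(comp[core])
  if (length(keep_comp) > 1L)
    mol_error("transform produced a disconnected product core")
  keep <- which(comp == keep_comp)
  if (length(keep) == m$n) return(m)
  idx <- integer(m$n); idx[keep] <- seq_along(keep)
  bkeep <- m$bond_a1 %in% keep & m$bond_a2 %in% keep
  new_mol(m$element[keep], m$charge[keep], m$aromatic[keep],
          m$hcount[keep], m$hfixed[keep], m$map[keep],
          idx[m$bond_a1[bkeep]], idx[m$bond_a2[bkeep]],
          m$bond_order[bkeep], m$bond_arom[bkeep],
          hspec = m$hspec[keep] %||% logical(length(keep)))
}

#' Load a reaction-scheme registry
#'
#' A registry is a tab-separated text file, one scheme per line:
#' `id<TAB>name<TAB>transform<TAB>example_reactants<TAB>example_product<TAB>lit_tag`
#' (`#` comments allowed). Every scheme is self-tested at load: applying the
#' transform to its worked-example reactants must reproduce the example
#' product (canonical-key equality), otherwise loading fails naming the
#' scheme.
#'
#' @param path registry file; defaults to the bundled registry
#' @return list of `npd_scheme`
#' @export
load_scheme_registry <- function(path = default_scheme_registry()) {
  if (!file.exists(path)) abort(paste0("cannot read scheme registry: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  schemes <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      abort(paste0("malformed registry line: ", substr(ln, 1, 60)))
    s <- tryCatch(
      reaction_scheme(f[[1]], f[[2]], f[[3]], f[[4]], f[[5]],
                      if (length(f) >= 6L) f[[6]] else ""),
      error = function(e)
        abort(sprintf("scheme '%s' failed to load: %s", f[[1]],
                      conditionMessage(e))))
    # load-time self-test
    rs <- strsplit(s$example_reactants, ".", fixed = TRUE)[[1]]
    expected <- mol_key(parse_structure(s$example_product))
    prods <- tryCatch(apply_scheme(s, lapply(rs, parse_structure)),
                      error = function(e)
                        abort(sprintf(
                          "scheme '%s' failed its self-test: %s",
                          s$id, conditionMessage(e))))
    keys <- vapply(prods, mol_key, "")
    if (!expected %in% keys)
      abort(sprintf(
        "scheme '%s' failed its self-test: example product not reproduced (got %s)",
        s$id, paste(keys, collapse = " ; ")))
    schemes[[s$id]] <- s
  }
  if (length(schemes) == 0L) abort("scheme registry is empty")
  schemes
}

#' Path of the bundled reaction-scheme registry
#' @return file path
#' @export
default_scheme_registry <- function() {
  system.file("schemes", "default_schemes.tsv", package = "npdesign",
              mustWork = TRUE)
}
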