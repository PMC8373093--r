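# Substructure matching: a small VF2-style backtracking monomorphism search.
# Queries use the same SMILES dialect as structures, with query semantics:
#   * unbracketed atoms put no constraint on hydrogen count;
#   * bracket H counts are exact requirements (e.g. [CH1]=O hits aldehydes
#     but not ketones, [OH1] a free hydroxyl but not an ether oxygen);
#   * charges always match exactly; aromaticity flags must agree;
#   * '*' matches any element;
#   * atom maps (e.g. [c:1]) tag atoms for reaction transforms and are
#     ignored during matching.

#' Parse a substructure query
#'
#' @param text query string (SMILES dialect, see package vignette)
#' @return an `npd_query` object
#' @export
parse_query <- function(text) {
  q <- .parse_smiles_raw(text)
  class(q) <- c("npd_query", class(q))
  attr(q, "query_string") <- text
  q
}

#' @export
print.npd_query <- function(x, ...) {
  cat("<npd_query> ", attr(x, "query_string"), " (", x$n, " atoms)\n", sep = "")
  invisible(x)
}

.as_query <- function(q) {
  if (inherits(q, "npd_query")) return(q)
  if (is_mol(q)) { class(q) <- c("npd_query", class(q)); return(q) }
  if (is.character(q)) return(parse_query(q))
  abort("query must be an npd_query, npd_mol or character string")
}

# adjacency: for each atom, matrix of (neighbor, bond index)
.adjacency <- function(m) {
  adj <- rep(list(NULL), m$n)
  for (k in seq_along(m$bond_a1)) {
    a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  adj
}

#' Find substructure matches of a query in a molecule
#'
#' Standard (non-induced) subgraph monomorphism: every query bond must map to
#' a target bond of compatible order/aromaticity; target atoms may carry
#' additional bonds.
#'
#' @param m target `npd_mol`
#' @param query an `npd_query`, `npd_mol` or query string
#' @param max_matches stop after this many matches (default all)
#' @return list of integer vectors; element `i` of a vector is the target
#'   atom matched to query atom `i`
#' @export
match_substructure <- function(m, query, max_matches = Inf) {
  stopifnot(is_mol(m))
  q <- .as_query(query)
  if (q$n == 0L || q$n > m$n) return(list())
  qadj <- .adjacency(q); tadj <- .adjacency(m)
  qdeg <- vapply(seq_len(q$n), function(a) NROW(qadj[[a]]), 1L)
  tdeg <- vapply(seq_len(m$n), function(a) NROW(tadj[[a]]), 1L)

  atom_ok <- function(qa, ta) {
    (q$element[[qa]] == "*" || q$element[[qa]] == m$element[[ta]]) &&
      q$aromatic[[qa]] == m$aromatic[[ta]] &&
      q$charge[[qa]] == m$charge[[ta]] &&
      (!isTRUE(q$hspec[[qa]]) || q$hcount[[qa]] == m$hcount[[ta]]) &&
      qdeg[[qa]] <= tdeg[[ta]]
  }
  bond_ok <- function(qk, tk) {
    if (q$bond_arom[[qk]] != m$bond_arom[[tk]]) return(FALSE)
    q$bond_arom[[qk]] || q$bond_order[[qk]] == m$bond_order[[tk]]
  }

  # query atom visit order: DFS keeping each new atom adjacent to the mapped
  # core (query must be connected)
  order <- integer(0); seen <- logical(q$n)
  stack <- 1L
  while (length(stack) > 0L) {
    a <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[a]]) next
    seen[[a]] <- TRUE; order <- c(order, a)
    nb <- qadj[[a]]
    if (!is.null(nb)) stack <- c(stack, nb[!seen[nb[, 1]], 1])
  }
  if (!all(seen)) abort("substructure queries must be connected")

  matches <- list()
  map <- integer(q$n)            # 0 = unmapped
  used <- logical(m$n)
  bt <- function(pos) {
    if (length(matches) >= max_matches) return(invisible())
    if (pos > q$n) {
      matches[[length(matches) + 1L]] <<- map
      return(invisible())
    }
    qa <- order[[pos]]
    nb <- qadj[[qa]]
    mapped_nb <- if (is.null(nb)) integer(0) else nb[map[nb[, 1]] != 0L, ,
                                                     drop = FALSE]
    cands <- if (NROW(mapped_nb) > 0L) {
      # restrict to target neighbors of the first mapped neighbor
      t0 <- map[[mapped_nb[1, 1]]]
      tnb <- tadj[[t0]]
      tnb[, 1]
    } else seq_len(m$n)
    for (ta in cands) {
      if (used[[ta]] || !atom_ok(qa, ta)) next
      ok <- TRUE
      if (NROW(mapped_nb) > 0L) {
        for (r in seq_len(nrow(mapped_nb))) {
          qb <- mapped_nb[r, 1]; qk <- mapped_nb[r, 2]
          tb <- map[[qb]]
          tnb <- tadj[[ta]]
          hit <- which(tnb[, 1] == tb)
          if (length(hit) == 0L || !bond_ok(qk, tnb[hit[[1]], 2])) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      map[[qa]] <<- ta; used[[ta]] <<- TRUE
      bt(pos + 1L)
      map[[qa]] <<- 0L; used[[ta]] <<- FALSE
      if (length(matches) >= max_matches) return(invisible())
    }
    invisible()
  }
  bt(1L)
  matches
}

#' Does a molecule contain a substructure?
#' @inheritParams match_substructure
#' @return logical scalar
#' @export
has_substructure <- function(m, query) {
  length(match_substructure(m, query, max_matches = 1L)) > 0L
}
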