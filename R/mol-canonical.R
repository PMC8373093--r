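# Canonical atom ranking and SMILES output.
#
# Ranks come from Weisfeiler-Lehman style refinement of an initial invariant
# (element, aromaticity, degree, H count, charge, ring membership). Remaining
# ties are broken by promoting, in turn, each member of the lowest tied class
# and keeping the lexicographically smallest SMILES the refinement produces —
# permutation-invariant by construction.

bond_class <- function(m) ifelse(m$bond_arom, 4L, m$bond_order)

.initial_invariant <- function(m) {
  ra <- if (length(m$bond_a1)) ring_atoms(m) else logical(m$n)
  deg <- tabulate(c(m$bond_a1, m$bond_a2), nbins = m$n)
  paste(m$element, m$aromatic, deg, m$hcount, m$charge, ra, sep = "|")
}

.labels_to_ranks <- function(lab) match(lab, sort(unique(lab)))

wl_refine <- function(m, ranks) {
  bc <- bond_class(m)
  adj <- vector("list", m$n)
  for (k in seq_along(m$bond_a1)) {
    a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  other <- function(k, a) if (m$bond_a1[[k]] == a) m$bond_a2[[k]] else m$bond_a1[[k]]
  # each round refines the partition (every new class is a subset of an old
  # one, the old rank being part of the label); stop when the class count
  # stops growing
  repeat {
    lab <- vapply(seq_len(m$n), function(a) {
      nb <- vapply(adj[[a]], function(k)
        sprintf("%02d:%06d", bc[[k]], ranks[[other(k, a)]]), "")
      sprintf("%06d;%s", ranks[[a]], paste(sort(nb), collapse = ","))
    }, "")
    new_ranks <- .labels_to_ranks(lab)
    stable <- length(unique(new_ranks)) == length(unique(ranks))
    ranks <- new_ranks
    if (stable) break
  }
  ranks
}

canonical_ranks <- function(m) {
  wl_refine(m, .labels_to_ranks(.initial_invariant(m)))
}

#' Canonical SMILES of a molecule
#'
#' @param m an `npd_mol`
#' @return a single SMILES string, invariant under atom renumbering
#' @export
canonical_smiles <- function(m) {
  comp <- igraph::components(mol_graph(m))
  if (comp$no > 1L)
    mol_error("molecule has disconnected fragments")
  .canon_rec(m, canonical_ranks(m))
}

.canon_rec <- function(m, ranks, depth = 0L) {
  if (depth > m$n) stop("canonicalization failed to converge")
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1L])
  if (length(tied) == 0L) return(.write_smiles(m, ranks))
  cls <- which(ranks == min(tied))
  best <- NULL
  for (a in cls) {
    r2 <- ranks * 2L
    r2[[a]] <- r2[[a]] - 1L
    s <- .canon_rec(m, wl_refine(m, .labels_to_ranks(r2)), depth + 1L)
    if (is.null(best) || s < best) best <- s
  }
  best
}

# Deterministic SMILES writer for a discrete ranking.
.write_smiles <- function(m, ranks) {
  bc <- bond_class(m)
  nbrs <- vector("list", m$n)
  for (k in seq_along(m$bond_a1)) {
    a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
    nbrs[[a]] <- rbind(nbrs[[a]], c(b, k))
    nbrs[[b]] <- rbind(nbrs[[b]], c(a, k))
  }
  implied <- implied_hcount(m)
  visited <- logical(m$n)
  used_bond <- logical(length(m$bond_a1))
  ring_open <- list()   # bond id -> digit
  next_digit <- 1L
  # pre-pass: DFS to identify back edges (ring closures)
  closure <- logical(length(m$bond_a1))
  st <- integer()
  start <- which.min(ranks)
  seen <- logical(m$n)
  dfs_order <- function(a) {
    seen[a] <<- TRUE
    nb <- nbrs[[a]]
    if (is.null(nb)) return(invisible())
    nb <- nb[order(ranks[nb[, 1]]), , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      b <- nb[r, 1]; k <- nb[r, 2]
      if (used_bond[[k]]) next
      used_bond[[k]] <<- TRUE
      if (seen[[b]]) closure[[k]] <<- TRUE else dfs_order(b)
    }
  }
  dfs_order(start)
  used_bond[] <- FALSE

  bond_sym <- function(k) {
    if (m$bond_arom[[k]]) return("")
    o <- m$bond_order[[k]]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    if (m$aromatic[[m$bond_a1[[k]]]] && m$aromatic[[m$bond_a2[[k]]]]) return("-")
    ""
  }

  atom_str <- function(a) {
    el <- m$element[[a]]
    sym <- if (m$aromatic[[a]]) tolower(el) else el
    plain <- el %in% .npd_organic && m$charge[[a]] == 0L &&
      m$hcount[[a]] == implied[[a]]
    if (plain) return(sym)
    h <- m$hcount[[a]]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- m$charge[[a]]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
      else if (ch > 0L) paste0("+", ch) else paste0("-", -ch)
    paste0("[", sym, hs, cs, "]")
  }

  emit <- function(a) {
    out <- atom_str(a)
    nb <- nbrs[[a]]
    if (!is.null(nb)) {
      nb <- nb[order(ranks[nb[, 1]]), , drop = FALSE]
      # ring-closure digits first
      for (r in seq_len(nrow(nb))) {
        k <- nb[r, 2]
        if (!closure[[k]]) next
        if (!is.null(ring_open[[as.character(k)]])) {
          d <- ring_open[[as.character(k)]]
          ring_open[[as.character(k)]] <<- NULL
        } else {
          d <- next_digit; next_digit <<- next_digit + 1L
          ring_open[[as.character(k)]] <<- d
        }
        ds <- if (d < 10L) as.character(d) else paste0("%", d)
        out <- paste0(out, bond_sym(k), ds)
        used_bond[[k]] <<- TRUE
      }
      branches <- character()
      for (r in seq_len(nrow(nb))) {
        b <- nb[r, 1]; k <- nb[r, 2]
        if (closure[[k]] || used_bond[[k]]) next
        used_bond[[k]] <<- TRUE
        visited[[b]] <<- TRUE
        branches <- c(branches, paste0(bond_sym(k), emit(b)))
      }
      if (length(branches) > 0L) {
        if (length(branches) > 1L)
          out <- paste0(out, paste0("(", branches[-length(branches)], ")",
                                    collapse = ""))
        out <- paste0(out, branches[[length(branches)]])
      }
    }
    out
  }
  visited[[start]] <- TRUE
  emit(start)
}
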