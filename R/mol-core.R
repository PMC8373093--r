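#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Elements accepted by the parser. Organic-subset atoms may be written without
# brackets; everything else needs [..].
.npd_organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.npd_aromatic_ok <- c("b", "c", "n", "o", "p", "s")

# Admissible valence lists (neutral atom); hypervalent P/S get the usual
# extended states. Charge shifts the target valence for the N/O/P/S/B block.
.npd_valences <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, Na = 1L, K = 1L, Se = c(2L, 4L, 6L)
)

new_mol <- function(element = character(), charge = integer(),
                    aromatic = logical(), hcount = integer(),
                    hfixed = logical(), map = integer(),
                    bond_a1 = integer(), bond_a2 = integer(),
                    bond_order = integer(), bond_arom = logical(),
                    hspec = logical(length(element))) {
  structure(list(
    n = length(element), element = element, charge = charge,
    aromatic = aromatic, hcount = hcount, hfixed = hfixed,
    hspec = hspec, map = map,
    bond_a1 = bond_a1, bond_a2 = bond_a2,
    bond_order = bond_order, bond_arom = bond_arom,
    smiles = NA_character_
  ), class = "npd_mol")
}

#' Test for a molecule object
#' @param x object
#' @return logical scalar
#' @export
is_mol <- function(x) inherits(x, "npd_mol")

#' @export
print.npd_mol <- function(x, ...) {
  cat("<npd_mol> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", x$n, " heavy, bonds: ", length(x$bond_a1),
      ", formula: ", format(molecular_formula(x)), "\n", sep = "")
  invisible(x)
}

#' @export
format.npd_mol <- function(x, ...) x$smiles

mol_error <- function(msg, pos = NA_integer_, text = NULL) {
  abort(
    if (is.na(pos)) msg else sprintf("%s (at position %d in %s)", msg, pos,
                                     encodeString(text, quote = "'")),
    class = "npd_parse_error", position = pos
  )
}

#' Parse a SMILES structure string into a molecule
#'
#' Supports the organic subset, bracket atoms with charge/H-count/atom-map,
#' ring closures (including `%nn`), branches, and bond symbols `- = # :`
#' (stereo bond marks `/ \\` are read as plain single bonds; constitution
#' only). Aromaticity is perceived with a single declared model: lowercase
#' input atoms are taken as aromatic, and Kekule 5- and 6-rings satisfying a
#' six-pi-electron count are promoted, so `C1=CC=CC=C1` and `c1ccccc1` yield
#' the same canonical key. Implicit hydrogens are filled from standard
#' valences; explicit bracket H counts are preserved.
#'
#' @param text a single structure string
#' @return an object of class `npd_mol` with its canonical key assigned
#' @examples
#' benzene <- parse_structure("c1ccccc1")
#' mol_key(benzene)
#' @export
parse_structure <- function(text) {
  sanitize_mol(.parse_smiles_raw(text), text = text)
}

# Tokenizer/parser without sanitization; used by parse_structure and by the
# substructure-query reader (queries may be fragments that would fail
# valence or ring checks).
.parse_smiles_raw <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    mol_error("structure must be a single character string")
  if (!nzchar(text)) mol_error("empty structure string", 1L, text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nch <- length(chars)

  element <- character(); charge <- integer(); aromatic <- logical()
  hcount <- integer(); hfixed <- logical(); hspec <- logical()
  map <- integer()
  b1 <- integer(); b2 <- integer(); bord <- integer(); barom <- logical()

  prev <- 0L                # atom index the next bond attaches to
  stack <- integer()        # open branch atoms
  pend <- NA_integer_       # pending explicit bond: 1,2,3 or 4L (aromatic)
  ring <- list()            # ring-closure table: key -> list(atom, bond)
  i <- 1L

  add_atom <- function(el, arom, chg, hc, hfix, mp, at_pos, hsp = FALSE) {
    element[[length(element) + 1L]] <<- el
    aromatic[[length(aromatic) + 1L]] <<- arom
    charge[[length(charge) + 1L]] <<- chg
    hcount[[length(hcount) + 1L]] <<- hc
    hfixed[[length(hfixed) + 1L]] <<- hfix
    hspec[[length(hspec) + 1L]] <<- hsp
    map[[length(map) + 1L]] <<- mp
    a <- length(element)
    if (prev > 0L) {
      o <- pend
      if (is.na(o)) o <- if (aromatic[[prev]] && arom) 4L else 1L
      b1[[length(b1) + 1L]] <<- prev; b2[[length(b2) + 1L]] <<- a
      bord[[length(bord) + 1L]] <<- if (o == 4L) 1L else o
      barom[[length(barom) + 1L]] <<- o == 4L
    } else if (!is.na(pend)) {
      mol_error("bond symbol with no preceding atom", at_pos, text)
    }
    prev <<- a; pend <<- NA_integer_
    invisible(a)
  }

  close_ring <- function(key, at_pos) {
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      o <- pend
      if (!is.na(op$bond) && !is.na(o) && op$bond != o)
        mol_error("conflicting ring-closure bond orders", at_pos, text)
      if (is.na(o)) o <- op$bond
      if (is.na(o)) o <- if (aromatic[[op$atom]] && aromatic[[prev]]) 4L else 1L
      if (op$atom == prev) mol_error("ring bond to self", at_pos, text)
      b1[[length(b1) + 1L]] <<- op$atom; b2[[length(b2) + 1L]] <<- prev
      bord[[length(bord) + 1L]] <<- if (o == 4L) 1L else o
      barom[[length(barom) + 1L]] <<- o == 4L
      ring[[key]] <<- NULL
    } else {
      if (prev == 0L) mol_error("ring closure before any atom", at_pos, text)
      ring[[key]] <<- list(atom = prev, bond = pend)
    }
    pend <<- NA_integer_
  }

  while (i <= nch) {
    ch <- chars[[i]]
    if (ch == "(") {
      if (prev == 0L) mol_error("branch with no preceding atom", i, text)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) mol_error("unmatched ')'", i, text)
      prev <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pend <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pend <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pend <- 3L; i <- i + 1L
    } else if (ch == ":") {
      pend <- 4L; i <- i + 1L
    } else if (ch == ".") {
      mol_error("multi-fragment input ('.') is not supported", i, text)
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        mol_error("'%' must be followed by two digits", i, text)
      close_ring(paste0("%", chars[i + 1L], chars[i + 2L]), i); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= nch && chars[[j]] != "]") j <- j + 1L
      if (j > nch) mol_error("unclosed bracket atom", i, text)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z])(@{0,2})(H([0-9]*))?((\\+{1,3}|-{1,3})([0-9]*)?)?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0L) mol_error("cannot parse bracket atom", i, text)
      sym <- m[[3]]
      arom <- sym %in% .npd_aromatic_ok
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      if (el == "H")
        mol_error("explicit hydrogen atoms are not supported; use H counts",
                  i, text)
      if (is.null(.npd_valences[[el]]))
        mol_error(paste0("unknown element '", el, "'"), i, text)
      hc <- if (nzchar(m[[5]])) if (nzchar(m[[6]])) as.integer(m[[6]]) else 1L else 0L
      chg <- 0L
      if (nzchar(m[[7]])) {
        sgn <- if (substr(m[[8]], 1, 1) == "+") 1L else -1L
        chg <- if (nzchar(m[[9]])) sgn * as.integer(m[[9]]) else sgn * nchar(m[[8]])
      }
      mp <- if (nzchar(m[[10]])) as.integer(m[[11]]) else 0L
      add_atom(el, arom, chg, hc, TRUE, mp, i, hsp = nzchar(m[[5]]))
      i <- j + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < nch) paste0(ch, chars[[i + 1L]]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, 0L, FALSE, 0L, i); i <- i + 2L
      } else if (ch %in% .npd_organic) {
        add_atom(ch, FALSE, 0L, 0L, FALSE, 0L, i); i <- i + 1L
      } else if (ch %in% .npd_aromatic_ok) {
        add_atom(paste0(toupper(ch)), TRUE, 0L, 0L, FALSE, 0L, i); i <- i + 1L
      } else if (ch == "*") {
        add_atom("*", FALSE, 0L, 0L, TRUE, 0L, i); i <- i + 1L
      } else {
        mol_error(paste0("unexpected symbol '", ch, "'"), i, text)
      }
    } else {
      mol_error(paste0("unexpected symbol '", ch, "'"), i, text)
    }
  }
  if (length(stack) > 0L) mol_error("unclosed branch", nch, text)
  if (length(ring) > 0L) mol_error("unclosed ring bond", nch, text)
  if (length(element) == 0L) mol_error("no atoms in input", 1L, text)
  if (!is.na(pend)) mol_error("dangling bond symbol", nch, text)

  new_mol(element, charge, aromatic, hcount, hfixed, map,
          b1, b2, bord, barom, hspec = hspec)
}

# ---- graph helpers ---------------------------------------------------------

mol_graph <- function(m) {
  igraph::make_graph(edges = rbind(m$bond_a1, m$bond_a2),
                     n = m$n, directed = FALSE)
}

# Topological (shortest-path bond-count) distance matrix.
mol_distances <- function(m) {
  if (m$n == 1L) return(matrix(0, 1, 1))
  igraph::distances(mol_graph(m))
}

# Logical vector: is bond i part of a ring (i.e. not a bridge)?
ring_bonds <- function(m) {
  nb <- length(m$bond_a1)
  if (nb == 0L) return(logical(0))
  g <- mol_graph(m)
  br <- as.integer(igraph::bridges(g))
  !(seq_len(nb) %in% br)
}

ring_atoms <- function(m) {
  rb <- ring_bonds(m)
  out <- logical(m$n)
  out[c(m$bond_a1[rb], m$bond_a2[rb])] <- TRUE
  out
}

# Smallest ring through each ring bond; returns a list of integer atom cycles
# (deduplicated by atom set, size <= max_size).
smallest_rings <- function(m, max_size = 7L) {
  rb <- which(ring_bonds(m))
  if (length(rb) == 0L) return(list())
  g <- mol_graph(m)
  seen <- character(); out <- list()
  for (e in rb) {
    u <- m$bond_a1[[e]]; v <- m$bond_a2[[e]]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    cyc <- as.integer(sp)
    if (length(cyc) < 3L || length(cyc) > max_size) next
    key <- paste(sort(cyc), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- cyc }
  }
  out
}

# ---- valence / implicit H / aromaticity ------------------------------------

# Target valence for an element with a formal charge.
.npd_target_valences <- function(el, chg) {
  v <- .npd_valences[[el]]
  if (is.null(v)) return(NULL)
  if (chg != 0L) {
    if (el == "C") v <- pmax(0L, v - abs(chg)) else v <- pmax(0L, v + chg)
  }
  v
}

# Integer "explicit" valence of every atom: aromatic bonds count 1.5 and the
# sum is rounded up (so aromatic CH in benzene sees 3, a fusion carbon 5).
explicit_valence <- function(m) {
  val <- numeric(m$n)
  o <- ifelse(m$bond_arom, 1.5, m$bond_order)
  for (k in seq_along(m$bond_a1)) {
    val[m$bond_a1[[k]]] <- val[m$bond_a1[[k]]] + o[[k]]
    val[m$bond_a2[[k]]] <- val[m$bond_a2[[k]]] + o[[k]]
  }
  ceiling(val - 1e-9)
}

# Implicit hydrogen count the parser/writer convention assigns to an atom
# given its bonds; used both at sanitization and to decide bracket printing.
implied_hcount <- function(m, idx = seq_len(m$n)) {
  ev <- explicit_valence(m)
  vapply(idx, function(a) {
    tv <- .npd_target_valences(m$element[[a]], m$charge[[a]])
    if (is.null(tv)) return(0L)
    dv <- tv[tv >= ev[[a]]]
    if (length(dv) == 0L) return(0L)
    as.integer(max(0L, dv[[1]] - ev[[a]]))
  }, integer(1))
}

# Promote Kekule rings to aromatic: 5/6-rings whose members are all
# sp2-eligible and whose pi-electron count is six.
perceive_aromaticity <- function(m) {
  rings <- smallest_rings(m, max_size = 6L)
  rings <- rings[vapply(rings, length, 1L) >= 5L]
  if (length(rings) == 0L) return(m)
  rb <- ring_bonds(m)
  bond_at <- function(a, b) {
    which((m$bond_a1 == a & m$bond_a2 == b) | (m$bond_a1 == b & m$bond_a2 == a))
  }
  repeat {
    changed <- FALSE
    for (cyc in rings) {
      k <- length(cyc)
      eidx <- vapply(seq_len(k), function(i)
        bond_at(cyc[[i]], cyc[[i %% k + 1L]])[1], 1L)
      if (all(m$bond_arom[eidx])) next
      pi_e <- 0; ok <- TRUE
      for (a in cyc) {
        inc <- which(m$bond_a1 == a | m$bond_a2 == a)
        if (m$aromatic[[a]]) {
          el <- m$element[[a]]
          pi_e <- pi_e + if (el %in% c("O", "S")) 2
            else if (el == "N" && m$hcount[[a]] > 0L) 2 else 1
          next
        }
        ords <- m$bond_order[inc]; aroms <- m$bond_arom[inc]
        dbl <- inc[ords == 2L & !aroms]
        if (any(ords == 3L)) { ok <- FALSE; break }
        el <- m$element[[a]]
        if (length(dbl) > 0L) {
          # a double bond into any ring keeps the atom in the pi system;
          # an exocyclic double (e.g. C=O) disqualifies the ring
          if (all(rb[dbl])) pi_e <- pi_e + 1 else { ok <- FALSE; break }
        } else if (el %in% c("N", "O", "S", "P")) {
          pi_e <- pi_e + 2
        } else {
          ok <- FALSE; break
        }
      }
      if (ok && pi_e == 6) {
        m$aromatic[cyc] <- TRUE
        m$bond_arom[eidx] <- TRUE
        m$bond_order[eidx] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Full sanitization: hydrogens, aromaticity, valence check, canonical key.
sanitize_mol <- function(m, text = NULL) {
  if (m$n == 0L) mol_error("molecule has no atoms")
  # duplicate bonds
  bk <- paste(pmin(m$bond_a1, m$bond_a2), pmax(m$bond_a1, m$bond_a2))
  if (anyDuplicated(bk)) mol_error("duplicate bond between the same atoms",
                                   text = text)
  # implicit H before aromatization, honouring Kekule orders for aliphatic
  # atoms and the aromatic convention for lowercase input
  need <- !m$hfixed
  if (any(need)) m$hcount[need] <- implied_hcount(m, which(need))
  m <- perceive_aromaticity(m)
  # aromatic atoms/bonds must sit in rings
  if (any(m$bond_arom)) {
    if (!all(ring_bonds(m)[m$bond_arom]))
      mol_error("aromatic bond outside a ring", text = text)
  }
  if (any(m$aromatic)) {
    ra <- ring_atoms(m)
    if (!all(ra[m$aromatic]))
      mol_error("aromatic atom outside a ring", text = text)
  }
  # valence admissibility: aromatic atoms are checked on their sigma
  # skeleton (each aromatic bond counts one; the pi system carries the rest),
  # aliphatic atoms on integer bond orders
  ev <- explicit_valence(m)
  sv <- numeric(m$n)
  for (k in seq_along(m$bond_a1)) {
    o <- if (m$bond_arom[[k]]) 1L else m$bond_order[[k]]
    sv[m$bond_a1[[k]]] <- sv[m$bond_a1[[k]]] + o
    sv[m$bond_a2[[k]]] <- sv[m$bond_a2[[k]]] + o
  }
  for (a in seq_len(m$n)) {
    if (m$element[[a]] == "*") next
    tv <- .npd_target_valences(m$element[[a]], m$charge[[a]])
    tot <- (if (m$aromatic[[a]]) sv[[a]] else ev[[a]]) + m$hcount[[a]]
    if (!is.null(tv) && tot > max(tv))
      mol_error(sprintf("valence %d not admissible for %s (atom %d)",
                        tot, m$element[[a]], a), text = text)
  }
  m$smiles <- canonical_smiles(m)
  m
}

#' Canonical key of a molecule
#' @param m an `npd_mol`
#' @return the canonical SMILES string
#' @export
mol_key <- function(m) {
  stopifnot(is_mol(m))
  m$smiles
}

#' Number of heavy atoms
#' @param m an `npd_mol`
#' @return integer count of non-hydrogen atoms
#' @export
heavy_atom_count <- function(m) {
  stopifnot(is_mol(m))
  m$n
}
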