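# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: CATS pair counting uses a hand-rolled
# Floyd-Warshall; exhaustive enumeration avoids run_design's search loop.

paper_set <- function() marinopyrrole_compounds()

paper_mol <- function(id) {
  tab <- paper_set()
  tab$mol[[which(tab$id == id)]]
}

# small, diverse molecule panel used by property tests
fixture_smiles <- c(
  "C", "CC", "CCO", "CC(=O)O", "OCC(=O)O", "c1ccccc1", "Cc1ccccc1",
  "Oc1ccccc1", "O=Cc1ccccc1", "c1ccncc1", "c1cc[nH]c1", "CCN", "CCN(C)C",
  "CC(C)Cl", "c1ccc(Cl)cc1", "CC(=O)Nc1ccccc1", "COC", "C=CC",
  "O=C(O)c1ccccc1", "c1ccc2ccccc2c1"
)
fixture_mols <- function() lapply(fixture_smiles, parse_structure)

# ---- independent CATS oracle ----------------------------------------------

# all-pairs shortest path by Floyd-Warshall over the bond list
oracle_distances <- function(m) {
  n <- m$n
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (k in seq_along(m$bond_a1)) {
    d[m$bond_a1[[k]], m$bond_a2[[k]]] <- 1
    d[m$bond_a2[[k]], m$bond_a1[[k]]] <- 1
  }
  for (via in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, via] + d[via, j] < d[i, j]) d[i, j] <- d[i, via] + d[via, j]
  d
}

oracle_cats <- function(m, scaling = "occurrence") {
  types <- assign_ppp_types(m)
  tnames <- c("D", "A", "P", "N", "L")
  pairs <- character(0)
  for (i in 1:5) for (j in i:5) pairs <- c(pairs, paste0(tnames[i], tnames[j]))
  v <- matrix(0, 15, 10, dimnames = list(pairs, 0:9))
  d <- oracle_distances(m)
  pkey <- function(a, b) {
    ia <- match(a, tnames); ib <- match(b, tnames)
    paste0(tnames[min(ia, ib)], tnames[max(ia, ib)])
  }
  for (a in seq_len(m$n)) {
    ta <- types[[a]]
    if (length(ta)) {
      for (x in seq_along(ta)) for (y in x:length(ta))
        v[pkey(ta[x], ta[y]), 1] <- v[pkey(ta[x], ta[y]), 1] + 1
    }
    for (b in seq_len(m$n)) {
      if (b <= a) next
      if (!is.finite(d[a, b]) || d[a, b] > 9) next
      for (x in types[[a]]) for (y in types[[b]])
        v[pkey(x, y), d[a, b] + 1] <- v[pkey(x, y), d[a, b] + 1] + 1
    }
  }
  if (scaling == "occurrence") {
    inc <- vapply(tnames, function(t)
      sum(vapply(types, function(tt) t %in% tt, TRUE)), 1)
    for (i in 1:5) for (j in i:5) {
      s <- inc[i] + inc[j]
      key <- paste0(tnames[i], tnames[j])
      v[key, ] <- if (s > 0) v[key, ] / s else 0
    }
  } else if (scaling == "size") v <- v / m$n
  out <- as.numeric(t(v))
  names(out) <- paste0(rep(pairs, each = 10), ".", 0:9)
  out
}

# ---- independent exhaustive route enumerator ------------------------------

# every product reachable in <= max_steps linear steps: each step applies a
# scheme with one previous product (or block) in one slot and blocks in the
# others; returns the set of canonical keys
oracle_enumerate <- function(blocks, schemes, max_steps = 3L) {
  keys <- vapply(blocks$mol, mol_key, "")
  level <- blocks$mol
  seen_products <- character(0)
  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (f in level) {
      for (s in schemes) {
        slots <- match_slots(s, f)
        for (sl in slots) {
          others <- setdiff(seq_len(s$arity), sl)
          pools <- lapply(others, function(i)
            Filter(function(b) sl != i || TRUE,
                   blocks$mol[vapply(blocks$mol, function(b)
                     length(match_slots(s, b)) > 0 && i %in% match_slots(s, b),
                     TRUE)]))
          grids <- if (length(others) == 0) list(list()) else {
            idx <- expand.grid(lapply(pools, seq_along))
            lapply(seq_len(nrow(idx)), function(r)
              lapply(seq_along(others), function(j) pools[[j]][[idx[r, j]]]))
          }
          for (fill in grids) {
            reactants <- vector("list", s$arity)
            reactants[[sl]] <- f
            for (j in seq_along(others)) reactants[[others[j]]] <- fill[[j]]
            prods <- tryCatch(apply_scheme(s, reactants),
                              error = function(e) list())
            for (p in prods) {
              k <- mol_key(p)
              if (!k %in% seen_products) {
                seen_products <- c(seen_products, k)
              }
              nxt[[length(nxt) + 1]] <- p
            }
          }
        }
      }
    }
    # next level: only newly formed products drive deeper steps
    dedup <- !duplicated(vapply(nxt, mol_key, ""))
    level <- nxt[dedup]
    if (length(level) == 0) break
  }
  sort(seen_products)
}

# atom-permuted copy of a molecule via an SD block with reordered atoms
permute_mol <- function(m, perm = NULL) {
  if (is.null(perm)) perm <- sample(m$n)
  inv <- integer(m$n); inv[perm] <- seq_len(m$n)
  m2 <- m
  for (f in c("element", "charge", "aromatic", "hcount", "hfixed",
              "hspec", "map"))
    m2[[f]] <- m[[f]][perm]
  m2$bond_a1 <- inv[m$bond_a1]; m2$bond_a2 <- inv[m$bond_a2]
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  write_sdf(f, list(m2), ids = "perm")
  read_library(f)$mol[[1]]
}
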