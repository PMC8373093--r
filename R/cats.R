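# CATS topological pharmacophore correlation vectors.
#
# Five potential pharmacophore point (PPP) types are assigned per atom from
# an explicit rule table; atom pairs are binned by shortest-path bond
# distance 0..9 over the 15 unordered type pairs, giving a 150-dimensional
# vector compared by Euclidean (default) or Manhattan distance.

.cats_types <- c("D", "A", "P", "N", "L")
.cats_pairs <- {
  p <- character(0)
  for (i in 1:5) for (j in i:5)
    p <- c(p, paste0(.cats_types[[i]], .cats_types[[j]]))
  p
}

#' The pharmacophore typing rule table
#'
#' The declared, versioned rule set used by [assign_ppp_types()]. An atom may
#' carry any subset of the five types.
#'
#' @return a tibble with columns `type`, `name`, `rule`
#' @export
cats_rule_table <- function() {
  tibble::tribble(
    ~type, ~name, ~rule,
    "D", "hydrogen-bond donor",
    "O or N bearing at least one hydrogen (formal charge >= 0)",
    "A", "hydrogen-bond acceptor",
    paste("any O not positively charged; N not positively charged,",
          "excluding pyrrole-type aromatic N-H, amide N and quaternary N"),
    "P", "positively ionizable",
    paste("N with positive formal charge; or neutral aliphatic amine N",
          "(all single bonds, no aromatic neighbor, not adjacent to C=O)"),
    "N", "negatively ionizable",
    paste("any atom with negative formal charge; or the hydroxyl O of a",
          "carboxylic acid group C(=O)OH"),
    "L", "lipophilic",
    paste("Cl, Br, I; neutral S with single bonds only; neutral C whose",
          "heavy-atom neighbors are all carbon")
  )
}

#' Assign potential pharmacophore point types to every atom
#'
#' @param m an `npd_mol`
#' @return a list (one element per atom) of character vectors drawn from
#'   `D` (donor), `A` (acceptor), `P` (pos. ionizable), `N` (neg. ionizable),
#'   `L` (lipophilic)
#' @export
assign_ppp_types <- function(m) {
  stopifnot(is_mol(m))
  adj <- .adjacency(m)
  nbrs <- function(a) if (is.null(adj[[a]])) integer(0) else adj[[a]][, 1]
  bond_orders <- function(a) {
    if (is.null(adj[[a]])) return(integer(0))
    ks <- adj[[a]][, 2]
    ifelse(m$bond_arom[ks], 4L, m$bond_order[ks])
  }
  # does atom a (a carbon) carry a double-bonded oxygen?
  is_carbonyl_c <- function(a) {
    if (m$element[[a]] != "C" || m$aromatic[[a]]) return(FALSE)
    nb <- adj[[a]]
    if (is.null(nb)) return(FALSE)
    any(m$element[nb[, 1]] == "O" & !m$bond_arom[nb[, 2]] &
          m$bond_order[nb[, 2]] == 2L)
  }
  lapply(seq_len(m$n), function(a) {
    el <- m$element[[a]]; ch <- m$charge[[a]]; h <- m$hcount[[a]]
    arom <- m$aromatic[[a]]
    nb <- nbrs(a); bo <- bond_orders(a)
    types <- character(0)
    if (el %in% c("N", "O") && h >= 1L && ch >= 0L) types <- c(types, "D")
    if (el == "O" && ch <= 0L) types <- c(types, "A")
    if (el == "N" && ch <= 0L && length(nb) < 4L &&
        !(arom && h >= 1L) && !any(vapply(nb, is_carbonyl_c, TRUE)))
      types <- c(types, "A")
    if (el == "N" &&
        (ch > 0L ||
           (ch == 0L && !arom && all(bo == 1L) &&
              !any(m$aromatic[nb]) && !any(vapply(nb, is_carbonyl_c, TRUE)))))
      types <- c(types, "P")
    neg <- ch < 0L
    if (!neg && el == "O" && h >= 1L && ch == 0L) {
      neg <- any(vapply(nb, is_carbonyl_c, TRUE))
    }
    if (neg) types <- c(types, "N")
    if (el %in% c("Cl", "Br", "I")) types <- c(types, "L")
    if (el == "S" && ch == 0L && all(bo %in% c(1L))) types <- c(types, "L")
    if (el == "C" && ch == 0L && (length(nb) == 0L ||
                                  all(m$element[nb] == "C")))
      types <- c(types, "L")
    types
  })
}

#' CATS correlation vector of a molecule
#'
#' Counts atom pairs by unordered pharmacophore type pair and shortest-path
#' topological distance 0-9 (longer pairs are discarded). The same-atom
#' convention: an atom contributes one count at distance 0 for every
#' unordered pair of types it carries, including same-type pairs.
#'
#' @param m an `npd_mol`
#' @param scaling `"occurrence"` (default; each type-pair block is divided by
#'   the summed incidence of its two types, 0/0 -> 0), `"raw"` (integer
#'   counts), or `"size"` (counts divided by heavy atom count)
#' @return a named numeric vector of length 150 (class `npd_cats`) with a
#'   `scaling` attribute
#' @export
cats_vector <- function(m, scaling = c("occurrence", "raw", "size")) {
  stopifnot(is_mol(m), m$n >= 1L)
  scaling <- match.arg(scaling)
  types <- assign_ppp_types(m)
  d <- mol_distances(m)
  v <- matrix(0, nrow = 15L, ncol = 10L,
              dimnames = list(.cats_pairs, as.character(0:9)))
  pidx <- matrix(0L, 5, 5, dimnames = list(.cats_types, .cats_types))
  for (i in 1:5) for (j in 1:5)
    pidx[i, j] <- match(paste0(.cats_types[[min(i, j)]],
                               .cats_types[[max(i, j)]]), .cats_pairs)
  for (a in seq_len(m$n)) {
    ta <- types[[a]]
    if (length(ta) == 0L) next
    ia <- match(ta, .cats_types)
    # same-atom pairs at distance 0, once per unordered pair
    for (x in seq_along(ia)) for (y in x:length(ia))
      v[pidx[ia[[x]], ia[[y]]], 1L] <- v[pidx[ia[[x]], ia[[y]]], 1L] + 1
    if (a < m$n) for (b in (a + 1L):m$n) {
      dd <- d[a, b]
      if (!is.finite(dd) || dd > 9) next
      tb <- types[[b]]
      if (length(tb) == 0L) next
      ib <- match(tb, .cats_types)
      for (x in ia) for (y in ib)
        v[pidx[x, y], dd + 1L] <- v[pidx[x, y], dd + 1L] + 1
    }
  }
  if (scaling == "occurrence") {
    inc <- vapply(.cats_types, function(t)
      sum(vapply(types, function(tt) t %in% tt, TRUE)), 1)
    for (i in 1:5) for (j in i:5) {
      s <- inc[[i]] + inc[[j]]
      r <- pidx[i, j]
      v[r, ] <- if (s > 0) v[r, ] / s else 0
    }
  } else if (scaling == "size") {
    v <- v / m$n
  }
  out <- as.numeric(t(v))
  names(out) <- paste0(rep(.cats_pairs, each = 10L), ".", 0:9)
  structure(out, scaling = scaling, class = "npd_cats")
}

#' @export
print.npd_cats <- function(x, ...) {
  nz <- sum(x > 0)
  cat("<CATS vector> 150 dims, ", nz, " non-zero, scaling=",
      attr(x, "scaling"), "\n", sep = "")
  invisible(x)
}

#' Distance between two CATS vectors
#'
#' @param a,b CATS vectors from [cats_vector()] with the same scaling scheme
#' @param metric `"euclidean"` (default) or `"manhattan"`
#' @return non-negative distance
#' @export
cats_distance <- function(a, b, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (!identical(attr(a, "scaling"), attr(b, "scaling")))
    abort(sprintf("CATS scaling schemes differ: '%s' vs '%s'",
                  attr(a, "scaling"), attr(b, "scaling")))
  d <- as.numeric(a) - as.numeric(b)
  if (metric == "euclidean") sqrt(sum(d^2)) else sum(abs(d))
}

#' Rank candidate molecules by CATS distance to a template
#'
#' @param candidates a tibble with a `mol` list-column (e.g. from
#'   [read_library()]), a list of `npd_mol`, or a character vector of
#'   structure strings
#' @param template the template `npd_mol` (or structure string)
#' @param scaling,metric passed to [cats_vector()] / [cats_distance()]
#' @return a tibble sorted by ascending `cats_distance` (ties broken by
#'   canonical key) with columns `rank`, `id`, `canonical_key`,
#'   `cats_distance`
#' @export
rank_by_cats <- function(candidates, template,
                         scaling = c("occurrence", "raw", "size"),
                         metric = c("euclidean", "manhattan")) {
  scaling <- match.arg(scaling); metric <- match.arg(metric)
  cand <- .as_mol_table(candidates)
  if (nrow(cand) == 0L) abort("no candidates to rank")
  if (is.character(template)) template <- parse_structure(template)
  vt <- cats_vector(template, scaling)
  cand$cats_distance <- vapply(cand$mol, function(m)
    cats_distance(cats_vector(m, scaling), vt, metric), 0)
  cand <- dplyr::arrange(cand, .data$cats_distance, .data$canonical_key)
  cand$rank <- seq_len(nrow(cand))
  dplyr::select(cand, "rank", "id", "canonical_key", "cats_distance",
                dplyr::everything())
}

# normalize candidate input to tibble(id, canonical_key, mol)
.as_mol_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("mol" %in% names(x))
    out <- as_tibble(x)
    if (!"canonical_key" %in% names(out))
      out$canonical_key <- vapply(out$mol, mol_key, "")
    if (!"id" %in% names(out)) out$id <- out$canonical_key
    return(out)
  }
  if (is.character(x)) x <- lapply(x, parse_structure)
  if (is_mol(x)) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, is_mol, TRUE)))
  keys <- vapply(x, mol_key, "")
  ids <- names(x) %||% keys
  tibble(id = ids, canonical_key = keys, mol = x)
}
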