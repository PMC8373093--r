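# Physicochemical descriptor block used by the first grid of the target-
# prediction cascade. Eight interpretable properties; logP and polar surface
# area are crude additive atom-contribution estimates (declared in the
# vignette), adequate for similarity mapping rather than property prediction.

.logp_contrib <- function(el, arom) {
  switch(el,
    C = if (arom) 0.30 else 0.20,
    N = if (arom) -0.40 else -0.60,
    O = if (arom) -0.30 else -0.50,
    S = 0.30, P = -0.30, F = 0.20, Cl = 0.70, Br = 0.90, I = 1.10,
    B = 0.10, 0)
}

.tpsa_contrib <- function(el, arom, h, dbl) {
  if (el == "O") {
    if (h > 0L) return(20.23)
    if (dbl) return(17.07)
    return(9.23)
  }
  if (el == "N") {
    if (arom) return(if (h > 0L) 15.79 else 12.89)
    if (h >= 2L) return(26.02)
    if (h == 1L) return(12.03)
    return(3.24)
  }
  0
}

#' Physicochemical descriptor vector of a molecule
#'
#' Eight properties: monoisotopic mass, additive logP estimate, H-bond donor
#' and acceptor counts (from the pharmacophore rule table), ring count
#' (cyclomatic number), rotatable-bond count, additive topological polar
#' surface area estimate, heavy-atom count.
#'
#' @param m an `npd_mol` (or structure string)
#' @return named numeric vector of length 8
#' @export
physchem_descriptors <- function(m) {
  if (is.character(m)) m <- parse_structure(m)
  stopifnot(is_mol(m))
  types <- assign_ppp_types(m)
  has_dbl <- logical(m$n)
  deg <- integer(m$n)
  for (k in seq_along(m$bond_a1)) {
    a <- m$bond_a1[[k]]; b <- m$bond_a2[[k]]
    deg[[a]] <- deg[[a]] + 1L; deg[[b]] <- deg[[b]] + 1L
    if (!m$bond_arom[[k]] && m$bond_order[[k]] == 2L)
      has_dbl[c(a, b)] <- TRUE
  }
  rb <- if (length(m$bond_a1)) ring_bonds(m) else logical(0)
  n_rot <- sum(!rb & !m$bond_arom & m$bond_order == 1L &
                 deg[m$bond_a1] >= 2L & deg[m$bond_a2] >= 2L)
  c(
    mw = monoisotopic_mass(molecular_formula(m)),
    logp = sum(vapply(seq_len(m$n), function(a)
      .logp_contrib(m$element[[a]], m$aromatic[[a]]), 0)) -
      0.15 * sum(m$hcount[m$element %in% c("N", "O")]),
    hbd = sum(vapply(types, function(t) "D" %in% t, TRUE)),
    hba = sum(vapply(types, function(t) "A" %in% t, TRUE)),
    rings = length(m$bond_a1) - m$n + 1L,
    rotb = n_rot,
    tpsa = sum(vapply(seq_len(m$n), function(a)
      .tpsa_contrib(m$element[[a]], m$aromatic[[a]], m$hcount[[a]],
                    has_dbl[[a]]), 0)),
    heavy = m$n
  )
}

#' Descriptor matrix for a set of molecules
#'
#' @param mols tibble with `mol` list-column, list of molecules, or character
#'   vector
#' @param space `"physchem"` (8 properties) or `"pharmacophore"` (150-dim
#'   CATS vector, occurrence scaling)
#' @return numeric matrix, one row per molecule
#' @export
descriptor_matrix <- function(mols, space = c("physchem", "pharmacophore")) {
  space <- match.arg(space)
  tab <- .as_mol_table(mols)
  rows <- lapply(tab$mol, function(m)
    if (space == "physchem") physchem_descriptors(m)
    else as.numeric(cats_vector(m, "occurrence")))
  mat <- do.call(rbind, rows)
  rownames(mat) <- tab$id
  mat
}

# z-scale columns against reference statistics; zero-variance columns pass
# through centred only.
.zscale_fit <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
.zscale_apply <- function(mat, zs) {
  sweep(sweep(mat, 2, zs$mu, "-"), 2, zs$sd, "/")
}
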