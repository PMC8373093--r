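# Monoisotopic masses of the most abundant isotope (IUPAC 2021 atomic mass
# evaluation, >= 6 decimals) and the electron mass in Da.
.npd_isotope_mass <- c(
  H  = 1.00782503207, B  = 11.00930536, C  = 12.0,
  N  = 14.0030740048, O  = 15.9949146196, F  = 18.99840316,
  Na = 22.98976928,  Si = 27.97692653,  P  = 30.97376163,
  S  = 31.97207100,  Cl = 34.96885268,  K  = 38.96370649,
  Se = 79.91652213,  Br = 78.91833710,  I  = 126.90447300
)
.npd_electron_mass <- 0.00054857990907

#' Molecular formula of a molecule
#'
#' Counts include implicit hydrogens; the net charge is the sum of formal
#' charges. Optionally protonate (`+H` per unit) to form e.g. the `[M+H]+`
#' ion the way high-resolution mass spectrometry reports it.
#'
#' @param m an `npd_mol`
#' @param protonate integer number of protons to add (default 0)
#' @return an `npd_formula`: named integer vector of element counts with a
#'   `charge` attribute
#' @examples
#' molecular_formula(parse_structure("c1ccccc1"))
#' @export
molecular_formula <- function(m, protonate = 0L) {
  stopifnot(is_mol(m))
  el <- m$element[m$element != "*"]
  counts <- table(el)
  out <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(m$hcount) + as.integer(protonate)
  if (nh > 0L) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + nh
  structure(out[order(names(out))],
            charge = sum(m$charge) + as.integer(protonate),
            class = "npd_formula")
}

#' Construct a formula from element counts
#' @param ... named integer counts, e.g. `C = 6, H = 6`
#' @param charge net charge
#' @return an `npd_formula`
#' @export
formula_of <- function(..., charge = 0L) {
  counts <- c(...)
  if (length(counts) > 0) {
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (any(counts < 0)) abort("element counts must be non-negative")
    counts <- counts[counts > 0]
  } else counts <- stats::setNames(integer(0), character(0))
  structure(counts[order(names(counts))], charge = as.integer(charge),
            class = "npd_formula")
}

#' @export
format.npd_formula <- function(x, ...) {
  els <- names(x)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  body <- paste0(vapply(hill, function(e)
    paste0(e, if (x[[e]] > 1L) x[[e]] else ""), ""), collapse = "")
  ch <- attr(x, "charge")
  sfx <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
    else if (ch > 0L) paste0(ch, "+") else paste0(-ch, "-")
  if (!nzchar(body)) body <- "(empty)"
  paste0(body, sfx)
}

#' @export
print.npd_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic (exact) mass of a formula or molecule
#'
#' Sum of the monoisotopic masses of the most abundant isotopes, minus one
#' electron mass per unit of positive charge (so a protonated ion mass lands
#' on the HRMS "calculated for" value at 4 decimals).
#'
#' @param f an `npd_formula` or an `npd_mol`
#' @return mass in Da (full precision; round to 4 decimals for reporting)
#' @examples
#' monoisotopic_mass(formula_of(H = 2, O = 1))
#' @export
monoisotopic_mass <- function(f) {
  if (is_mol(f)) f <- molecular_formula(f)
  stopifnot(inherits(f, "npd_formula"))
  els <- names(f)
  unknown <- setdiff(els, names(.npd_isotope_mass))
  if (length(unknown) > 0L)
    abort(paste0("no monoisotopic mass tabulated for element(s): ",
                 paste(unknown, collapse = ", ")))
  sum(.npd_isotope_mass[els] * as.numeric(f)) -
    attr(f, "charge") * .npd_electron_mass
}
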