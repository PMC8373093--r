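# Library input/output: tab-separated SMILES files and SD files (V2000).
# SD output writes aromatic bonds with order 4 and reads them back the same
# way; interchange with tools that insist on a Kekule SD block is a
# documented limitation.

#' Read a molecule library
#'
#' Accepts either a tab-separated file (`structure<TAB>id`, one record per
#' line, `#` comments allowed) or an SD file (V2000; detected by `V2000` /
#' `$$$$` markers). Records that fail to parse are skipped with a warning and
#' counted in the `n_skipped` attribute; input order is preserved.
#'
#' @param path file path
#' @return a tibble with columns `id`, `input`, `canonical_key` and a
#'   list-column `mol` of parsed molecules
#' @export
read_library <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read library file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("V2000", lines, fixed = TRUE)) ||
      any(trimws(lines) == "$$$$")) {
    return(.read_sdf(lines, path))
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  # a results-file header names its structure column; skip it silently
  if (length(lines) > 0L &&
      tolower(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][[1]]) %in%
        c("canonical_key", "structure", "smiles", "input"))
    lines <- lines[-1L]
  rows <- list(); skipped <- 0L
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    smi <- trimws(parts[[1]])
    id <- if (length(parts) >= 2L) trimws(parts[[2]]) else paste0("mol", i)
    m <- tryCatch(parse_structure(smi), error = function(e) e)
    if (is_mol(m)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = id, input = smi, canonical_key = mol_key(m), mol = list(m))
    } else {
      skipped <- skipped + 1L
      warn(sprintf("skipping record %d ('%s'): %s", i, id,
                   conditionMessage(m)))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(id = character(), input = character(),
           canonical_key = character(), mol = list())
  attr(out, "n_skipped") <- skipped
  out
}

.read_sdf <- function(lines, path) {
  recs <- split(lines, cumsum(dplyr::lag(trimws(lines) == "$$$$",
                                         default = FALSE)))
  rows <- list(); skipped <- 0L
  for (rec in recs) {
    rec <- rec[trimws(rec) != "$$$$"]
    if (length(rec) < 4L || !any(nzchar(trimws(rec)))) next
    id <- trimws(rec[[1]])
    m <- tryCatch(.parse_molblock(rec), error = function(e) e)
    if (is_mol(m)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = if (nzchar(id)) id else paste0("mol", length(rows) + 1L),
        input = mol_key(m), canonical_key = mol_key(m), mol = list(m))
    } else {
      skipped <- skipped + 1L
      warn(sprintf("skipping SD record '%s': %s", id, conditionMessage(m)))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(id = character(), input = character(),
           canonical_key = character(), mol = list())
  attr(out, "n_skipped") <- skipped
  out
}

.parse_molblock <- function(rec) {
  counts <- rec[[4]]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) mol_error("bad counts line in molblock")
  el <- character(na); chg <- integer(na); val <- integer(na)
  for (i in seq_len(na)) {
    ln <- rec[[4L + i]]
    el[[i]] <- trimws(substr(ln, 32, 34))
    v <- suppressWarnings(as.integer(trimws(substr(ln, 49, 51))))
    val[[i]] <- if (is.na(v)) 0L else v
  }
  b1 <- integer(nb); b2 <- integer(nb); bo <- integer(nb); ba <- logical(nb)
  for (i in seq_len(nb)) {
    ln <- rec[[4L + na + i]]
    b1[[i]] <- as.integer(substr(ln, 1, 3))
    b2[[i]] <- as.integer(substr(ln, 4, 6))
    o <- as.integer(substr(ln, 7, 9))
    if (o == 4L) { bo[[i]] <- 1L; ba[[i]] <- TRUE } else bo[[i]] <- o
  }
  for (ln in rec[grepl("^M  CHG", rec)]) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- f[[1]]
    for (j in seq_len(k)) chg[[f[[2L * j]]]] <- f[[2L * j + 1L]]
  }
  arom_atom <- logical(na)
  arom_atom[c(b1[ba], b2[ba])] <- TRUE
  # a non-zero valence field fixes the hydrogen count explicitly
  # (sigma valence: aromatic bonds count one)
  sigma <- integer(na)
  for (i in seq_len(nb)) {
    o <- if (ba[[i]]) 1L else bo[[i]]
    sigma[[b1[[i]]]] <- sigma[[b1[[i]]]] + o
    sigma[[b2[[i]]]] <- sigma[[b2[[i]]]] + o
  }
  hfix <- val > 0L
  hc <- ifelse(hfix, pmax(0L, ifelse(val == 15L, 0L, val) - sigma), 0L)
  m <- new_mol(el, chg, arom_atom, as.integer(hc), hfix, integer(na),
               b1, b2, bo, ba, hspec = hfix)
  sanitize_mol(m)
}

#' Write molecules to a tab-separated results file
#'
#' @param path output path
#' @param records a data frame with a `mol` list-column and/or a
#'   `canonical_key` column plus an `id` column; any further atomic columns
#'   are written as extra tab-separated fields
#' @return the path, invisibly
#' @export
write_results <- function(path, records) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records[, !vapply(records, is.list, TRUE), drop = FALSE])
  if (!"canonical_key" %in% names(df) && "mol" %in% names(records))
    df <- cbind(canonical_key = vapply(records$mol, mol_key, ""), df)
  first <- intersect(c("canonical_key", "id"), names(df))
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write molecules to an SD file (V2000)
#'
#' Aromatic bonds are written with bond order 4. Coordinates are zero (the
#' toolkit is purely topological).
#'
#' @param path output path
#' @param mols list of `npd_mol`
#' @param ids character ids (defaults to canonical keys)
#' @return the path, invisibly
#' @export
write_sdf <- function(path, mols, ids = NULL) {
  ids <- ids %||% vapply(mols, mol_key, "")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    nb <- length(m$bond_a1)
    writeLines(c(ids[[i]], "  npdesign", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", m$n, nb), con)
    implied <- implied_hcount(m)
    sigma <- integer(m$n)
    for (k in seq_len(nb)) {
      o <- if (m$bond_arom[[k]]) 1L else m$bond_order[[k]]
      sigma[[m$bond_a1[[k]]]] <- sigma[[m$bond_a1[[k]]]] + o
      sigma[[m$bond_a2[[k]]]] <- sigma[[m$bond_a2[[k]]]] + o
    }
    for (a in seq_len(m$n)) {
      # write the valence field when the implicit-H convention would not
      # reconstruct the stored hydrogen count (e.g. pyrrole-type N-H)
      val <- if (m$hcount[[a]] != implied[[a]]) {
        v <- sigma[[a]] + m$hcount[[a]]
        if (v == 0L) 15L else v
      } else 0L
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d%3d%3d%3d%3d",
                         0, 0, 0, m$element[[a]], 0L, 0L, 0L, 0L, 0L, val), con)
    }
    for (k in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0", m$bond_a1[[k]], m$bond_a2[[k]],
                         if (m$bond_arom[[k]]) 4L else m$bond_order[[k]]), con)
    chg <- which(m$charge != 0L)
    if (length(chg) > 0L)
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, m$charge[chg]),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
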