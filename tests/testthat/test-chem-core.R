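# Molecular core: parsing, canonicalization, formulas, exact masses, I/O.

test_that("parsing perceives aromaticity and assigns canonical keys", {
  benzene <- parse_structure("c1ccccc1")
  expect_equal(heavy_atom_count(benzene), 6)
  expect_true(all(benzene$aromatic))
  expect_true(all(benzene$element == "C"))
  # Kekule input unifies with the aromatic form
  expect_identical(mol_key(parse_structure("C1=CC=CC=C1")), mol_key(benzene))
  # pyrrole keeps its N-H through perception
  pyr <- parse_structure("C1=CC=CN1")
  expect_identical(mol_key(pyr), mol_key(parse_structure("c1cc[nH]c1")))
})

test_that("the named imidazole intermediate has the structure-derived formula", {
  # 2-allyl-6-(4,5-bis(2-chlorophenyl)-1H-imidazol-2-yl)phenol, drawn from
  # its IUPAC name
  m <- paper_mol("intermediate_4")
  expect_identical(format(molecular_formula(m)), "C24H18Cl2N2O")
})

test_that("parse errors are structured and name the position", {
  expect_error(parse_structure(""), class = "npd_parse_error")
  err <- tryCatch(parse_structure("CC(Q)C"), error = function(e) e)
  expect_s3_class(err, "npd_parse_error")
  expect_equal(err$position, 4L)
  expect_error(parse_structure("C1CC"), "ring")
  expect_error(parse_structure("CC("), "branch")
})

test_that("molecular formulas count implicit hydrogens and charges", {
  expect_identical(format(molecular_formula(parse_structure("c1ccccc1"))),
                   "C6H6")
  f2 <- molecular_formula(paper_mol("design_2"), protonate = 1)
  expect_identical(format(f2), "C26H21Cl2N2O3+")
  expect_identical(attr(f2, "charge"), 1L)
  f3 <- molecular_formula(paper_mol("design_3"), protonate = 1)
  expect_identical(format(f3), "C23H19Cl2N2O2+")
})

test_that("monoisotopic masses hit reference values", {
  expect_equal(round(monoisotopic_mass(formula_of(H = 2, O = 1)), 4), 18.0106)
  expect_equal(monoisotopic_mass(formula_of()), 0)
  expect_error(monoisotopic_mass(formula_of(Xx = 1)), "Xx")
  # protonated design 2: printed HRMS value
  expect_equal(round(monoisotopic_mass(
    molecular_formula(paper_mol("design_2"), protonate = 1)), 4), 479.0924)
})

test_that("mass is additive over disjoint formula merges", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "Cl", "S")
  for (i in 1:20) {
    a <- stats::setNames(sample(0:8, 6, replace = TRUE), els)
    b <- stats::setNames(sample(0:8, 6, replace = TRUE), els)
    fa <- do.call(formula_of, as.list(a))
    fb <- do.call(formula_of, as.list(b))
    fab <- do.call(formula_of, as.list(a + b))
    expect_equal(monoisotopic_mass(fab),
                 monoisotopic_mass(fa) + monoisotopic_mass(fb),
                 tolerance = 1e-10)
  }
})

test_that("protonation shifts mass by the proton mass", {
  for (m in fixture_mols()) {
    dm <- monoisotopic_mass(molecular_formula(m, protonate = 1)) -
      monoisotopic_mass(molecular_formula(m))
    expect_equal(dm, 1.00728, tolerance = 1e-4)
  }
})

test_that("canonicalization is idempotent and permutation-invariant", {
  set.seed(7)
  mols <- c(fixture_mols(), paper_set()$mol)
  for (m in mols) {
    k <- mol_key(m)
    expect_identical(mol_key(parse_structure(k)), k)   # idempotent
    for (r in 1:3) {
      expect_identical(mol_key(permute_mol(m)), k)
    }
  }
})

test_that("library round trips preserve canonical keys (TSV and SD file)", {
  set.seed(1)
  mols <- fixture_mols()[sample(length(fixture_smiles), 10)]
  keys <- vapply(mols, mol_key, "")
  tsv <- tempfile(fileext = ".tsv")
  write_results(tsv, tibble::tibble(id = paste0("m", 1:10), mol = mols))
  back <- read_library(tsv)
  expect_identical(back$canonical_key, keys)
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(sdf, mols, ids = paste0("m", 1:10))
  back2 <- read_library(sdf)
  expect_identical(back2$canonical_key, keys)
  expect_identical(back2$id, paste0("m", 1:10))
})

test_that("invalid library records are skipped with a warning and counted", {
  f <- tempfile()
  writeLines(c("CCO\tok1", "not_a_structure((\tbad", "c1ccccc1\tok2"), f)
  expect_warning(lib <- read_library(f), "skipping")
  expect_equal(nrow(lib), 2)
  expect_identical(lib$id, c("ok1", "ok2"))
  expect_equal(attr(lib, "n_skipped"), 1L)
  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_library(empty)), 0)
  expect_error(read_library(tempfile()), "cannot read")
})
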