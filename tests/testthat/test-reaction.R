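# Reaction engine: slot matching, transforms, registry self-tests.

reg <- load_scheme_registry()

test_that("match_slots identifies applicable slots", {
  expect_identical(match_slots(reg$ester, parse_structure("Oc1ccccc1")), 2L)
  expect_identical(match_slots(reg$ester, parse_structure("CCCC")),
                   integer(0))
  benzil <- parse_structure("O=C(c1ccccc1)C(=O)c1ccccc1")
  expect_identical(match_slots(reg$dr, benzil), 1L)
  # an aldehyde with a free phenol fits both the aldehyde slot and the
  # esterification phenol slot
  expect_identical(match_slots(reg$dr, paper_mol("block_6_aldehyde")), 2L)
  expect_identical(match_slots(reg$ester, paper_mol("block_6_aldehyde")), 2L)
})

test_that("the imidazole condensation reproduces its literature products", {
  benzil <- parse_structure("O=C(c1ccccc1)C(=O)c1ccccc1")
  benzaldehyde <- parse_structure("O=Cc1ccccc1")
  p <- apply_scheme(reg$dr, list(benzil, benzaldehyde))
  expect_length(p, 1)
  expect_identical(mol_key(p[[1]]), paper_set()$canonical_key[
    paper_set()$id == "lophine"])
  # the two published couplings
  p4 <- apply_scheme(reg$dr, list(paper_mol("block_5_diketone"),
                                  paper_mol("block_6_aldehyde")))
  expect_identical(mol_key(p4[[1]]), mol_key(paper_mol("intermediate_4")))
  p3 <- apply_scheme(reg$dr, list(paper_mol("block_5_diketone"),
                                  paper_mol("block_7_aldehyde")))
  expect_identical(mol_key(p3[[1]]), mol_key(paper_mol("design_3")))
})

test_that("esterification of the phenol intermediate gives the esters", {
  p2a <- apply_scheme(reg$ester, list(paper_mol("methoxyacetic_acid"),
                                      paper_mol("intermediate_4")))
  expect_true(mol_key(paper_mol("design_2a")) %in%
                vapply(p2a, mol_key, ""))
})

test_that("slot mismatches raise structured errors naming the slot", {
  expect_error(
    apply_scheme(reg$dr, list(parse_structure("CCCC"),
                              parse_structure("O=Cc1ccccc1"))),
    "slot 1", class = "npd_slot_error")
  expect_error(apply_scheme(reg$dr, list(parse_structure("CCCC"))),
               "needs 2 reactants")
})

test_that("product atoms are bounded by reactant atoms minus leaving groups", {
  for (s in reg) {
    rs <- lapply(strsplit(s$example_reactants, ".", fixed = TRUE)[[1]],
                 parse_structure)
    prods <- apply_scheme(s, rs)
    n_react <- sum(vapply(rs, heavy_atom_count, 1L))
    for (p in prods) expect_lte(heavy_atom_count(p), n_react)
  }
})

test_that("products are invariant under reactant atom renumbering", {
  set.seed(9)
  r1 <- paper_mol("block_5_diketone"); r2 <- paper_mol("block_6_aldehyde")
  base <- sort(vapply(apply_scheme(reg$dr, list(r1, r2)), mol_key, ""))
  for (i in 1:3) {
    p <- apply_scheme(reg$dr, list(permute_mol(r1), permute_mol(r2)))
    expect_identical(sort(vapply(p, mol_key, "")), base)
  }
})

test_that("registry loading self-tests every scheme and names failures", {
  expect_gte(length(reg), 2)
  expect_true(all(c("dr", "ester") %in% names(reg)))
  broken <- tempfile()
  writeLines(paste("badscheme", "broken example",
                   "[C:1](=[O:2])[OH1].[OH1:3][c:4]>>[C:1](=[O:2])[O:3][c:4]",
                   "CC(=O)O.Oc1ccccc1", "CCCC", sep = "\t"), broken)
  expect_error(load_scheme_registry(broken), "badscheme")
  malformed <- tempfile()
  writeLines("only\ttwo", malformed)
  expect_error(load_scheme_registry(malformed), "malformed")
})

test_that("a user-authored scheme with a worked example is accepted", {
  s <- reaction_scheme(
    "amide2", "amide coupling (user)",
    "[C:1](=[O:2])[OH1].[NH2:3][C:4]>>[C:1](=[O:2])[NH1:3][C:4]",
    example_reactants = "CC(=O)O.NCc1ccccc1",
    example_product = "CC(=O)NCc1ccccc1")
  p <- apply_scheme(s, list(parse_structure("CC(=O)O"),
                            parse_structure("NCc1ccccc1")))
  expect_identical(mol_key(p[[1]]),
                   mol_key(parse_structure("CC(=O)NCc1ccccc1")))
  # and via a registry file
  f <- tempfile()
  writeLines(paste("amide2", "amide coupling (user)",
                   "[C:1](=[O:2])[OH1].[NH2:3][C:4]>>[C:1](=[O:2])[NH1:3][C:4]",
                   "CC(=O)O.NCc1ccccc1", "CC(=O)NCc1ccccc1", sep = "\t"), f)
  reg2 <- load_scheme_registry(f)
  expect_identical(names(reg2), "amide2")
})
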