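# CATS pharmacophore typing, correlation vectors, distances, ranking.

test_that("pharmacophore typing follows the declared rule table", {
  phenol <- parse_structure("Oc1ccccc1")
  t_phenol <- assign_ppp_types(phenol)
  expect_setequal(t_phenol[[1]], c("D", "A"))        # phenol oxygen
  benzene <- parse_structure("c1ccccc1")
  expect_true(all(vapply(assign_ppp_types(benzene),
                         function(t) identical(t, "L"), TRUE)))
  # lophine: pyrrole-type N-H is a donor, pyridine-type N an acceptor
  lop <- parse_structure("c1ccc(-c2nc(-c3ccccc3)c(-c4ccccc4)[nH]2)cc1")
  tl <- assign_ppp_types(lop)
  nh <- which(lop$element == "N" & lop$hcount > 0)
  npyr <- which(lop$element == "N" & lop$hcount == 0)
  expect_true("D" %in% tl[[nh]])
  expect_false("A" %in% tl[[nh]])
  expect_true("A" %in% tl[[npyr]])
  # carboxylic acid hydroxyl is negatively ionizable
  acid <- parse_structure("CC(=O)O")
  to <- assign_ppp_types(acid)
  oh <- which(acid$element == "O" & acid$hcount == 1)
  expect_true("N" %in% to[[oh]])
})

test_that("CATS vectors match the all-pairs shortest-path oracle", {
  for (smi in fixture_smiles) {
    m <- parse_structure(smi)
    for (sc in c("raw", "occurrence", "size")) {
      expect_equal(as.numeric(cats_vector(m, sc)),
                   as.numeric(oracle_cats(m, sc)),
                   tolerance = 1e-12, info = paste(smi, sc))
    }
  }
})

test_that("degenerate and same-atom conventions hold", {
  v <- cats_vector(parse_structure("C"), "raw")
  expect_equal(unname(v[["LL.0"]]), 1)
  expect_equal(sum(v), 1)
  # ethanol: donor-acceptor same-atom pair at distance 0 on the hydroxyl O
  ve <- cats_vector(parse_structure("CCO"), "raw")
  expect_equal(unname(ve[["DA.0"]]), 1)
  expect_true(ve[["DL.2"]] >= 1)   # O to the terminal methyl carbon
})

test_that("vectors are invariant under atom renumbering", {
  set.seed(5)
  for (smi in c("CC(=O)Nc1ccccc1", "Oc1ccc(Cl)cc1", "CCN(C)C")) {
    m <- parse_structure(smi)
    v1 <- as.numeric(cats_vector(m))
    for (r in 1:3)
      expect_equal(as.numeric(cats_vector(permute_mol(m))), v1)
  }
})

test_that("the distance obeys metric axioms on fixture vectors", {
  vs <- lapply(fixture_mols(), cats_vector)
  n <- length(vs)
  set.seed(3)
  for (r in 1:40) {
    ijk <- sample(n, 3, replace = TRUE)
    a <- vs[[ijk[1]]]; b <- vs[[ijk[2]]]; cc <- vs[[ijk[3]]]
    dab <- cats_distance(a, b); dba <- cats_distance(b, a)
    expect_equal(dab, dba)                                  # symmetry
    expect_gte(dab, 0)
    expect_lte(dab, cats_distance(a, cc) + cats_distance(cc, b) + 1e-12)
  }
  expect_equal(cats_distance(vs[[1]], vs[[1]]), 0)          # identity
  expect_error(cats_distance(cats_vector(fixture_mols()[[1]], "raw"),
                             cats_vector(fixture_mols()[[2]], "size")),
               "scaling")
})

test_that("ranking is ascending, stable, and finds the template", {
  tpl <- paper_mol("marinopyrrole_A")
  cand <- paper_set()
  ranked <- rank_by_cats(cand, tpl)
  expect_equal(ranked$cats_distance[[1]], 0)
  expect_identical(ranked$id[[1]], "marinopyrrole_A")
  expect_true(!is.unsorted(ranked$cats_distance))
  # permuting the candidate order leaves the ranking unchanged
  perm <- cand[rev(seq_len(nrow(cand))), ]
  ranked2 <- rank_by_cats(perm, tpl)
  expect_identical(ranked$canonical_key, ranked2$canonical_key)
  # agrees with an independent brute-force sort
  tv <- cats_vector(tpl)
  d <- vapply(cand$mol, function(m) cats_distance(cats_vector(m), tv), 0)
  ord <- order(d, vapply(cand$mol, mol_key, ""))
  expect_identical(ranked$canonical_key,
                   vapply(cand$mol[ord], mol_key, ""))
})
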