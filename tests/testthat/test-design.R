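# Breadth-first forward-synthetic design.

reg <- load_scheme_registry()

paper_blocks <- function() {
  tab <- paper_set()
  tab[tab$id %in% c("block_5_diketone", "block_6_aldehyde",
                    "block_7_aldehyde", "glycolic_acid",
                    "methoxyacetic_acid", "acetic_acid"), ]
}

test_that("fitness is 1 for self and orders analogs sensibly", {
  tpl <- paper_mol("marinopyrrole_A")
  expect_equal(fitness(tpl, tpl), 1.0)
  far <- fitness(parse_structure("C"), tpl)
  near <- fitness(paper_mol("design_2"), tpl)
  expect_lt(far, near)
  # matches brute-force recomputation of the declared kernel
  set.seed(2)
  mols <- fixture_mols()
  for (r in 1:10) {
    ij <- sample(length(mols), 2)
    d <- sqrt(sum((oracle_cats(mols[[ij[1]]]) - oracle_cats(mols[[ij[2]]]))^2))
    expect_equal(fitness(mols[[ij[1]]], mols[[ij[2]]]), 1 / (1 + d),
                 tolerance = 1e-12)
  }
})

test_that("the design run rebuilds the published designs with their routes", {
  cfg <- design_config(paper_mol("marinopyrrole_A"), paper_blocks(), reg,
                       n_start = 6, beam_width = Inf, seed = 1)
  res <- run_design(cfg)
  key_of <- function(id) paper_set()$canonical_key[paper_set()$id == id]
  expect_true(all(vapply(c("intermediate_4", "design_3", "design_2",
                           "design_2a", "design_2b"),
                         function(id) key_of(id) %in% res$canonical_key, TRUE)))
  expect_equal(res$n_steps[res$canonical_key == key_of("intermediate_4")], 1L)
  expect_equal(res$n_steps[res$canonical_key == key_of("design_3")], 1L)
  expect_equal(res$n_steps[res$canonical_key == key_of("design_2a")], 2L)
  r2 <- res$route[[which(res$canonical_key == key_of("design_2"))]]
  expect_identical(vapply(r2, `[[`, "", "scheme"), c("dr", "ester"))
  # linear chaining: each step consumes the previous product
  expect_true(r2[[1]]$product %in% r2[[2]]$reactants)
})

test_that("identical config and seed reproduce the identical run", {
  cfg <- design_config(paper_mol("marinopyrrole_A"), paper_blocks(), reg,
                       n_start = 4, beam_width = 5, seed = 11)
  a <- run_design(cfg); b <- run_design(cfg)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$route, b$route)
})

test_that("exhaustive mode equals the independent enumerator on a toy library", {
  toy <- paper_blocks()[1:4, ]   # diketone, two aldehydes, glycolic acid
  cfg <- design_config(paper_mol("marinopyrrole_A"), toy, reg,
                       n_start = 4, beam_width = Inf, seed = 3)
  res <- run_design(cfg)
  expect_identical(sort(res$canonical_key),
                   oracle_enumerate(toy, reg, max_steps = 3))
})

test_that("no candidate ever exceeds three synthesis steps", {
  blocks <- generate_blocks(fixture_spec(seed = 5, n_building_blocks = 10))
  lib <- tibble::tibble(id = blocks$id, mol = lapply(blocks$structure,
                                                     parse_structure))
  for (seed in 1:10) {
    cfg <- design_config(paper_mol("marinopyrrole_A"), lib, reg,
                         n_start = 6, beam_width = 5, seed = seed)
    res <- run_design(cfg)
    if (nrow(res)) expect_true(all(res$n_steps <= 3L))
  }
})

test_that("a reconstructable template is recovered at rank 1, distance 0", {
  tpl <- parse_structure("CC(=O)Oc1ccccc1")   # phenyl acetate
  lib <- c(acetic = "CC(=O)O", phenol = "Oc1ccccc1")
  cfg <- design_config(tpl, lib, reg, n_start = 2, beam_width = Inf, seed = 1)
  res <- run_design(cfg)
  expect_identical(res$canonical_key[[1]], mol_key(tpl))
  expect_equal(res$cats_distance[[1]], 0)
  expect_equal(res$rank[[1]], 1L)
})

test_that("select_top is a monotone, cutoff-respecting prefix", {
  cfg <- design_config(paper_mol("marinopyrrole_A"), paper_blocks(), reg,
                       n_start = 6, beam_width = Inf, seed = 1)
  res <- run_design(cfg)
  top5 <- select_top(res, 5)
  expect_equal(nrow(top5), 5)
  expect_lte(max(top5$cats_distance), min(res$cats_distance[
    !res$canonical_key %in% top5$canonical_key]))
  cut <- select_top(res, 100, distance_cutoff = 1.2)
  expect_true(all(cut$cats_distance < 1.2))
  expect_equal(nrow(select_top(res, 10000)), nrow(res))
})

test_that("degenerate configs error or warn cleanly", {
  expect_error(design_config(paper_mol("marinopyrrole_A"), paper_blocks(),
                             reg, max_steps = 4), "max_steps")
  cfg <- design_config(paper_mol("marinopyrrole_A"),
                       c(inert = "CCCC"), reg, n_start = 1, seed = 1)
  expect_warning(res <- run_design(cfg), "no candidates")
  expect_equal(nrow(res), 0)
})
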