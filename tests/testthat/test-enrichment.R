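test_that("hypergeometric tail matches exact enumeration", {
  # U=10, N=5, S=4, n=4: C(5,4)C(5,0)/C(10,4) = 5/210
  annot <- tibble::tibble(term = "T1", member = sprintf("g%02d", 1:5))
  universe <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrich(sprintf("g%02d", c(1:4)), annot, universe)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$n, 4L)
  expect_equal(res$N, 5L)
  expect_equal(res$S, 4L)
  expect_equal(res$U, 10L)

  # no overlap: P(X >= 0) = 1
  res0 <- hypergeom_enrich(sprintf("g%02d", 6:9), annot, universe)
  expect_equal(res0$n, 0L)
  expect_equal(res0$p_value, 1)

  # sample = universe and full category: certain outcome
  res1 <- hypergeom_enrich(universe, annot, universe)
  expect_equal(res1$n, 5L)
  expect_equal(res1$p_value, 1)
})

test_that("p-values agree with the combinatorial oracle and are monotone in n", {
  set.seed(23)
  for (i in 1:300) {
    U <- sample(5:60, 1)
    N <- sample(1:U, 1)
    S <- sample(1:U, 1)
    n <- sample(max(0, S + N - U):min(N, S), 1)
    universe <- sprintf("u%03d", 1:U)
    term_members <- universe[1:N]
    smp <- c(term_members[seq_len(n)],
             setdiff(universe, term_members)[seq_len(S - n)])
    res <- hypergeom_enrich(smp, tibble::tibble(term = "T", member = term_members),
                            universe)
    expect_equal(res$p_value, hyper_tail_oracle(n, N, S, U), tolerance = 1e-12)
  }

  # monotone decreasing in n at fixed (U, N, S)
  ps <- vapply(0:5, hyper_tail_oracle, numeric(1), N = 10, S = 8, U = 40)
  expect_identical(ps, sort(ps, decreasing = TRUE))
})

test_that("module labelling picks the coherent category", {
  mods <- fake_module_set(list(
    fake_module(c("m1", "m2"), c("g1", "g2", "g3"), "g4")
  ))
  annot <- tibble::tibble(
    term = c(rep("perfect", 4), rep("noise", 3)),
    member = c("g1", "g2", "g3", "g4", "g5", "g6", "g7")
  )
  lab <- label_modules(mods, annot, gene_universe = sprintf("g%d", 1:20))
  expect_equal(lab$annotation$label, "perfect")
  expect_equal(lab$annotation$n, lab$annotation$S)  # n = S
  expect_equal(lab$annotation$fraction, 1)
  expect_equal(lab$annotation$mirna_label, "unannotated")

  # empty annotation: unannotated
  lab2 <- label_modules(mods, annot[0, ], gene_universe = sprintf("g%d", 1:20))
  expect_equal(lab2$annotation$label, "unannotated")
})

test_that("a planted category at 60% purity is almost always the top label", {
  set.seed(41)
  hits <- 0L
  universe <- sprintf("g%03d", 1:400)
  for (i in 1:100) {
    arm <- sample(universe, 30)
    planted <- c(sample(arm, 18), sample(setdiff(universe, arm), 12))
    annot <- dplyr::bind_rows(
      tibble::tibble(term = "planted", member = planted),
      purrr::map_dfr(1:10, function(k) {
        tibble::tibble(term = sprintf("bg%02d", k),
                       member = sample(universe, 30))
      })
    )
    mods <- fake_module_set(list(fake_module(c("m1", "m2"), arm)))
    lab <- label_modules(mods, annot, gene_universe = universe)
    if (lab$annotation$label == "planted") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("label permutation preserves values; cell shuffling worsens scores", {
  sim <- small_sim(n_modules = 2, rng_seed = 13, n_mirnas = 60, n_mrnas = 400)
  assoc <- sim_assoc(sim)
  cfg <- search_config(n_modules = 2, admission_margin = 0.2, rng_seed = 3)

  bl <- permuted_baseline(assoc, cfg, sim$annotation, mode = "labels",
                          rng_seed = 8)
  expect_s3_class(bl, "permuted_baseline")
  # relabeling is an isomorphism: value multiset and score multiset unchanged
  expect_identical(sort(bl$real_scores), sort(bl$permuted_scores))

  bc <- permuted_baseline(assoc, cfg, sim$annotation, mode = "cells",
                          real = bl$real, rng_seed = 9)
  expect_gt(min(bc$permuted_scores), min(bc$real_scores))
})

test_that("real enrichment beats the permuted-label baseline on planted data", {
  sim <- small_sim(n_modules = 5, rng_seed = 19, n_mirnas = 80, n_mrnas = 500)
  assoc <- sim_assoc(sim)
  cfg <- search_config(n_modules = 5, admission_margin = 0.2, rng_seed = 5)
  bl <- permuted_baseline(assoc, cfg, sim$annotation, mode = "labels",
                          rng_seed = 6)
  expect_true(all(bl$real_p < min(bl$permuted_p)))
  expect_lt(bl$p_value, 0.01)
})

test_that("validated pair density follows the covered-cell arithmetic", {
  mod <- fake_module(c("m1", "m2", "m3"), sprintf("g%d", 1:10))
  ms <- fake_module_set(list(mod))
  pairs <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                          mrna = c("g1", "g2", "g3"))
  d <- validated_pair_density(ms, pairs)
  expect_equal(d$n_pairs_inside, 3)
  expect_equal(d$cells_covered, 30)
  expect_equal(d$density, 0.1)
  expect_equal(d$modules_with_pair, 1)

  # disjoint pairs count zero; duplicates and order do not matter
  far <- tibble::tibble(mirna = "mx", mrna = "gx")
  expect_equal(validated_pair_density(ms, far)$n_pairs_inside, 0)
  dup <- dplyr::bind_rows(pairs, pairs)[sample(6), ]
  expect_equal(validated_pair_density(ms, dup)$density, 0.1)

  # overlapping modules: covered cells are counted once
  ms2 <- fake_module_set(list(mod, mod))
  expect_equal(validated_pair_density(ms2, pairs)$cells_covered, 30)
})

test_that("planted validated pairs enrich module density against baseline", {
  sim <- small_sim(n_modules = 3, rng_seed = 23, n_mirnas = 80, n_mrnas = 500)
  assoc <- sim_assoc(sim)
  cfg <- search_config(n_modules = 3, admission_margin = 0.2, rng_seed = 2)
  ms <- discover_modules(assoc, cfg)
  bl <- permuted_baseline(assoc, cfg, sim$annotation, mode = "labels",
                          real = label_modules(ms, sim$annotation,
                                               gene_universe = colnames(assoc)),
                          rng_seed = 14)
  d <- validated_pair_density(ms, sim$validated_pairs,
                              baseline = bl$permuted)
  expect_gte(d$fold, 5)
})
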