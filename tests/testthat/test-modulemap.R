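test_that("overlap similarity behaves as a max-denominator metric complement", {
  expect_equal(overlap(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap(letters[1:3], letters[10:12]), 0)
  expect_equal(overlap(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  expect_equal(overlap(c("a", "b", "c", "d"), c("a", "b"), "union"), 0.5)
  expect_equal(overlap(c("a", "b", "c"), c("a", "b"), "union"), 2 / 3)
  expect_error(overlap(character(0), "a"), "non-empty")
})

test_that("similarity matrices are symmetric, unit-diagonal and metric", {
  set.seed(61)
  pool <- sprintf("f%03d", 1:60)
  mods <- lapply(1:25, function(i) {
    fake_module(sample(pool, sample(3:8, 1)), sample(pool, sample(5:15, 1)))
  })
  sims <- similarity_matrices(fake_module_set(mods))
  for (s in sims) {
    expect_true(isSymmetric(s))
    expect_equal(unname(diag(s)), rep(1, 25))
    expect_true(all(s >= 0 & s <= 1))
    # triangle inequality of d = 1 - s over every triple (exhaustive)
    d <- 1 - s
    triples <- combn(25, 3)
    for (t in seq_len(ncol(triples))) {
      i <- triples[1, t]; j <- triples[2, t]; k <- triples[3, t]
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
      expect_lte(d[j, k], d[j, i] + d[i, k] + 1e-12)
    }
  }

  # identical miRNA sets: off-diagonal 1 on the miRNA side
  twins <- fake_module_set(list(fake_module(c("a", "b"), c("x", "y")),
                                fake_module(c("a", "b"), c("z", "w"))))
  s2 <- similarity_matrices(twins)
  expect_equal(s2$mirna[1, 2], 1)
  expect_equal(s2$mrna[1, 2], 0)
  expect_error(similarity_matrices(fake_module_set(list(twins$modules[[1]]))),
               "at least 2")
})

test_that("classical MDS reproduces embeddable distances", {
  # collinear configuration d(A,B) = 1, d(B,C) = 1, d(A,C) = 2
  s <- 1 - matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  x <- classical_mds(s, 1)[, 1]
  gaps <- as.vector(dist(x))
  expect_equal(sort(gaps), c(1, 1, 2), tolerance = 1e-8)

  # identical modules project to identical (all-zero) coordinates
  s1 <- matrix(1, 3, 3)
  expect_equal(unname(classical_mds(s1, 1)[, 1]), rep(0, 3))

  # random 1-D-embeddable distances reconstruct to < 1e-8, and the sign
  # convention makes the output reflection-stable
  set.seed(77)
  for (i in 1:10) {
    pts <- sort(runif(8, 0, 0.5))
    d <- as.matrix(dist(pts))
    x <- classical_mds(1 - d, 1)[, 1]
    expect_lt(max(abs(as.matrix(dist(x)) - d)), 1e-8)
    x2 <- classical_mds(1 - d, 1)[, 1]
    expect_identical(x, x2)
    expect_gte(x[which.max(abs(x))], 0)
    # independent cross-check against stats::cmdscale up to reflection
    ref <- cmdscale(d, k = 1)[, 1]
    expect_lt(min(max(abs(x - ref)), max(abs(x + ref))), 1e-8)
  }
})

test_that("layout places, sizes and colours modules as specified", {
  mods <- list(
    fake_module(c("a", "b"), sprintf("p%d", 1:6)),
    fake_module(c("a", "b"), sprintf("q%d", 1:6)),
    fake_module(c("c", "d"), c(sprintf("p%d", 1:4), "q1", "q2")),
    fake_module(c("e", "f"), sprintf("s%d", 1:6))
  )
  ms <- fake_module_set(mods)
  ms$annotation <- tibble::tibble(
    module = 1:4, label = c("t1", "t2", "t3", "t4"),
    n = c(6L, 3L, 2L, 1L), N = 10L, S = c(6L, 30L, 10L, 10L), U = 100L,
    p_value = 1e-4, fraction = c(1, 0.1, 0.2, 0.1),
    mirna_label = "unannotated", mirna_p_value = NA_real_,
    top_terms = list(tibble::tibble())
  )
  lay <- layout_modules(ms)
  # modules 1 and 2 share all miRNAs and no mRNAs: co-located on X only
  expect_equal(lay$x[1], lay$x[2], tolerance = 1e-10)
  expect_gt(abs(lay$y[1] - lay$y[2]), 0.05)
  # radius is proportional to the enriched fraction: 100% vs 10% is 10:1
  expect_equal(lay$radius[1] / lay$radius[2], 10)
  # z-order is a permutation, larger modules first (rank 1 = back)
  expect_setequal(lay$z_rank, 1:4)
  expect_true(all(lay$radius > 0))

  p <- autoplot(lay)
  expect_s3_class(p, "ggplot")
})

test_that("layout is invariant to module input order", {
  set.seed(71)
  pool <- sprintf("f%03d", 1:40)
  mods <- lapply(1:6, function(i) {
    fake_module(sample(pool, 4), sample(pool, 8))
  })
  ms <- fake_module_set(mods)
  ms$annotation <- tibble::tibble(
    module = 1:6, label = sprintf("t%d", 1:6), n = 3L, N = 10L, S = 10L,
    U = 100L, p_value = 1e-3, fraction = seq(0.2, 0.7, 0.1),
    mirna_label = "unannotated", mirna_p_value = NA_real_,
    top_terms = rep(list(tibble::tibble()), 6)
  )
  lay <- layout_modules(ms)

  perm <- c(4, 2, 6, 1, 3, 5)
  ms2 <- ms
  ms2$modules <- ms$modules[perm]
  ms2$annotation <- ms$annotation[perm, ]
  ms2$annotation$module <- 1:6
  lay2 <- layout_modules(ms2)
  expect_equal(lay2$x, lay$x[perm], tolerance = 1e-9)
  expect_equal(lay2$y, lay$y[perm], tolerance = 1e-9)
  expect_equal(lay2$radius, lay$radius[perm])
})

test_that("the colour code supports palette_size^2 categories", {
  mods <- lapply(1:100, function(i) {
    fake_module(sprintf("m%d_%d", i, 1:2), sprintf("g%d_%d", i, 1:3))
  })
  ms <- fake_module_set(mods)
  ms$annotation <- tibble::tibble(
    module = 1:100, label = sprintf("term%03d", 1:100), n = 2L, N = 5L,
    S = 3L, U = 500L, p_value = 1e-3, fraction = 0.5,
    mirna_label = "unannotated", mirna_p_value = NA_real_,
    top_terms = rep(list(tibble::tibble()), 100)
  )
  lay <- layout_modules(ms, palette_size = 10)
  codes <- paste(lay$perimeter_colour, lay$area_colour)
  expect_lte(length(unique(codes)), 100)
  expect_equal(anyDuplicated(codes), 0L)  # 100 distinct terms, all unique
  expect_true(all(lay$perimeter_colour %in% 1:10))
  expect_true(all(lay$area_colour %in% 1:10))

  # more distinct terms than the palette can encode overflow into "other"
  expect_warning(layout_modules(ms, palette_size = 3), "capacity")
})

test_that("module graph export applies sign-specific thresholds", {
  m <- fake_module(c("m1", "m2"), c("g1", "g2"), c("g3"))
  m$edges$association <- c(-0.9, -0.4, -0.6, -0.3, 0.7, 0.2)
  g_all <- export_module_graph(m, 0, 0)
  expect_equal(nrow(g_all$edges), 6)

  g_half <- export_module_graph(m, 0.5, 0.5)
  expect_equal(nrow(g_half$edges), 3)  # |a| >= 0.5 survives on either arm
  expect_setequal(round(g_half$edges$weight, 1), c(0.9, 0.6, 0.7))

  g_perfect <- suppressWarnings(export_module_graph(m, 1, 0.9))
  expect_equal(nrow(g_perfect$edges), 0)  # only |a| = 1 direct edges kept
  expect_warning(export_module_graph(m, 1, 0.9), "exclude")

  tmp <- withr::local_tempdir()
  gml <- file.path(tmp, "module.graphml")
  etsv <- file.path(tmp, "edges.tsv")
  export_module_graph(m, 0, 0, graphml_file = gml, edges_file = etsv)
  expect_true(file.exists(gml))
  reread <- readr::read_tsv(etsv, show_col_types = FALSE)
  expect_equal(nrow(reread), 6)
  expect_equal(igraph::vcount(g_all$graph), 5)
})
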