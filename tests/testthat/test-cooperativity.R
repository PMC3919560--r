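make_loci <- function(mirna, chrom, start, end, host = NA_character_) {
  tibble::tibble(mirna = mirna, chrom = chrom, start = start, end = end,
                 strand = "+", host_gene = host)
}

test_that("genomic clustering follows the 10 kb / host-gene rule", {
  # 5 kb apart: one cluster
  cl <- build_genomic_clusters(make_loci(c("a", "b"), "chr1",
                                         c(1000, 6100), c(1100, 6200)))
  expect_equal(sort(unique(cl$mirna)), c("a", "b"))
  expect_equal(unique(cl$name), "a_cluster")

  # 15 kb apart, no host gene: no cluster
  cl2 <- build_genomic_clusters(make_loci(c("a", "b"), "chr1",
                                          c(1000, 16100), c(1100, 16200)))
  expect_equal(nrow(cl2), 0)

  # but a shared host gene links them regardless of distance
  cl3 <- build_genomic_clusters(make_loci(c("a", "b"), c("chr1", "chr9"),
                                          c(1000, 900000), c(1100, 900100),
                                          host = c("HOST1", "HOST1")))
  expect_equal(nrow(cl3), 2)

  # single-linkage chain A-8kb-B-8kb-C collapses to one cluster
  cl4 <- build_genomic_clusters(make_loci(c("A", "B", "C"), "chr2",
                                          c(0, 8100, 16200),
                                          c(100, 8200, 16300)))
  expect_equal(sort(unique(cl4$mirna)), c("A", "B", "C"))
  expect_equal(unique(cl4$name), "A_cluster")

  expect_error(build_genomic_clusters(make_loci("a", "chr1", 100, 50)),
               "malformed")
})

test_that("clustering matches brute-force transitive closure on random loci", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 50
    loci <- tibble::tibble(
      mirna = sprintf("mir%02d", 1:n),
      chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
      start = sample.int(2e5, n),
      host_gene = sample(c(NA, NA, NA, "H1", "H2"), n, replace = TRUE)
    )
    loci$end <- loci$start + 100L
    got <- build_genomic_clusters(loci, window = 10000)

    # oracle: adjacency + repeated boolean closure
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j])
      adj[i, j] <- (loci$chrom[i] == loci$chrom[j] && gap <= 10000) ||
        (!is.na(loci$host_gene[i]) && !is.na(loci$host_gene[j]) &&
           loci$host_gene[i] == loci$host_gene[j])
    }
    reach <- adj
    repeat {
      nxt <- reach | (reach %*% reach > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp_id <- apply(reach, 1, function(r) min(which(r)))
    oracle_groups <- split(loci$mirna, comp_id)
    oracle_groups <- Filter(function(g) length(g) >= 2, oracle_groups)
    oracle_sets <- sort(vapply(oracle_groups,
                               function(g) paste(sort(g), collapse = ","),
                               character(1)))
    got_sets <- sort(vapply(split(got$mirna, got$name),
                            function(g) paste(sort(g), collapse = ","),
                            character(1)))
    expect_identical(unname(got_sets), unname(oracle_sets))
  }
})

test_that("target-count profile takes the most inverse correlation", {
  corr <- named_matrix(c(-0.2, -0.7, 0.1,   # g001: all three target
                         0.3, 0.5, -0.4,    # g002: only first targets
                         0.2, 0.2, 0.2,     # g003: none target
                         -0.9, 0.1, 0.1),   # g004: first two target
                       3, 4, "miR", "g")
  targ <- named_matrix(c(TRUE, TRUE, TRUE,
                         TRUE, FALSE, FALSE,
                         FALSE, FALSE, FALSE,
                         TRUE, TRUE, FALSE), 3, 4, "miR", "g")
  pr <- target_count_profile(corr, targ, rownames(corr))
  expect_equal(pr$k[pr$mrna == "g001"], 3L)
  expect_equal(pr$correlation[pr$mrna == "g001"], -0.7)
  expect_equal(pr$k[pr$mrna == "g002"], 1L)
  expect_equal(pr$correlation[pr$mrna == "g002"], 0.3)  # min even if positive
  expect_false("g003" %in% pr$mrna)
  expect_equal(pr$correlation[pr$mrna == "g004"], -0.9)

  # brute-force per-cell scan agrees on the whole toy matrix
  for (g in pr$mrna) {
    hit <- targ[, g]
    expect_equal(pr$k[pr$mrna == g], sum(hit))
    expect_equal(pr$correlation[pr$mrna == g], min(corr[hit, g]))
  }

  # aggregation is order-invariant in the member list
  pr2 <- target_count_profile(corr, targ, rev(rownames(corr)))
  expect_identical(pr, pr2)

  # group with no targets: empty profile, not an error
  empty <- target_count_profile(corr, targ & FALSE, rownames(corr))
  expect_equal(nrow(empty), 0)
})

test_that("trend rho reflects the per-level medians", {
  pr <- tibble::tibble(mrna = sprintf("g%d", 1:6),
                       k = c(1L, 1L, 2L, 2L, 3L, 3L),
                       correlation = c(-0.1, -0.1, -0.2, -0.2, -0.3, -0.3))
  tr <- cooperativity_trend(pr)
  expect_equal(tr$levels, 1:3)
  expect_equal(tr$medians, c(-0.1, -0.2, -0.3))
  expect_equal(tr$rho, -1)

  # all medians tie: undefined, not zero
  flat <- pr
  flat$correlation <- -0.2
  expect_true(is.na(cooperativity_trend(flat)$rho))

  # fewer than three populated levels: undefined
  two <- pr[pr$k <= 2, ]
  expect_true(is.na(cooperativity_trend(two)$rho))
})

test_that("permutation p-value uses the add-one estimator and a fixed seed", {
  sim <- generate_dataset(n_mirnas = 60, n_mrnas = 700, n_samples = 40,
                          module_specs = list(),
                          coop_specs = list(coop_spec(5, 400)),
                          rng_seed = 104)
  corr <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
  members <- sim$truth$coop[[1]]$members
  res <- cooperativity_pvalue(corr, sim$targets, members, n_perm = 100,
                              rng_seed = 5)
  expect_s3_class(res, "cooperativity_result")
  expect_lte(res$rho, -0.8)
  expect_equal(res$p_value,
               (1 + sum(res$null_rho <= res$rho, na.rm = TRUE)) / 101)
  # most extreme case reports 1/101, the published "< 0.01"
  if (all(res$null_rho > res$rho, na.rm = TRUE)) {
    expect_equal(res$p_value, 1 / 101)
  }
  res2 <- cooperativity_pvalue(corr, sim$targets, members, n_perm = 100,
                               rng_seed = 5)
  expect_identical(res$p_value, res2$p_value)

  expect_error(cooperativity_pvalue(corr, sim$targets, members, n_perm = 0),
               "n_perm")
})

test_that("planted additive effect is recovered within 20%", {
  slopes <- vapply(1:3, function(s) {
    sim <- generate_dataset(n_mirnas = 60, n_mrnas = 700, n_samples = 40,
                            module_specs = list(),
                            coop_specs = list(coop_spec(5, 500)),
                            rng_seed = 200 + s)
    corr <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
    tr <- cooperativity_trend(
      target_count_profile(corr, sim$targets, sim$truth$coop[[1]]$members)
    )
    unname(stats::coef(stats::lm(tr$medians ~ tr$levels))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.1)), 0.02)
})

test_that("cooperativity_analysis summarises groupings above the size floor", {
  sim <- generate_dataset(n_mirnas = 60, n_mrnas = 700, n_samples = 40,
                          module_specs = list(),
                          coop_specs = list(coop_spec(5, 300)),
                          rng_seed = 300)
  corr <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
  out <- cooperativity_analysis(corr, sim$targets, sim$groupings,
                                n_perm = 50, rng_seed = 4)
  expect_equal(out$name, "coop_01")
  expect_equal(out$n, 5L)
  expect_lte(out$rho, -0.8)
  expect_s3_class(out$result[[1]], "cooperativity_result")
  expect_equal(glance(out$result[[1]])$rho, out$rho)
})
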