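# Shared builders for test fixtures; everything is generated in code.

named_matrix <- function(values, nr, nc, rp = "m", cp = "g") {
  matrix(values, nr, nc,
         dimnames = list(sprintf("%s%03d", rp, seq_len(nr)),
                         sprintf("%s%03d", cp, seq_len(nc))))
}

# small planted-module world used by several suites
small_sim <- function(n_modules = 3, rng_seed = 7, n_mirnas = 100,
                      n_mrnas = 600, noise_sd = 0.1) {
  generate_dataset(
    n_mirnas = n_mirnas, n_mrnas = n_mrnas, n_samples = 40,
    module_specs = replicate(n_modules,
                             planted_module_spec(noise_sd = noise_sd),
                             simplify = FALSE),
    rng_seed = rng_seed
  )
}

sim_assoc <- function(sim) {
  corr <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
  integrate_associations(corr, sim$targets)
}

# independent oracle: Spearman as rank-then-Pearson with average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# independent oracle: exhaustive best mean over all fixed-size submatrices
exhaustive_best_score <- function(a, sr, sc) {
  rcomb <- combn(nrow(a), sr)
  ccomb <- combn(ncol(a), sc)
  best <- Inf
  for (i in seq_len(ncol(rcomb))) {
    rows <- rcomb[, i]
    colsums <- colSums(a[rows, , drop = FALSE])
    for (j in seq_len(ncol(ccomb))) {
      s <- sum(colsums[ccomb[, j]]) / (sr * sc)
      if (s < best) best <- s
    }
  }
  best
}

# independent oracle: upper-tail hypergeometric by explicit enumeration
hyper_tail_oracle <- function(n, N, S, U) {
  ks <- seq(n, min(N, S))
  sum(choose(N, ks) * choose(U - N, S - ks)) / choose(U, S)
}

# module stub for overlap/layout tests
fake_module <- function(mirnas, direct, indirect = character(0)) {
  structure(list(
    mirnas = sort(mirnas), direct_mrnas = sort(direct),
    indirect_mrnas = sort(indirect), score = -0.5,
    seed = list(rows = mirnas, cols = direct, score = -0.5),
    edges = tibble::tibble(
      mirna = rep(sort(mirnas), times = length(direct) + length(indirect)),
      mrna = rep(c(sort(direct), sort(indirect)), each = length(mirnas)),
      association = rep(c(rep(-0.5, length(direct)), rep(0.5, length(indirect))),
                        each = length(mirnas)),
      arm = rep(c(rep("direct", length(direct)),
                  rep("indirect", length(indirect))), each = length(mirnas))
    )
  ), class = "mirna_module")
}

fake_module_set <- function(modules) {
  feats <- unique(unlist(lapply(modules, function(m) {
    c(m$mirnas, m$direct_mrnas, m$indirect_mrnas)
  })))
  structure(list(modules = modules, config = search_config(),
                 n_mirnas = length(feats), n_mrnas = length(feats)),
            class = "mirna_module_set")
}

unclass_mat <- function(x) {
  x <- unclass(x)
  attr(x, "targets") <- NULL
  x
}
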