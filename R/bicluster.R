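#' Search configuration for module discovery
#'
#' Bundles the bicluster search parameters. Defaults follow the published
#' method where it states them: at most 10 miRNAs and 250 mRNAs per module
#' (the mean numbers of predicted miRNAs per mRNA and targets per miRNA) and
#' 100 modules per run. The annealing schedule and seed dimensions are not
#' stated there and default to standard practice: geometric cooling with
#' factor 0.95, 200 moves per temperature, stop temperature 1e-3, and an
#' initial temperature calibrated so roughly 80% of early uphill moves are
#' accepted; seeds are 5 miRNAs x 20 mRNAs.
#'
#' @param seed_rows,seed_cols Fixed seed dimensions (miRNAs x mRNAs).
#' @param max_mirnas Cap on module miRNAs (the paper's column threshold, 10).
#' @param max_mrnas Cap on total module mRNAs across the direct and indirect
#'   arms (the paper's row threshold, 250).
#' @param n_modules Number of search rounds / modules returned.
#' @param n_restarts Independent SA restarts per round; the best seed is kept.
#' @param t0 Initial temperature on the mean-score scale, or `NULL` for the
#'   adaptive 80%-acceptance calibration.
#' @param cooling Geometric cooling factor in (0, 1).
#' @param moves_per_temp Proposed moves per temperature step.
#' @param t_stop Stop temperature.
#' @param mask_policy `"seed-exclusion"` (cells of previous seeds are treated
#'   as +1, the worst value, in later seed searches) or `"value-damping"`
#'   (cells of previous seeds are halved).
#' @param admission_margin Minimum |mean association| a candidate row/column
#'   must reach to be admitted during expansion; 0 (default) admits any
#'   candidate with the correct sign.
#' @param rng_seed Integer seed governing the whole search, or `NULL` to use
#'   the current RNG state.
#' @return A list of class `"search_config"`.
#' @export
search_config <- function(seed_rows = 5L, seed_cols = 20L,
                          max_mirnas = 10L, max_mrnas = 250L,
                          n_modules = 100L, n_restarts = 1L,
                          t0 = NULL, cooling = 0.95, moves_per_temp = 200L,
                          t_stop = 1e-3, mask_policy = c("seed-exclusion",
                                                         "value-damping"),
                          admission_margin = 0, rng_seed = NULL) {
  mask_policy <- match.arg(mask_policy)
  stopifnot(
    seed_rows >= 1, seed_cols >= 1, max_mirnas >= seed_rows,
    max_mrnas >= seed_cols, n_modules >= 0, n_restarts >= 1,
    cooling > 0, cooling < 1, moves_per_temp >= 1, t_stop > 0,
    admission_margin >= 0
  )
  structure(list(
    seed_rows = as.integer(seed_rows), seed_cols = as.integer(seed_cols),
    max_mirnas = as.integer(max_mirnas), max_mrnas = as.integer(max_mrnas),
    n_modules = as.integer(n_modules), n_restarts = as.integer(n_restarts),
    t0 = t0, cooling = cooling, moves_per_temp = as.integer(moves_per_temp),
    t_stop = t_stop, mask_policy = mask_policy,
    admission_margin = admission_margin, rng_seed = rng_seed
  ), class = "search_config")
}

#' Mean-association score of a submatrix
#'
#' The objective the seed search minimizes: the arithmetic mean of the
#' association values over the selected miRNA rows and mRNA columns. An ideal
#' direct module (all cells -1) scores -1; an empty region scores 0.
#'
#' @param assoc Association (or correlation) matrix, miRNAs x mRNAs.
#' @param rows,cols Row/column selectors (ids or indices), both non-empty.
#' @return A single number in `[-1, 1]`.
#' @export
score_submatrix <- function(assoc, rows, cols) {
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("submatrix row and column sets must be non-empty", call. = FALSE)
  }
  mean(assoc[rows, cols, drop = FALSE])
}

#' Simulated-annealing seed search
#'
#' Finds a fixed-size submatrix with (near-)minimal mean association by
#' simulated annealing: single row/column replacement moves accepted by the
#' Metropolis criterion under a geometrically cooled temperature. With
#' `cfg$n_restarts > 1` the best of several independent runs is returned.
#'
#' @param assoc Association matrix (miRNAs x mRNAs) with dimnames.
#' @param cfg A [search_config()].
#' @return A list with `rows` (miRNA ids), `cols` (mRNA ids) and `score`.
#' @export
sa_seed_search <- function(assoc, cfg = search_config()) {
  if (nrow(assoc) < cfg$seed_rows || ncol(assoc) < cfg$seed_cols) {
    stop(sprintf("matrix (%d x %d) smaller than seed (%d x %d)",
                 nrow(assoc), ncol(assoc), cfg$seed_rows, cfg$seed_cols),
         call. = FALSE)
  }
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  t0 <- cfg$t0 %||% calibrate_t0(assoc, cfg)
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    res <- sa_seed_search_cpp(assoc, cfg$seed_rows, cfg$seed_cols,
                              t0, cfg$cooling, cfg$moves_per_temp, cfg$t_stop)
    if (is.null(best) || res$score < best$score) best <- res
  }
  list(rows = rownames(assoc)[sort(best$rows)],
       cols = colnames(assoc)[sort(best$cols)],
       score = best$score)
}

# Initial temperature such that ~80% of sampled uphill moves are accepted:
# T0 = mean(uphill delta) / -log(0.8), on the mean-score scale.
calibrate_t0 <- function(assoc, cfg, n_probe = 200L) {
  area <- cfg$seed_rows * cfg$seed_cols
  deltas <- replicate(n_probe, {
    rs <- sample.int(nrow(assoc), cfg$seed_rows)
    cs <- sample.int(ncol(assoc), cfg$seed_cols)
    s0 <- sum(assoc[rs, cs])
    if (runif(1) < 0.5 && nrow(assoc) > cfg$seed_rows) {
      cand <- sample(setdiff(seq_len(nrow(assoc)), rs), 1L)
      (sum(assoc[cand, cs]) - sum(assoc[rs[1L], cs])) / area
    } else if (ncol(assoc) > cfg$seed_cols) {
      cand <- sample(setdiff(seq_len(ncol(assoc)), cs), 1L)
      (sum(assoc[rs, cand]) - sum(assoc[rs, cs[1L]])) / area
    } else 0
  })
  up <- deltas[deltas > 0]
  if (length(up) == 0L) return(0.1)
  mean(up) / -log(0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic expansion of a seed into a full module
#'
#' Grows a seed submatrix into a module: miRNAs with the most negative mean
#' association to the seed's direct mRNAs are added up to `cfg$max_mirnas`;
#' then mRNA columns are admitted best-first from either arm — direct
#' candidates by most negative mean association to the module miRNAs,
#' indirect candidates by most positive — until the combined arms reach
#' `cfg$max_mrnas`. Candidates whose mean association has the wrong sign (or
#' falls below `cfg$admission_margin` in magnitude) are never added. Ties
#' break lexicographically by feature id, so expansion is deterministic.
#'
#' @param assoc Association matrix (miRNAs x mRNAs) with dimnames.
#' @param seed A list with `rows` and `cols` (ids), e.g. from
#'   [sa_seed_search()].
#' @param cfg A [search_config()].
#' @return A list of class `"mirna_module"` with elements `mirnas`,
#'   `direct_mrnas`, `indirect_mrnas`, `score` (mean association of the
#'   direct arm), `seed` and `edges` (a tibble of per-pair values).
#' @export
expand_seed <- function(assoc, seed, cfg = search_config()) {
  stopifnot(all(seed$rows %in% rownames(assoc)),
            all(seed$cols %in% colnames(assoc)))
  mirnas <- sort(seed$rows)
  direct <- sort(seed$cols)
  margin <- cfg$admission_margin

  # miRNA rows: most negative mean association to the current direct arm
  while (length(mirnas) < cfg$max_mirnas) {
    cand <- setdiff(rownames(assoc), mirnas)
    if (length(cand) == 0L) break
    mu <- rowMeans(assoc[cand, direct, drop = FALSE])
    ord <- order(mu, cand)
    if (mu[ord[1L]] >= 0 || -mu[ord[1L]] < margin) break
    mirnas <- sort(c(mirnas, cand[ord[1L]]))
  }

  # mRNA columns: interleaved best-first admission into either arm
  indirect <- character(0)
  mu_all <- colMeans(assoc[mirnas, , drop = FALSE])
  while (length(direct) + length(indirect) < cfg$max_mrnas) {
    cand <- setdiff(colnames(assoc), c(direct, indirect))
    if (length(cand) == 0L) break
    mu <- mu_all[cand]
    ok <- abs(mu) > 0 & abs(mu) >= margin
    if (!any(ok)) break
    ord <- order(-abs(mu), names(mu))
    pick <- ord[ok[ord]][1L]
    if (mu[pick] < 0) direct <- sort(c(direct, names(mu)[pick]))
    else indirect <- sort(c(indirect, names(mu)[pick]))
  }

  new_module(assoc, mirnas, direct, indirect, seed)
}

new_module <- function(assoc, mirnas, direct, indirect, seed) {
  all_mrnas <- c(direct, indirect)
  edges <- tibble::tibble(
    mirna = rep(mirnas, times = length(all_mrnas)),
    mrna = rep(all_mrnas, each = length(mirnas)),
    association = as.vector(assoc[mirnas, all_mrnas, drop = FALSE]),
    arm = rep(c(rep("direct", length(direct)),
                rep("indirect", length(indirect))), each = length(mirnas))
  )
  structure(list(
    mirnas = mirnas,
    direct_mrnas = direct,
    indirect_mrnas = indirect,
    score = score_submatrix(assoc, mirnas, direct),
    seed = seed,
    edges = edges
  ), class = "mirna_module")
}

#' @export
print.mirna_module <- function(x, ...) {
  cat(sprintf(
    "<mirna_module> %d miRNAs, %d direct + %d indirect mRNAs, score %.3f\n",
    length(x$mirnas), length(x$direct_mrnas), length(x$indirect_mrnas),
    x$score
  ))
  invisible(x)
}

#' Discover miRNA-mRNA functional modules
#'
#' Runs `cfg$n_modules` independent rounds of simulated-annealing seed search
#' plus deterministic expansion on the association matrix. Between rounds the
#' mask policy steers later searches away from already-returned seeds, so
#' successive rounds explore new structure while expanded modules may still
#' overlap. Modules are returned ordered by ascending score (best first).
#'
#' @param assoc Association matrix from [integrate_associations()] (any
#'   numeric miRNA x mRNA matrix with dimnames works).
#' @param cfg A [search_config()].
#' @return An object of class `"mirna_module_set"`: a list with `modules`
#'   (list of `"mirna_module"`), `config`, and the matrix dimensions. Use
#'   [tidy()] for a long membership tibble and [glance()] for one row per
#'   module.
#' @export
discover_modules <- function(assoc, cfg = search_config()) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  search_mat <- unclass(assoc)
  attr(search_mat, "targets") <- NULL
  seed_area <- cfg$seed_rows * cfg$seed_cols
  modules <- vector("list", cfg$n_modules)
  n_found <- 0L
  round_cfg <- cfg
  round_cfg$rng_seed <- NULL  # one seeding for the whole run
  for (k in seq_len(cfg$n_modules)) {
    unmasked <- sum(search_mat < 1)
    if (length(search_mat) - seed_area < 0 || unmasked < seed_area) {
      warning(sprintf("stopping after %d of %d rounds: no admissible seeds left",
                      n_found, cfg$n_modules), call. = FALSE)
      break
    }
    seed <- sa_seed_search(search_mat, round_cfg)
    mod <- expand_seed(unclass(assoc), seed, cfg)
    n_found <- n_found + 1L
    modules[[n_found]] <- mod
    cells <- cbind(match(seed$rows, rownames(search_mat)),
                   rep(match(seed$cols, colnames(search_mat)),
                       each = length(seed$rows)))
    if (cfg$mask_policy == "seed-exclusion") {
      search_mat[cells] <- 1
    } else {
      search_mat[cells] <- search_mat[cells] * 0.5
    }
  }
  modules <- modules[seq_len(n_found)]
  ord <- order(vapply(modules, `[[`, numeric(1), "score"),
               vapply(modules, function(m) paste(m$mirnas, collapse = ","),
                      character(1)))
  structure(list(
    modules = modules[ord],
    config = cfg,
    n_mirnas = nrow(assoc),
    n_mrnas = ncol(assoc)
  ), class = "mirna_module_set")
}

#' @export
print.mirna_module_set <- function(x, ...) {
  cat(sprintf("<mirna_module_set> %d modules over %d miRNAs x %d mRNAs\n",
              length(x$modules), x$n_mirnas, x$n_mrnas))
  if (length(x$modules) > 0L) {
    sc <- vapply(x$modules, `[[`, numeric(1), "score")
    cat(sprintf("  scores: best %.3f, median %.3f, worst %.3f\n",
                min(sc), median(sc), max(sc)))
  }
  invisible(x)
}

#' Tidy a module set into a long membership tibble
#'
#' @param x A `"mirna_module_set"` from [discover_modules()].
#' @param ... Unused.
#' @return A tibble with columns `module`, `side` (`"mirna"`/`"mrna"`), `arm`
#'   (`"mirna"`, `"direct"` or `"indirect"`), `feature` and `mean_association`
#'   (the feature's mean association against the opposite side's direct arm
#'   or miRNA set).
#' @method tidy mirna_module_set
#' @export
tidy.mirna_module_set <- function(x, ...) {
  purrr::imap_dfr(x$modules, function(m, i) {
    mirna_mu <- vapply(m$mirnas, function(id) {
      mean(m$edges$association[m$edges$mirna == id & m$edges$arm == "direct"])
    }, numeric(1))
    mrna_mu <- vapply(c(m$direct_mrnas, m$indirect_mrnas), function(id) {
      mean(m$edges$association[m$edges$mrna == id])
    }, numeric(1))
    tibble::tibble(
      module = i,
      side = c(rep("mirna", length(m$mirnas)),
               rep("mrna", length(mrna_mu))),
      arm = c(rep("mirna", length(m$mirnas)),
              rep("direct", length(m$direct_mrnas)),
              rep("indirect", length(m$indirect_mrnas))),
      feature = c(m$mirnas, m$direct_mrnas, m$indirect_mrnas),
      mean_association = c(mirna_mu, mrna_mu)
    )
  })
}

#' One-row-per-module summary of a module set
#'
#' @param x A `"mirna_module_set"`.
#' @param ... Unused.
#' @return A tibble with module index, arm sizes and score.
#' @method glance mirna_module_set
#' @export
glance.mirna_module_set <- function(x, ...) {
  tibble::tibble(
    module = seq_along(x$modules),
    n_mirnas = vapply(x$modules, function(m) length(m$mirnas), integer(1)),
    n_direct = vapply(x$modules, function(m) length(m$direct_mrnas), integer(1)),
    n_indirect = vapply(x$modules, function(m) length(m$indirect_mrnas), integer(1)),
    score = vapply(x$modules, `[[`, numeric(1), "score")
  )
}
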