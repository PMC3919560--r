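#' Group miRNAs into genomic clusters
#'
#' Single-linkage clustering of miRNA loci: two miRNAs are linked when they
#' lie on the same chromosome with at most `window` bp between their intervals
#' or when they share a host gene. Connected components of size >= 2 become
#' clusters, named after the lexicographically first member.
#'
#' @param loci A data frame of miRNA loci with columns `mirna`, `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `host_gene` (`NA` for
#'   intergenic miRNAs), e.g. from [read_bed_loci()].
#' @param window Maximum gap in bp between intervals, default 10000 (10 kb).
#' @return A tibble with columns `name`, `kind` (`"genomic_cluster"`),
#'   `mirna`; one row per cluster member.
#' @export
build_genomic_clusters <- function(loci, window = 10000) {
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("mirna", "chrom", "start", "end") %in% names(loci)))
  if (anyDuplicated(loci$mirna)) {
    stop("duplicated miRNA ids in `loci`", call. = FALSE)
  }
  if (any(loci$start >= loci$end)) {
    stop("malformed interval: start must be < end", call. = FALSE)
  }
  if (!"host_gene" %in% names(loci)) loci$host_gene <- NA_character_
  n <- nrow(loci)
  if (n < 2L) return(empty_grouping_tbl())
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  gap <- pmax(loci$start[i], loci$start[j]) - pmin(loci$end[i], loci$end[j])
  near <- loci$chrom[i] == loci$chrom[j] & gap <= window
  shared_host <- !is.na(loci$host_gene[i]) & !is.na(loci$host_gene[j]) &
    loci$host_gene[i] == loci$host_gene[j]
  keep <- near | shared_host
  g <- igraph::graph_from_data_frame(
    data.frame(from = loci$mirna[i[keep]], to = loci$mirna[j[keep]]),
    directed = FALSE, vertices = loci$mirna
  )
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- Filter(function(m) length(m) >= 2L, members)
  if (length(members) == 0L) return(empty_grouping_tbl())
  purrr::map_dfr(members, function(m) {
    m <- sort(m)
    tibble::tibble(name = paste0(m[1L], "_cluster"), kind = "genomic_cluster",
                   mirna = m)
  }) |>
    dplyr::arrange(.data$name, .data$mirna)
}

empty_grouping_tbl <- function() {
  tibble::tibble(name = character(), kind = character(), mirna = character())
}

#' Per-mRNA target-count profile for a miRNA grouping
#'
#' For every mRNA predicted to be targeted by at least one member of the
#' grouping, reports the number of targeting members `k` and the maximum
#' inverse correlation over those members, read as the minimum signed
#' correlation (most negative), even when all candidates are positive.
#'
#' @param corr Correlation matrix (miRNAs x mRNAs). By convention the raw
#'   Spearman matrix restricted to predicted-target pairs; pass the
#'   association matrix to analyse the conflict-filtered values instead.
#' @param targets Target matrix/pair list accepted by
#'   [integrate_associations()].
#' @param members Character vector of grouping member miRNA ids; members
#'   absent from `corr` are dropped.
#' @return A tibble with columns `mrna`, `k` and `correlation`; zero rows when
#'   no member targets anything.
#' @export
target_count_profile <- function(corr, targets, members) {
  tmat <- as_target_matrix(targets, rownames(corr), colnames(corr))
  pr <- profile_fast(corr, tmat, intersect(members, rownames(corr)))
  tibble::tibble(mrna = pr$mrna, k = pr$k, correlation = pr$correlation) |>
    dplyr::arrange(.data$mrna)
}

# Vectorized core shared by the tibble API and the permutation loop, where
# tibble/dplyr overhead would dominate (100+ calls per grouping).
profile_fast <- function(corr, tmat, members) {
  if (length(members) == 0L) {
    return(list(mrna = character(), k = integer(), correlation = double()))
  }
  res <- profile_kmin_cpp(corr, tmat, match(members, rownames(corr)))
  keep <- res$k >= 1L & is.finite(res$min)
  list(mrna = colnames(corr)[keep], k = res$k[keep],
       correlation = res$min[keep])
}

trend_rho_fast <- function(k, correlation) {
  if (length(k) == 0L) return(NA_real_)
  med <- vapply(split(correlation, k), median, numeric(1))
  if (length(med) < 3L) return(NA_real_)
  suppressWarnings(cor(as.numeric(names(med)), med, method = "spearman"))
}

#' Cooperativity trend over target-count levels
#'
#' Summarizes a target-count profile into per-level medians and their
#' Spearman rank correlation with the level: a strongly negative trend rho
#' means repression deepens as more members of the grouping target an mRNA,
#' the signature of cooperativity.
#'
#' @param profile Tibble from [target_count_profile()].
#' @return A list with `levels` (populated target counts), `medians` (median
#'   correlation per level) and `rho` (Spearman correlation of medians vs
#'   level; `NA` when fewer than 3 populated levels or all medians tie).
#' @export
cooperativity_trend <- function(profile) {
  if (nrow(profile) == 0L) {
    return(list(levels = integer(), medians = double(), rho = NA_real_))
  }
  med <- vapply(split(profile$correlation, profile$k), median, numeric(1))
  lev <- as.integer(names(med))
  list(levels = lev, medians = unname(med),
       rho = trend_rho_fast(profile$k, profile$correlation))
}

#' Cooperativity significance by permutation
#'
#' Compares the observed trend rho of a miRNA grouping against `n_perm`
#' random groupings of the same size drawn uniformly (without replacement,
#' per grouping) from all miRNAs in the matrix. The empirical p-value uses
#' the add-one estimator `(1 + #{null rho <= observed}) / (1 + n_perm)`, so
#' an observation more extreme than every null draw at the default 100
#' permutations reports p = 1/101 (printed "< 0.01" in the published style).
#'
#' @inheritParams target_count_profile
#' @param name Grouping name carried into the result.
#' @param kind Grouping kind (`"family"` or `"genomic_cluster"`).
#' @param n_perm Number of random groupings, default 100.
#' @param exclude_members If `TRUE` (default), null groupings are drawn from
#'   the non-member miRNAs, so the null is not contaminated by the very
#'   grouping under test; members of other groupings stay in the pool.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return A list of class `"cooperativity_result"` with the grouping, the
#'   observed `levels`/`medians`/`rho`, `p_value` (`NA` when rho is
#'   undefined), `n_permutations` and the null rho draws.
#' @export
cooperativity_pvalue <- function(corr, targets, members, name = "group",
                                 kind = "family", n_perm = 100L,
                                 exclude_members = TRUE, rng_seed = NULL) {
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  members <- intersect(members, rownames(corr))
  n <- length(members)
  pool <- if (exclude_members) setdiff(rownames(corr), members)
          else rownames(corr)
  if (length(pool) < n) {
    stop("not enough miRNAs in the matrix to sample null groupings",
         call. = FALSE)
  }
  tmat <- as_target_matrix(targets, rownames(corr), colnames(corr))
  obs <- cooperativity_trend(target_count_profile(corr, tmat, members))
  null_rho <- vapply(seq_len(n_perm), function(b) {
    draw <- sample(pool, n)
    pr <- profile_fast(corr, tmat, draw)
    trend_rho_fast(pr$k, pr$correlation)
  }, numeric(1))
  p <- if (is.na(obs$rho)) {
    NA_real_
  } else {
    (1 + sum(null_rho <= obs$rho, na.rm = TRUE)) / (1 + n_perm)
  }
  structure(list(
    name = name, kind = kind, members = sort(members), n = n,
    levels = obs$levels, medians = obs$medians, rho = obs$rho,
    p_value = p, n_permutations = as.integer(n_perm), null_rho = null_rho
  ), class = "cooperativity_result")
}

#' @export
print.cooperativity_result <- function(x, ...) {
  cat(sprintf("<cooperativity_result> %s (%s, n = %d): rho = %s, P %s\n",
              x$name, x$kind, x$n,
              ifelse(is.na(x$rho), "undefined", sprintf("%.2f", x$rho)),
              format_pvalue(x$p_value, x$n_permutations)))
  invisible(x)
}

format_pvalue <- function(p, n_perm) {
  if (is.na(p)) return("undefined")
  if (p <= 1 / (1 + n_perm) + 1e-12) return(sprintf("< %.2g", 1 / n_perm))
  sprintf("= %.2g", p)
}

#' @method tidy cooperativity_result
#' @export
tidy.cooperativity_result <- function(x, ...) {
  tibble::tibble(k = x$levels, median_correlation = x$medians)
}

#' @method glance cooperativity_result
#' @export
glance.cooperativity_result <- function(x, ...) {
  tibble::tibble(name = x$name, kind = x$kind, n = x$n, rho = x$rho,
                 p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Cooperativity analysis over many groupings
#'
#' Convenience wrapper running [cooperativity_pvalue()] for each grouping in
#' a long table (as produced by [build_genomic_clusters()] or
#' [read_family_tsv()]), keeping groupings with at least `min_size` members
#' present in the matrix.
#'
#' @inheritParams target_count_profile
#' @param groupings Tibble with columns `name`, `kind`, `mirna`.
#' @param min_size Minimum member count after intersection; the published
#'   analysis reports groupings with n > 2, i.e. `min_size = 3`.
#' @param n_perm,rng_seed Passed to [cooperativity_pvalue()].
#' @return A tibble with one row per grouping: `name`, `kind`, `n`, `rho`,
#'   `p_value`; the full `"cooperativity_result"` objects in a list column
#'   `result`.
#' @export
cooperativity_analysis <- function(corr, targets, groupings, min_size = 3L,
                                   n_perm = 100L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tmat <- as_target_matrix(targets, rownames(corr), colnames(corr))
  groups <- split(groupings$mirna, groupings$name)
  kinds <- vapply(split(groupings$kind, groupings$name), `[[`, character(1), 1L)
  res <- purrr::imap(groups, function(members, nm) {
    members <- intersect(members, rownames(corr))
    if (length(members) < min_size) return(NULL)
    cooperativity_pvalue(corr, tmat, members, name = nm, kind = kinds[[nm]],
                         n_perm = n_perm)
  })
  res <- purrr::compact(res)
  out <- purrr::map_dfr(res, glance)
  out$result <- unname(res)
  out
}
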