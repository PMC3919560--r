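#' Hypergeometric over-representation of annotation terms
#'
#' For each term, computes the upper-tail hypergeometric probability of
#' drawing at least the observed number of term members in a sample of the
#' given size from the universe: `P(X >= n)` with `X ~
#' Hypergeometric(U, N, S)` where `U` is the universe size, `N` the term size
#' and `S` the sample size.
#'
#' @param sample Character vector of member ids (e.g. a module's mRNAs). Ids
#'   outside the universe are dropped (a message reports how many).
#' @param annotation A long tibble with columns `term` and `member`, e.g. from
#'   [read_annotation_tsv()].
#' @param universe Character vector of universe ids; defaults to all annotated
#'   members. For module annotation, pass all mRNAs of the association matrix.
#' @param adjust If `TRUE`, adds a Benjamini-Hochberg adjusted column
#'   `p_adjusted`; raw p-values are always reported.
#' @return A tibble with columns `term`, `n` (overlap), `N` (term size), `S`
#'   (sample size after intersection), `U` (universe size) and `p_value`,
#'   sorted by ascending p then term id. Zero rows when the sample is empty
#'   after intersection.
#' @export
hypergeom_enrich <- function(sample, annotation, universe = NULL,
                             adjust = FALSE) {
  stopifnot(all(c("term", "member") %in% names(annotation)))
  universe <- unique(universe %||% annotation$member)
  annotation <- annotation[annotation$member %in% universe, , drop = FALSE]
  sample <- unique(sample)
  dropped <- sum(!sample %in% universe)
  if (dropped > 0L) {
    message(sprintf("%d sample id(s) outside the universe dropped", dropped))
  }
  sample <- intersect(sample, universe)
  s <- length(sample)
  u <- length(universe)
  if (s == 0L || nrow(annotation) == 0L) {
    return(tibble::tibble(term = character(), n = integer(), N = integer(),
                          S = integer(), U = integer(), p_value = double()))
  }
  terms <- split(annotation$member, annotation$term)
  out <- purrr::imap_dfr(terms, function(members, term) {
    members <- unique(members)
    nn <- length(intersect(sample, members))
    tibble::tibble(
      term = term, n = nn, N = length(members), S = s, U = u,
      p_value = phyper(nn - 1L, length(members), u - length(members), s,
                       lower.tail = FALSE)
    )
  }) |>
    dplyr::arrange(.data$p_value, .data$term)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Annotate modules with enriched categories and miRNA classes
#'
#' Labels each module with its most significantly enriched gene category
#' (over the combined direct + indirect mRNA arms) and its most
#' over-represented miRNA family/cluster, mirroring the published module
#' tables: the enriched fraction `n/S` later drives bubble size in the
#' module map.
#'
#' @param module_set A `"mirna_module_set"` from [discover_modules()].
#' @param gene_annotation Long tibble (`term`, `member`) of mRNA categories.
#' @param mirna_annotation Optional long tibble (`term`, `member`) of miRNA
#'   families/clusters; [read_family_tsv()] and [build_genomic_clusters()]
#'   output can be converted with `name` -> `term`, `mirna` -> `member`.
#' @param gene_universe,mirna_universe Universe id vectors; default to all
#'   mRNAs / miRNAs of the matrix the modules were discovered in when that
#'   information is present, otherwise to the annotated members.
#' @param top_n Number of top terms retained per module (default 10, as in
#'   the published software).
#' @return The module set with an added `annotation` tibble: one row per
#'   module with `label` (top term or `"unannotated"`), `n`, `N`, `S`,
#'   `p_value`, `fraction` (`n/S`), `mirna_label`, `mirna_p_value`, and a
#'   list column `top_terms` holding each module's top-`top_n` enrichment.
#' @export
label_modules <- function(module_set, gene_annotation,
                          mirna_annotation = NULL, gene_universe = NULL,
                          mirna_universe = NULL, top_n = 10L) {
  stopifnot(inherits(module_set, "mirna_module_set"))
  rows <- purrr::imap_dfr(module_set$modules, function(m, i) {
    mrnas <- c(m$direct_mrnas, m$indirect_mrnas)
    enr <- suppressMessages(
      hypergeom_enrich(mrnas, gene_annotation, universe = gene_universe)
    )
    top <- head(enr, top_n)
    row <- if (nrow(enr) == 0L || all(enr$n == 0L)) {
      tibble::tibble(module = i, label = "unannotated", n = NA_integer_,
                     N = NA_integer_, S = length(mrnas), U = NA_integer_,
                     p_value = NA_real_, fraction = NA_real_)
    } else {
      best <- enr[enr$n > 0L, ][1L, ]
      tibble::tibble(module = i, label = best$term, n = best$n, N = best$N,
                     S = best$S, U = best$U, p_value = best$p_value,
                     fraction = best$n / best$S)
    }
    if (!is.null(mirna_annotation) && nrow(mirna_annotation) > 0L) {
      menr <- suppressMessages(
        hypergeom_enrich(m$mirnas, mirna_annotation,
                         universe = mirna_universe)
      )
      menr <- menr[menr$n > 0L, , drop = FALSE]
      row$mirna_label <- if (nrow(menr) > 0L) menr$term[1L] else "unannotated"
      row$mirna_p_value <- if (nrow(menr) > 0L) menr$p_value[1L] else NA_real_
    } else {
      row$mirna_label <- "unannotated"
      row$mirna_p_value <- NA_real_
    }
    row$top_terms <- list(top)
    row
  })
  module_set$annotation <- rows
  module_set
}

#' Permuted-label significance baseline
#'
#' Estimates how enriched a module set would look by chance: the discovery run
#' is repeated after permuting the association matrix's labels, and the
#' top-term p-values of the real and permuted runs are compared with a
#' Mann-Whitney (Wilcoxon rank-sum) test on the -log10 scale.
#'
#' With `mode = "labels"` (default) the miRNA and mRNA labels of the matrix
#' are permuted. This leaves the matrix values and hence the discovered
#' bicluster structure and scores unchanged (relabeling is an isomorphism)
#' but scrambles the correspondence to the annotation, which is exactly the
#' null the enrichment comparison needs. `mode = "cells"` instead shuffles
#' entries independently within each row, destroying the column structure
#' itself; use it to compare module scores against chance.
#'
#' @param assoc Association matrix.
#' @param cfg A [search_config()]; the permuted run uses the identical config.
#' @param gene_annotation Long tibble (`term`, `member`).
#' @param mode `"labels"` or `"cells"` (see above).
#' @param real A pre-computed, labeled real run (a `"mirna_module_set"` with
#'   `annotation`) to avoid recomputation; when `NULL` it is run here.
#' @param rng_seed Optional seed for the permutation and the permuted run.
#' @return A list of class `"permuted_baseline"`: `real_p`, `permuted_p`
#'   (top-term p-value vectors), `test` (the `htest`), `p_value`, the
#'   permuted `"mirna_module_set"`, and both runs' module scores.
#' @export
permuted_baseline <- function(assoc, cfg, gene_annotation,
                              mode = c("labels", "cells"), real = NULL,
                              rng_seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(real)) {
    real <- label_modules(discover_modules(assoc, cfg), gene_annotation,
                          gene_universe = colnames(assoc))
  }
  perm <- unclass(assoc)
  attr(perm, "targets") <- NULL
  if (mode == "labels") {
    rownames(perm) <- base::sample(rownames(perm))
    colnames(perm) <- base::sample(colnames(perm))
  } else {
    for (i in seq_len(nrow(perm))) perm[i, ] <- base::sample(perm[i, ])
  }
  perm_cfg <- cfg
  perm_cfg$rng_seed <- NULL  # permutation RNG stream continues
  perm_run <- label_modules(discover_modules(perm, perm_cfg), gene_annotation,
                            gene_universe = colnames(perm))
  real_p <- real$annotation$p_value
  perm_p <- perm_run$annotation$p_value
  test <- if (sum(!is.na(real_p)) > 0L && sum(!is.na(perm_p)) > 0L) {
    suppressWarnings(
      wilcox.test(-log10(real_p), -log10(perm_p), alternative = "greater")
    )
  } else NULL
  structure(list(
    real_p = real_p, permuted_p = perm_p, test = test,
    p_value = if (is.null(test)) NA_real_ else test$p.value,
    real = real, permuted = perm_run,
    real_scores = vapply(real$modules, `[[`, numeric(1), "score"),
    permuted_scores = vapply(perm_run$modules, `[[`, numeric(1), "score"),
    mode = mode
  ), class = "permuted_baseline")
}

#' @export
print.permuted_baseline <- function(x, ...) {
  cat(sprintf(
    "<permuted_baseline> mode '%s': %d real vs %d permuted modules, location-test P = %.3g\n",
    x$mode, length(x$real_p), length(x$permuted_p), x$p_value
  ))
  invisible(x)
}

#' Density of validated miRNA-mRNA pairs within modules
#'
#' Counts experimentally validated pairs falling inside modules (miRNA in the
#' module, mRNA in either arm) and reports their density over the distinct
#' (miRNA, mRNA) cells covered by any module, plus the fold change against a
#' baseline module set (typically a permuted run).
#'
#' @param module_set A `"mirna_module_set"`.
#' @param pairs A data frame with columns `mirna` and `mrna` of validated
#'   pairs (duplicates are ignored), e.g. from [read_validated_pairs()].
#' @param baseline Optional baseline `"mirna_module_set"` for the fold change.
#' @return A one-row tibble: `n_modules`, `modules_with_pair`, `mean_mirnas`,
#'   `mean_mrnas`, `n_pairs_inside`, `cells_covered`, `density`, and
#'   `baseline_density`/`fold` when a baseline is given.
#' @export
validated_pair_density <- function(module_set, pairs, baseline = NULL) {
  stopifnot(inherits(module_set, "mirna_module_set"))
  if (length(module_set$modules) == 0L) {
    stop("module set is empty", call. = FALSE)
  }
  pairs <- unique(tibble::tibble(mirna = as.character(pairs$mirna),
                                 mrna = as.character(pairs$mrna)))
  stats <- density_stats(module_set, pairs)
  out <- tibble::tibble(
    n_modules = length(module_set$modules),
    modules_with_pair = stats$modules_with_pair,
    mean_mirnas = mean(vapply(module_set$modules,
                              function(m) length(m$mirnas), integer(1))),
    mean_mrnas = mean(vapply(module_set$modules, function(m) {
      length(m$direct_mrnas) + length(m$indirect_mrnas)
    }, integer(1))),
    n_pairs_inside = stats$n_inside,
    cells_covered = stats$cells,
    density = stats$density
  )
  if (!is.null(baseline)) {
    bs <- density_stats(baseline, pairs)
    out$baseline_density <- bs$density
    out$fold <- if (bs$density > 0) {
      stats$density / bs$density
    } else if (stats$density > 0) Inf else NA_real_
  }
  out
}

density_stats <- function(module_set, pairs) {
  cell_keys <- unique(unlist(lapply(module_set$modules, function(m) {
    mrnas <- c(m$direct_mrnas, m$indirect_mrnas)
    as.vector(outer(m$mirnas, mrnas, paste, sep = "\r"))
  })))
  pair_keys <- paste(pairs$mirna, pairs$mrna, sep = "\r")
  inside <- pair_keys %in% cell_keys
  with_pair <- sum(vapply(module_set$modules, function(m) {
    keys <- as.vector(outer(m$mirnas, c(m$direct_mrnas, m$indirect_mrnas),
                            paste, sep = "\r"))
    any(pair_keys %in% keys)
  }, logical(1)))
  list(
    n_inside = sum(inside),
    cells = length(cell_keys),
    density = if (length(cell_keys) > 0) sum(inside) / length(cell_keys) else 0,
    modules_with_pair = with_pair
  )
}
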