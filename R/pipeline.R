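#' Run the full module-discovery pipeline
#'
#' Executes the end-to-end workflow on in-memory inputs: Spearman correlation,
#' target integration, bicluster discovery, enrichment labelling, overlap/MDS
#' layout, and optionally cooperativity analysis, the permuted-label baseline
#' and the validated-pair density evaluation. All stage outputs plus a run
#' manifest are written under `out_dir`.
#'
#' @param mirna_expr,mrna_expr Expression matrices (features x samples).
#' @param targets Target matrix or pair tibble.
#' @param gene_annotation Long tibble (`term`, `member`).
#' @param out_dir Output directory.
#' @param cfg A [search_config()]; its `rng_seed` (or `rng_seed` below)
#'   governs the whole run.
#' @param mirna_groupings Optional tibble (`name`, `kind`, `mirna`) for
#'   cooperativity analysis and miRNA-class labelling.
#' @param validated_pairs Optional tibble (`mirna`, `mrna`).
#' @param run_baseline If `TRUE`, also runs the permuted-label baseline (and
#'   uses it for the density fold).
#' @param n_perm Cooperativity permutations (default 100).
#' @param rng_seed Seed applied to the whole run; overrides `cfg$rng_seed`.
#' @return A list of class `"mirna_pipeline_run"` with every stage result and
#'   the output paths.
#' @export
run_pipeline <- function(mirna_expr, mrna_expr, targets, gene_annotation,
                         out_dir, cfg = search_config(),
                         mirna_groupings = NULL, validated_pairs = NULL,
                         run_baseline = FALSE, n_perm = 100L,
                         rng_seed = NULL) {
  if (!is.null(rng_seed)) cfg$rng_seed <- rng_seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  corr <- stage("correlation", compute_correlations(mirna_expr, mrna_expr))
  assoc <- stage("integration", integrate_associations(corr, targets))
  write_matrix_tsv(unclass_assoc(assoc), file.path(out_dir, "association_matrix.tsv"),
                   "mirna")
  readr::write_tsv(tidy(assoc), file.path(out_dir, "association_triplets.tsv"))

  modules <- stage("bicluster", discover_modules(assoc, cfg))
  mirna_annot <- if (!is.null(mirna_groupings) && nrow(mirna_groupings) > 0) {
    tibble::tibble(term = mirna_groupings$name, member = mirna_groupings$mirna)
  } else NULL
  modules <- stage("enrichment", label_modules(
    modules, gene_annotation, mirna_annotation = mirna_annot,
    gene_universe = colnames(assoc), mirna_universe = rownames(assoc)
  ))
  write_modules_json(modules, file.path(out_dir, "modules.json"))
  write_modules_tsv(modules, file.path(out_dir, "modules.tsv"))
  readr::write_tsv(
    dplyr::select(modules$annotation, -"top_terms"),
    file.path(out_dir, "module_enrichment.tsv")
  )

  layout <- if (length(modules$modules) >= 2L) {
    l <- stage("layout", layout_modules(modules))
    readr::write_tsv(l, file.path(out_dir, "module_layout.tsv"))
    save_plot_quietly(autoplot(l), file.path(out_dir, "module_map.svg"))
    l
  } else NULL

  coop <- if (!is.null(mirna_groupings) && nrow(mirna_groupings) > 0) {
    res <- stage("cooperativity", cooperativity_analysis(
      corr_restricted_to_targets(corr, assoc), assoc_targets(assoc),
      mirna_groupings, n_perm = n_perm
    ))
    readr::write_tsv(dplyr::select(res, -"result"),
                     file.path(out_dir, "cooperativity.tsv"))
    res
  } else NULL

  baseline <- if (run_baseline) {
    b <- stage("baseline", permuted_baseline(assoc, cfg, gene_annotation,
                                             real = modules))
    readr::write_tsv(tibble::tibble(
      run = rep(c("real", "permuted"), c(length(b$real_p), length(b$permuted_p))),
      top_term_p = c(b$real_p, b$permuted_p)
    ), file.path(out_dir, "baseline_pvalues.tsv"))
    b
  } else NULL

  density <- if (!is.null(validated_pairs) && nrow(validated_pairs) > 0) {
    d <- stage("density", validated_pair_density(
      modules, validated_pairs,
      baseline = if (!is.null(baseline)) baseline$permuted else NULL
    ))
    readr::write_tsv(d, file.path(out_dir, "validated_density.tsv"))
    d
  } else NULL

  manifest <- list(
    package = "mirmodules",
    version = as.character(utils::packageVersion("mirmodules")),
    rng_seed = cfg$rng_seed,
    config = cfg[setdiff(names(cfg), "t0")],
    n_mirnas = nrow(assoc), n_mrnas = ncol(assoc),
    n_modules = length(modules$modules),
    stages = c("correlation", "integration", "bicluster", "enrichment",
               if (!is.null(layout)) "layout",
               if (!is.null(coop)) "cooperativity",
               if (!is.null(baseline)) "baseline",
               if (!is.null(density)) "density")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    correlation = corr, association = assoc, modules = modules,
    layout = layout, cooperativity = coop, baseline = baseline,
    density = density, out_dir = out_dir, manifest = manifest
  ), class = "mirna_pipeline_run")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

unclass_assoc <- function(assoc) {
  x <- unclass(assoc)
  attr(x, "targets") <- NULL
  x
}

assoc_targets <- function(assoc) attr(assoc, "targets")

# Cooperativity uses raw correlations restricted to predicted-target pairs by
# default; the association matrix only supplies the target flags here.
corr_restricted_to_targets <- function(corr, assoc) {
  corr[rownames(assoc), colnames(assoc), drop = FALSE]
}

save_plot_quietly <- function(plot, path) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, plot, width = 7, height = 6)),
    error = function(e) invisible(NULL)  # headless devices may lack SVG
  )
}

#' @export
print.mirna_pipeline_run <- function(x, ...) {
  cat(sprintf("<mirna_pipeline_run> %d modules -> %s\n",
              length(x$modules$modules), x$out_dir))
  invisible(x)
}
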