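#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids and a
#' numeric body; gzipped files are handled transparently. Lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @return A numeric matrix (features x samples) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  ids <- trimws(as.character(df[[1L]]))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- ids
  validate_expression(mat, path)
}

#' Write an expression or association matrix to TSV
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "feature") {
  df <- tibble::as_tibble(mat, rownames = id_column)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read predicted miRNA-target input
#'
#' Two dialects: a two-column pair list (miRNA id, mRNA id) or a dense 0/1
#' matrix in the expression-file layout.
#'
#' @param path File path.
#' @param dialect `"pairs"` or `"matrix"`.
#' @return For `"pairs"`, a tibble with columns `mirna` and `mrna`; for
#'   `"matrix"`, a logical matrix.
#' @export
read_target_pairs <- function(path, dialect = c("pairs", "matrix")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    mat <- read_expression_tsv(path)
    mode(mat) <- "logical"
    return(mat)
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  tibble::tibble(mirna = trimws(df[[1L]]), mrna = trimws(df[[2L]]))
}

#' Read a two-column term/member annotation TSV
#'
#' @param path File path; first column term id, second member id. GAF-like
#'   files can be pre-cut to these two columns.
#' @return A tibble with columns `term` and `member`.
#' @export
read_annotation_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  tibble::tibble(term = trimws(df[[1L]]), member = trimws(df[[2L]]))
}

#' Read miRNA family definitions (miFam-like two-column TSV)
#'
#' @param path File path; first column family name, second miRNA id.
#' @return A tibble with columns `name`, `kind` (`"family"`), `mirna`.
#' @export
read_family_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  tibble::tibble(name = trimws(df[[1L]]), kind = "family",
                 mirna = trimws(df[[2L]]))
}

#' Read miRNA loci from BED
#'
#' BED6 with the name field holding the miRNA id; 0-based half-open
#' coordinates. An optional 7th column is read as the host gene (`.` = none).
#'
#' @param path File path.
#' @return A tibble with columns `mirna`, `chrom`, `start`, `end`, `strand`,
#'   `host_gene`.
#' @export
read_bed_loci <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        show_col_types = FALSE)
  out <- tibble::tibble(
    mirna = trimws(as.character(df[[4L]])),
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "+",
    host_gene = if (ncol(df) >= 7L) as.character(df[[7L]]) else NA_character_
  )
  out$host_gene[out$host_gene %in% "."] <- NA_character_
  out
}

#' Read validated miRNA-mRNA pairs (Tarbase-like two-column TSV)
#'
#' @param path File path.
#' @return A tibble with unique `mirna`, `mrna` pairs.
#' @export
read_validated_pairs <- function(path) {
  df <- read_target_pairs(path, "pairs")
  dplyr::distinct(df)
}

#' Serialize a module set to JSON
#'
#' @param module_set A `"mirna_module_set"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_modules_json <- function(module_set, path) {
  payload <- list(
    n_modules = length(module_set$modules),
    config = module_set$config[setdiff(names(module_set$config), "t0")],
    modules = lapply(seq_along(module_set$modules), function(i) {
      m <- module_set$modules[[i]]
      list(module = i, mirnas = m$mirnas, direct_mrnas = m$direct_mrnas,
           indirect_mrnas = m$indirect_mrnas, score = m$score,
           seed = m$seed[c("rows", "cols", "score")],
           edges = as.list(m$edges))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a module set's membership as a flat TSV
#'
#' One row per (module, side, feature) with the feature's mean association,
#' i.e. the [tidy()] view.
#'
#' @param module_set A `"mirna_module_set"`.
#' @param path Output path.
#' @export
write_modules_tsv <- function(module_set, path) {
  readr::write_tsv(tidy(module_set), path)
  invisible(path)
}

#' Write the synthetic dataset to a directory in the pipeline's file dialects
#'
#' Emits miRNA/mRNA expression TSVs, a target pair TSV, annotation TSV, family
#' TSV, BED loci, validated-pair TSV and a truth JSON.
#'
#' @param sim A `"mirna_sim"` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return A named list of the file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    mirna_expr = file.path(dir, "mirna_expression.tsv"),
    mrna_expr = file.path(dir, "mrna_expression.tsv"),
    targets = file.path(dir, "target_pairs.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    families = file.path(dir, "families.tsv"),
    loci = file.path(dir, "loci.bed"),
    validated = file.path(dir, "validated_pairs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(sim$mirna_expr, paths$mirna_expr, "mirna")
  write_matrix_tsv(sim$mrna_expr, paths$mrna_expr, "mrna")
  idx <- which(sim$targets, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(
    mirna = rownames(sim$targets)[idx[, 1L]],
    mrna = colnames(sim$targets)[idx[, 2L]]
  ) |> dplyr::arrange(.data$mirna, .data$mrna), paths$targets)
  readr::write_tsv(sim$annotation, paths$annotation)
  readr::write_tsv(sim$groupings[, c("name", "mirna")], paths$families)
  readr::write_tsv(tibble::tibble(
    chrom = sim$loci$chrom, start = sim$loci$start, end = sim$loci$end,
    name = sim$loci$mirna, score = 0L, strand = sim$loci$strand,
    host_gene = ifelse(is.na(sim$loci$host_gene), ".", sim$loci$host_gene)
  ), paths$loci, col_names = FALSE)
  readr::write_tsv(sim$validated_pairs, paths$validated)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}
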