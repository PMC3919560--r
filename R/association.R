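#' Spearman correlation matrix between matched miRNA and mRNA expression
#'
#' Computes the rank correlation of every miRNA profile against every mRNA
#' profile across the samples the two matrices share. This is the raw
#' correlation matrix \eqn{C(MN)} that [integrate_associations()] filters
#' against predicted-target evidence.
#'
#' @param mirna_expr,mrna_expr Numeric matrices (features x samples) with
#'   unique rownames (feature ids) and colnames (sample ids), as returned by
#'   [read_expression_tsv()].
#' @param method Correlation method passed to [stats::cor()]; the default
#'   `"spearman"` uses average ranks for ties.
#' @param min_samples Minimum number of pairwise-complete matched samples a
#'   cell needs; below this (or for a zero-variance feature) the cell is `NA`.
#' @return A numeric matrix (miRNAs x mRNAs) of correlations in `[-1, 1]`,
#'   with `NA` for cells that could not be estimated.
#' @examples
#' mi <- matrix(1:4, 1, 4, dimnames = list("miR-a", paste0("s", 1:4)))
#' mr <- matrix(4:1, 1, 4, dimnames = list("GENE1", paste0("s", 1:4)))
#' compute_correlations(mi, mr)
#' @export
compute_correlations <- function(mirna_expr, mrna_expr, method = "spearman",
                                 min_samples = 3L) {
  mirna_expr <- validate_expression(mirna_expr, "mirna_expr")
  mrna_expr <- validate_expression(mrna_expr, "mrna_expr")
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < min_samples) {
    stop(sprintf(
      "need at least %d matched samples, got %d (miRNA matrix has %d samples, mRNA matrix %d)",
      min_samples, length(shared), ncol(mirna_expr), ncol(mrna_expr)
    ), call. = FALSE)
  }
  x <- t(mirna_expr[, shared, drop = FALSE])
  y <- t(mrna_expr[, shared, drop = FALSE])
  cc <- suppressWarnings(
    cor(x, y, method = method, use = "pairwise.complete.obs")
  )
  # zero-variance features yield NaN from cor(); flag as missing, not 0
  cc[is.nan(cc)] <- NA_real_
  # enforce the pairwise-complete minimum when inputs contain NAs
  if (anyNA(mirna_expr) || anyNA(mrna_expr)) {
    nobs <- crossprod(!is.na(x), !is.na(y))
    cc[nobs < min_samples] <- NA_real_
  }
  cc
}

validate_expression <- function(mat, what) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop(sprintf("`%s` needs feature rownames and sample colnames", what),
         call. = FALSE)
  }
  rownames(mat) <- trimws(rownames(mat))
  colnames(mat) <- trimws(colnames(mat))
  if (anyDuplicated(rownames(mat))) {
    stop(sprintf("duplicated feature ids in `%s`", what), call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop(sprintf("duplicated sample ids in `%s`", what), call. = FALSE)
  }
  mat
}

#' Integrate expression correlations with predicted-target evidence
#'
#' Neutralizes cells whose correlation sign conflicts with the presence or
#' absence of a predicted target site, producing the association matrix
#' \eqn{\hat{A}} that the bicluster search operates on:
#' \itemize{
#'   \item negative correlation with a predicted site is kept (direct evidence),
#'   \item positive correlation without a site is kept (indirect evidence),
#'   \item negative without a site and positive with a site are set to 0,
#'   \item zero or missing correlations are set to 0.
#' }
#' No correlation magnitude threshold is applied.
#'
#' @param corr Numeric correlation matrix (miRNAs x mRNAs), e.g. from
#'   [compute_correlations()].
#' @param targets Logical or 0/1 matrix of predicted target sites, or a
#'   two-column data frame of (miRNA id, mRNA id) pairs as read by
#'   [read_target_pairs()]. Labels are intersected with `corr`.
#' @return A numeric matrix of class `"mirna_assoc"` (miRNAs x mRNAs) with the
#'   aligned logical target matrix in `attr(, "targets")`.
#' @export
integrate_associations <- function(corr, targets) {
  stopifnot(is.matrix(corr), is.numeric(corr))
  tmat <- as_target_matrix(targets, rownames(corr), colnames(corr))
  m <- intersect(rownames(corr), rownames(tmat))
  n <- intersect(colnames(corr), colnames(tmat))
  if (length(m) == 0L || length(n) == 0L) {
    stop("no shared miRNA/mRNA labels between correlation and target matrices",
         call. = FALSE)
  }
  cc <- corr[m, n, drop = FALSE]
  tt <- tmat[m, n, drop = FALSE]
  a <- cc
  a[is.na(a)] <- 0
  a[a < 0 & !tt] <- 0  # negative but no predicted site: conflict
  a[a > 0 & tt] <- 0   # positive despite predicted site: conflict
  structure(a, targets = tt, class = c("mirna_assoc", class(a)))
}

# Normalize pair list / 0-1 matrix / logical matrix to a logical matrix over
# the given label sets. Pairs referring to unknown labels are dropped.
as_target_matrix <- function(targets, mirna_ids, mrna_ids) {
  if (is.data.frame(targets)) {
    stopifnot(ncol(targets) >= 2L)
    mi <- trimws(as.character(targets[[1L]]))
    mr <- trimws(as.character(targets[[2L]]))
    tt <- matrix(FALSE, length(mirna_ids), length(mrna_ids),
                 dimnames = list(mirna_ids, mrna_ids))
    keep <- mi %in% mirna_ids & mr %in% mrna_ids
    tt[cbind(mi[keep], mr[keep])] <- TRUE
    return(tt)
  }
  if (is.matrix(targets)) {
    mode(targets) <- "logical"
    return(targets)
  }
  stop("`targets` must be a matrix or a two-column pair data frame",
       call. = FALSE)
}

#' @export
print.mirna_assoc <- function(x, ...) {
  nz <- sum(x != 0)
  cat(sprintf(
    "<mirna_assoc> %d miRNAs x %d mRNAs, %d non-zero associations (%.1f%%)\n",
    nrow(x), ncol(x), nz, 100 * nz / length(x)
  ))
  invisible(x)
}

#' Tidy an association matrix into a sparse triplet tibble
#'
#' @param x A `"mirna_assoc"` matrix from [integrate_associations()].
#' @param ... Unused.
#' @return A tibble with columns `mirna`, `mrna`, `association`, `predicted_target`,
#'   one row per non-zero cell.
#' @method tidy mirna_assoc
#' @export
tidy.mirna_assoc <- function(x, ...) {
  idx <- which(x != 0, arr.ind = TRUE)
  tt <- attr(x, "targets")
  tibble::tibble(
    mirna = rownames(x)[idx[, 1L]],
    mrna = colnames(x)[idx[, 2L]],
    association = x[idx],
    predicted_target = tt[idx]
  ) |>
    dplyr::arrange(.data$mirna, .data$mrna)
}
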