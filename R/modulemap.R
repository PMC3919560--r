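#' Overlap similarity between two label lists
#'
#' The list-similarity metric behind the module map:
#' `|L1 intersect L2| / max(|L1|, |L2|)`. Unlike the min-denominator form it
#' does not inflate the similarity of a small list nested in a large one, and
#' its complement `1 - s` satisfies the triangle inequality, so module
#' similarities project consistently onto plotting axes. The union denominator
#' (Jaccard) is available as an option and is also metric-complemented.
#'
#' @param l1,l2 Character vectors (non-empty after `unique()`).
#' @param denominator `"max"` (default) or `"union"`.
#' @return A similarity in `[0, 1]`: 1 iff the sets are equal, 0 iff disjoint.
#' @examples
#' overlap(c("a", "b", "c", "d"), c("a", "b"))  # 0.5
#' @export
overlap <- function(l1, l2, denominator = c("max", "union")) {
  denominator <- match.arg(denominator)
  l1 <- unique(l1); l2 <- unique(l2)
  if (length(l1) == 0L || length(l2) == 0L) {
    stop("overlap() requires non-empty sets", call. = FALSE)
  }
  inter <- length(intersect(l1, l2))
  denom <- switch(denominator,
    max = max(length(l1), length(l2)),
    union = length(union(l1, l2))
  )
  inter / denom
}

#' Pairwise module similarity matrices
#'
#' Computes the miRNA-side and mRNA-side similarity matrices over all module
#' pairs using [overlap()]; the mRNA side uses the combined direct + indirect
#' arms. Both matrices are symmetric with unit diagonal, and `1 - s` is a
#' metric on the modules.
#'
#' @param module_set A `"mirna_module_set"` with at least 2 modules.
#' @param denominator Passed to [overlap()].
#' @return A list with elements `mirna` and `mrna`, each a symmetric numeric
#'   matrix with module indices as dimnames.
#' @export
similarity_matrices <- function(module_set, denominator = "max") {
  mods <- module_set$modules
  if (length(mods) < 2L) {
    stop("need at least 2 modules to compute similarities", call. = FALSE)
  }
  mirna_sets <- lapply(mods, `[[`, "mirnas")
  mrna_sets <- lapply(mods, function(m) c(m$direct_mrnas, m$indirect_mrnas))
  list(
    mirna = overlap_matrix(mirna_sets, denominator),
    mrna = overlap_matrix(mrna_sets, denominator)
  )
}

overlap_matrix <- function(sets, denominator) {
  n <- length(sets)
  s <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s[i, j] <- s[j, i] <- overlap(sets[[i]], sets[[j]], denominator)
    }
  }
  dimnames(s) <- list(seq_len(n), seq_len(n))
  s
}

#' Classical multidimensional scaling of a similarity matrix
#'
#' Converts similarities to distances `d = 1 - s`, double-centers the squared
#' distance matrix, eigen-decomposes it and returns the top coordinates.
#' Negative eigenvalues (non-Euclidean residue) are truncated to zero. Each
#' dimension is reflected so its largest-magnitude coordinate is positive,
#' making the output deterministic.
#'
#' @param similarity Symmetric similarity matrix with unit diagonal, values in
#'   `[0, 1]`.
#' @param dims Number of dimensions (the module map uses 1 per axis).
#' @return A numeric matrix (modules x dims). All-identical modules give all
#'   zero coordinates.
#' @export
classical_mds <- function(similarity, dims = 1L) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  d <- 1 - similarity
  n <- nrow(d)
  d2 <- d^2
  jc <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * jc %*% d2 %*% jc
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  k <- min(dims, n)
  x <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  if (dims > k) x <- cbind(x, matrix(0, n, dims - k))
  # reflection convention: largest-magnitude coordinate positive per dim
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(x[, j]))
    if (x[i, j] < 0) x[, j] <- -x[, j]
  }
  rownames(x) <- rownames(similarity)
  x
}

#' Lay out annotated modules as a bubble-plot table
#'
#' Derives the 2D module map: X from classical MDS of the miRNA-side
#' similarities, Y from the mRNA side, bubble radius proportional to the
#' enriched fraction of the top category (`n/S`), a (perimeter, area) colour
#' pair per distinct category from a `palette_size^2` code, and a z-order that
#' draws larger modules behind smaller ones.
#'
#' @param module_set A labeled `"mirna_module_set"` (see [label_modules()])
#'   with at least 2 modules.
#' @param palette_size Colours in the base palette; `palette_size^2` distinct
#'   categories can be encoded (default 10, i.e. up to 100 categories). Excess
#'   categories share the `"other"` colour pair with a warning.
#' @param r_min,r_max Radius range for the linear map from enriched fraction;
#'   the defaults (0, 1) make radius equal to the fraction, i.e. directly
#'   proportional. Modules with no annotation get the minimum positive radius.
#' @param denominator Passed to [similarity_matrices()].
#' @return A tibble of class `"module_layout"`: `module`, `x`, `y`, `radius`,
#'   `label`, `fraction`, `perimeter_colour`, `area_colour`, `size` (total
#'   members) and `z_rank` (1 = drawn first / furthest back).
#' @export
layout_modules <- function(module_set, palette_size = 10L, r_min = 0,
                           r_max = 1, denominator = "max") {
  stopifnot(inherits(module_set, "mirna_module_set"))
  if (is.null(module_set$annotation)) {
    stop("modules must be annotated first; see label_modules()", call. = FALSE)
  }
  sims <- similarity_matrices(module_set, denominator)
  x <- classical_mds(sims$mirna, 1L)[, 1L]
  y <- classical_mds(sims$mrna, 1L)[, 1L]
  ann <- module_set$annotation
  frac <- ann$fraction
  filled <- frac[!is.na(frac)]
  frac[is.na(frac)] <- if (length(filled)) min(filled) * 0.1 + 1e-6 else 0.1
  radius <- r_min + frac * (r_max - r_min)

  terms <- unique(ann$label)
  capacity <- palette_size^2
  if (length(terms) > capacity) {
    warning(sprintf("%d categories exceed the %d colour-pair capacity; extras share 'other'",
                    length(terms), capacity), call. = FALSE)
    shown <- terms[seq_len(capacity - 1L)]
  } else {
    shown <- terms
  }
  code <- match(ann$label, shown)  # NA -> "other"
  code[is.na(code)] <- capacity
  perimeter <- ((code - 1L) %/% palette_size) + 1L
  area <- ((code - 1L) %% palette_size) + 1L

  size <- vapply(module_set$modules, function(m) {
    length(m$mirnas) + length(m$direct_mrnas) + length(m$indirect_mrnas)
  }, integer(1))
  out <- tibble::tibble(
    module = seq_along(module_set$modules),
    x = unname(x), y = unname(y),
    radius = radius,
    label = ann$label, fraction = ann$fraction,
    perimeter_colour = perimeter, area_colour = area,
    size = size,
    z_rank = rank(-size, ties.method = "first")
  )
  class(out) <- c("module_layout", class(out))
  out
}

#' Bubble-plot of a module layout
#'
#' @param object A `"module_layout"` tibble from [layout_modules()].
#' @param ... Unused.
#' @return A ggplot: modules positioned by miRNA-side (X) and mRNA-side (Y)
#'   MDS coordinates, bubble area scaled by radius, fill/outline encoding the
#'   top category, larger modules drawn behind smaller ones.
#' @method autoplot module_layout
#' @export
autoplot.module_layout <- function(object, ...) {
  df <- object[order(object$z_rank), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$y, size = .data$radius,
    fill = factor(.data$area_colour), colour = factor(.data$perimeter_colour)
  )) +
    ggplot2::geom_point(shape = 21, stroke = 1.2, alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 18, name = "enriched fraction") +
    ggplot2::labs(
      x = "miRNA similarity (classical MDS)",
      y = "mRNA similarity (classical MDS)",
      fill = "area colour", colour = "perimeter colour"
    ) +
    ggplot2::theme_minimal()
}

#' Cooperativity scatter/trend plot
#'
#' @param object A `"cooperativity_result"` from [cooperativity_pvalue()].
#' @param profile Optional full per-mRNA profile (from
#'   [target_count_profile()]) to show as points behind the per-level medians.
#' @param ... Unused.
#' @return A ggplot of median most-inverse correlation against the number of
#'   targeting grouping members.
#' @method autoplot cooperativity_result
#' @export
autoplot.cooperativity_result <- function(object, profile = NULL, ...) {
  med <- tidy(object)
  p <- ggplot2::ggplot(med, ggplot2::aes(x = .data$k,
                                         y = .data$median_correlation))
  if (!is.null(profile)) {
    p <- p + ggplot2::geom_jitter(
      data = profile, ggplot2::aes(x = .data$k, y = .data$correlation),
      width = 0.12, height = 0, alpha = 0.3, colour = "grey50",
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 2.5) +
    ggplot2::labs(
      x = "number of targeting grouping members (k)",
      y = "max inverse miRNA-mRNA correlation",
      title = sprintf("%s: rho = %s, P %s", object$name,
                      ifelse(is.na(object$rho), "undefined",
                             sprintf("%.2f", object$rho)),
                      format_pvalue(object$p_value, object$n_permutations))
    ) +
    ggplot2::theme_minimal()
}

#' Export a module as a bipartite graph
#'
#' Builds the module's miRNA-mRNA graph with edges weighted by |association|
#' and classed direct (inverse) or indirect (positive). Edges below the
#' sign-specific magnitude threshold are dropped — the file-based equivalent
#' of the interactive viewer's correlation sliders.
#'
#' @param module A `"mirna_module"`.
#' @param neg_threshold,pos_threshold Minimum |association| for direct and
#'   indirect edges respectively, in `[0, 1]`.
#' @param graphml_file,edges_file Optional output paths (GraphML via igraph;
#'   tab-separated edge list).
#' @return Invisibly, a list with the `igraph` graph and the edge tibble.
#' @export
export_module_graph <- function(module, neg_threshold = 0, pos_threshold = 0,
                                graphml_file = NULL, edges_file = NULL) {
  stopifnot(inherits(module, "mirna_module"),
            neg_threshold >= 0, neg_threshold <= 1,
            pos_threshold >= 0, pos_threshold <= 1)
  edges <- module$edges |>
    dplyr::filter(
      (.data$arm == "direct" & .data$association <= 0 &
         abs(.data$association) >= neg_threshold) |
        (.data$arm == "indirect" & .data$association >= 0 &
           abs(.data$association) >= pos_threshold),
      .data$association != 0
    ) |>
    dplyr::transmute(
      mirna = .data$mirna, mrna = .data$mrna,
      sign_class = .data$arm, weight = abs(.data$association)
    )
  if (nrow(edges) == 0L) {
    warning("thresholds exclude every edge; exporting an empty-edge graph",
            call. = FALSE)
  }
  vertices <- data.frame(
    name = c(module$mirnas, module$direct_mrnas, module$indirect_mrnas),
    type = c(rep(TRUE, length(module$mirnas)),
             rep(FALSE, length(module$direct_mrnas) +
                   length(module$indirect_mrnas)))
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna", "mrna", "sign_class", "weight")],
    directed = FALSE, vertices = vertices
  )
  if (!is.null(graphml_file)) {
    igraph::write_graph(g, graphml_file, format = "graphml")
  }
  if (!is.null(edges_file)) readr::write_tsv(edges, edges_file)
  invisible(list(graph = g, edges = edges))
}
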