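#' Specification of one planted module
#'
#' @param n_mirnas,n_direct,n_indirect Member counts for the miRNA set and the
#'   two mRNA arms.
#' @param effect Latent effect size: direct mRNAs follow `-effect * activity`,
#'   indirect mRNAs `+effect * activity`.
#' @param noise_sd Gaussian noise standard deviation added to every member
#'   profile (the latent activity has unit variance).
#' @return A list of class `"planted_module_spec"`.
#' @export
planted_module_spec <- function(n_mirnas = 6L, n_direct = 20L,
                                n_indirect = 10L, effect = 1, noise_sd = 0.1) {
  stopifnot(n_mirnas >= 1, n_direct >= 1, n_indirect >= 0, noise_sd >= 0)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_direct = as.integer(n_direct),
                 n_indirect = as.integer(n_indirect),
                 effect = effect, noise_sd = noise_sd),
            class = "planted_module_spec")
}

#' Specification of one planted cooperative grouping
#'
#' Members share a latent activity; each of `n_targets` mRNAs is targeted by a
#' random subset of `k` members (`k` uniform on 1..n_members) and its profile
#' is scaled so the expected member-mRNA correlation is `k * effect` — a
#' purely additive cooperativity model.
#'
#' @param n_members Grouping size.
#' @param n_targets Number of targeted mRNAs (default 500).
#' @param effect Per-additional-miRNA correlation effect (default -0.1).
#' @param noise_sd Noise on member miRNA profiles around the shared activity.
#' @return A list of class `"coop_spec"`.
#' @export
coop_spec <- function(n_members = 5L, n_targets = 500L, effect = -0.1,
                      noise_sd = 0.05) {
  stopifnot(n_members >= 2, n_targets >= 1, effect < 0,
            abs(effect) * n_members < 1, noise_sd >= 0)
  structure(list(n_members = as.integer(n_members),
                 n_targets = as.integer(n_targets),
                 effect = effect, noise_sd = noise_sd),
            class = "coop_spec")
}

#' Generate a synthetic matched miRNA/mRNA dataset with planted structure
#'
#' Emulates the statistical structure the module model assumes: each planted
#' module has a latent per-sample activity; member miRNAs track it, direct
#' mRNAs track its negative, indirect mRNAs its positive, all plus Gaussian
#' noise; background features are independent noise. Predicted-target flags
#' cover planted direct pairs (minus a false-negative rate) plus background
#' pairs at a false-positive rate. Planted gene categories coincide with
#' module arms at a configurable purity, and validated pairs fall inside
#' planted modules at a multiple of the background rate. Optional cooperative
#' groupings implement additive per-miRNA effects on shared targets.
#'
#' @param n_mirnas,n_mrnas,n_samples Matrix dimensions (defaults 200, 2000,
#'   40: a desk-scale analogue of a matched tumour panel).
#' @param module_specs List of [planted_module_spec()]s (default: 5 modules).
#' @param coop_specs Optional list of [coop_spec()]s.
#' @param bg_target_rate Background predicted-target rate (default 0.02).
#' @param fn_rate Fraction of planted direct pairs whose predicted-target flag
#'   is dropped (default 0.1), modelling prediction false negatives.
#' @param annotation_purity Fraction of each planted category coming from the
#'   module's arms (default 0.8); the rest are random background genes.
#' @param n_bg_terms Number of random background categories (default 20).
#' @param validated_in_rate,validated_bg_rate Validated-pair rates inside
#'   planted modules and among background target pairs (defaults 0.05 and
#'   0.005, a 10x planting).
#' @param rng_seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A list of class `"mirna_sim"`: `mirna_expr`, `mrna_expr` (feature x
#'   sample matrices), `targets` (logical matrix), `annotation` (term/member
#'   tibble), `groupings` (name/kind/mirna tibble covering planted modules and
#'   cooperative groups), `loci` (BED-like tibble placing cooperative group
#'   members within 10 kb), `validated_pairs` (mirna/mrna tibble) and `truth`
#'   (planted memberships, pairs and parameters).
#' @export
generate_dataset <- function(n_mirnas = 200L, n_mrnas = 2000L,
                             n_samples = 40L,
                             module_specs = replicate(5, planted_module_spec(),
                                                      simplify = FALSE),
                             coop_specs = NULL,
                             bg_target_rate = 0.02, fn_rate = 0.1,
                             annotation_purity = 0.8, n_bg_terms = 20L,
                             validated_in_rate = 0.05,
                             validated_bg_rate = 0.005,
                             rng_seed = 1L) {
  set.seed(rng_seed)
  need_mi <- sum(vapply(module_specs, `[[`, integer(1), "n_mirnas")) +
    sum(vapply(coop_specs %||% list(), `[[`, integer(1), "n_members"))
  need_mr <- sum(vapply(module_specs, function(s) s$n_direct + s$n_indirect,
                        integer(1))) +
    sum(vapply(coop_specs %||% list(), `[[`, integer(1), "n_targets"))
  if (need_mi > n_mirnas || need_mr > n_mrnas) {
    stop(sprintf(
      "planted structure needs %d miRNAs and %d mRNAs but only %d x %d available",
      need_mi, need_mr, n_mirnas, n_mrnas), call. = FALSE)
  }

  mirna_ids <- sprintf("miR-%03d", seq_len(n_mirnas))
  mrna_ids <- sprintf("GENE%04d", seq_len(n_mrnas))
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  mirna_expr <- matrix(stats::rnorm(n_mirnas * n_samples), n_mirnas,
                       dimnames = list(mirna_ids, sample_ids))
  mrna_expr <- matrix(stats::rnorm(n_mrnas * n_samples), n_mrnas,
                      dimnames = list(mrna_ids, sample_ids))
  targets <- matrix(stats::runif(n_mirnas * n_mrnas) < bg_target_rate,
                    n_mirnas, dimnames = list(mirna_ids, mrna_ids))

  next_mi <- 1L; next_mr <- 1L
  truth_modules <- list()
  groupings <- empty_grouping_tbl()
  for (k in seq_along(module_specs)) {
    sp <- module_specs[[k]]
    mi <- mirna_ids[seq.int(next_mi, length.out = sp$n_mirnas)]
    next_mi <- next_mi + sp$n_mirnas
    di <- mrna_ids[seq.int(next_mr, length.out = sp$n_direct)]
    next_mr <- next_mr + sp$n_direct
    ii <- mrna_ids[seq.int(next_mr, length.out = sp$n_indirect)]
    next_mr <- next_mr + sp$n_indirect
    z <- stats::rnorm(n_samples)
    mirna_expr[mi, ] <- rep(z, each = sp$n_mirnas) +
      stats::rnorm(sp$n_mirnas * n_samples, sd = sp$noise_sd)
    mrna_expr[di, ] <- rep(-sp$effect * z, each = sp$n_direct) +
      stats::rnorm(sp$n_direct * n_samples, sd = sp$noise_sd)
    if (sp$n_indirect > 0) {
      mrna_expr[ii, ] <- rep(sp$effect * z, each = sp$n_indirect) +
        stats::rnorm(sp$n_indirect * n_samples, sd = sp$noise_sd)
    }
    tt <- matrix(stats::runif(sp$n_mirnas * sp$n_direct) >= fn_rate,
                 sp$n_mirnas, sp$n_direct)
    targets[mi, di] <- tt
    targets[mi, ii] <- FALSE  # indirect pairs carry no predicted site
    truth_modules[[k]] <- list(mirnas = mi, direct_mrnas = di,
                               indirect_mrnas = ii, spec = sp)
    groupings <- dplyr::bind_rows(groupings, tibble::tibble(
      name = sprintf("family_%02d", k), kind = "family", mirna = mi
    ))
  }

  truth_coop <- list()
  loci <- tibble::tibble(mirna = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), host_gene = character())
  for (k in seq_along(coop_specs %||% list())) {
    sp <- coop_specs[[k]]
    mi <- mirna_ids[seq.int(next_mi, length.out = sp$n_members)]
    next_mi <- next_mi + sp$n_members
    mr <- mrna_ids[seq.int(next_mr, length.out = sp$n_targets)]
    next_mr <- next_mr + sp$n_targets
    a <- stats::rnorm(n_samples)
    mirna_expr[mi, ] <- rep(a, each = sp$n_members) +
      stats::rnorm(sp$n_members * n_samples, sd = sp$noise_sd)
    klev <- sample.int(sp$n_members, sp$n_targets, replace = TRUE)
    for (t in seq_len(sp$n_targets)) {
      who <- sample(mi, klev[t])
      r <- abs(sp$effect) * klev[t]  # target |correlation| with the activity
      beta <- r / sqrt(1 - r^2)
      mrna_expr[mr[t], ] <- sign(sp$effect) * beta * a + stats::rnorm(n_samples)
      targets[mi, mr[t]] <- FALSE
      targets[who, mr[t]] <- TRUE
    }
    truth_coop[[k]] <- list(members = mi, targets = mr, k = klev, spec = sp)
    groupings <- dplyr::bind_rows(groupings, tibble::tibble(
      name = sprintf("coop_%02d", k), kind = "genomic_cluster", mirna = mi
    ))
    # place cooperative group members within 10 kb on their own chromosome
    loci <- dplyr::bind_rows(loci, tibble::tibble(
      mirna = mi, chrom = sprintf("chr%d", k),
      start = as.integer(1000 + (seq_along(mi) - 1L) * 5000L),
      end = as.integer(1100 + (seq_along(mi) - 1L) * 5000L),
      strand = "+", host_gene = NA_character_
    ))
  }

  annotation <- synth_annotation(truth_modules, mrna_ids, annotation_purity,
                                 n_bg_terms)
  validated <- synth_validated(truth_modules, targets, validated_in_rate,
                               validated_bg_rate)

  structure(list(
    mirna_expr = mirna_expr, mrna_expr = mrna_expr, targets = targets,
    annotation = annotation, groupings = groupings, loci = loci,
    validated_pairs = validated,
    truth = list(modules = truth_modules, coop = truth_coop,
                 rng_seed = rng_seed,
                 params = list(bg_target_rate = bg_target_rate,
                               fn_rate = fn_rate,
                               annotation_purity = annotation_purity,
                               validated_in_rate = validated_in_rate,
                               validated_bg_rate = validated_bg_rate))
  ), class = "mirna_sim")
}

synth_annotation <- function(truth_modules, mrna_ids, purity, n_bg_terms) {
  planted <- purrr::imap_dfr(truth_modules, function(m, k) {
    arm <- c(m$direct_mrnas, m$indirect_mrnas)
    n_in <- max(1L, round(length(arm) * purity))
    n_out <- round(n_in / purity) - n_in
    members <- c(sample(arm, n_in),
                 sample(setdiff(mrna_ids, arm), n_out))
    tibble::tibble(term = sprintf("planted_category_%02d", k),
                   member = members)
  })
  bg <- purrr::map_dfr(seq_len(n_bg_terms), function(k) {
    size <- min(length(mrna_ids), sample(10:60, 1))
    tibble::tibble(term = sprintf("background_term_%02d", k),
                   member = sample(mrna_ids, size))
  })
  dplyr::bind_rows(planted, bg) |> dplyr::distinct()
}

synth_validated <- function(truth_modules, targets, in_rate, bg_rate) {
  inside <- purrr::map_dfr(truth_modules, function(m) {
    pairs <- expand.grid(mirna = m$mirnas, mrna = m$direct_mrnas,
                         stringsAsFactors = FALSE)
    pairs[stats::runif(nrow(pairs)) < in_rate, , drop = FALSE]
  })
  planted_mi <- unlist(lapply(truth_modules, `[[`, "mirnas"))
  planted_mr <- unlist(lapply(truth_modules,
                              function(m) c(m$direct_mrnas, m$indirect_mrnas)))
  bg_cells <- which(targets, arr.ind = TRUE)
  bg_cells <- bg_cells[!(rownames(targets)[bg_cells[, 1]] %in% planted_mi &
                           colnames(targets)[bg_cells[, 2]] %in% planted_mr), ,
                       drop = FALSE]
  keep <- stats::runif(nrow(bg_cells)) < bg_rate
  outside <- tibble::tibble(
    mirna = rownames(targets)[bg_cells[keep, 1]],
    mrna = colnames(targets)[bg_cells[keep, 2]]
  )
  dplyr::bind_rows(tibble::as_tibble(inside), outside) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$mirna, .data$mrna)
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat(sprintf(
    "<mirna_sim> %d miRNAs x %d mRNAs x %d samples; %d planted modules, %d cooperative groups\n",
    nrow(x$mirna_expr), nrow(x$mrna_expr), ncol(x$mirna_expr),
    length(x$truth$modules), length(x$truth$coop)
  ))
  invisible(x)
}
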