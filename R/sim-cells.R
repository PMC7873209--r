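#' Generate the gene annotation for a simulated dataset
#'
#' One record per gene: a unique id, its chromosome element, and a
#' log-normal gene length (bp) used later for bulk length-normalized TPM.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id`, `element`, `length`.
#' @export
#' @examples
#' ann <- generate_annotation(sim_config(seed = 1))
#' nrow(ann)  # 1242 with the default element layout
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  el <- config$elements
  gene_id <- unlist(lapply(seq_len(nrow(el)), function(i) {
    sprintf("g%s_%04d", gsub("[^0-9A-Za-z]", "", el$element[i]), seq_len(el$n_genes[i]))
  }))
  element <- rep(el$element, el$n_genes)
  lengths <- withr::with_seed(config$seed + 1000L, {
    pmax(200, round(rlnorm(length(gene_id),
                           config$gene_length_meanlog,
                           config$gene_length_sdlog)))
  })
  tibble(gene_id = gene_id, element = element, length = lengths)
}

# Build the per-gene truth (base rates, breadth classes, activity by type)
# and the genes x types relative-rate matrix. Internal.
build_gene_program <- function(config, annotation) {
  el <- config$elements
  types <- config$cell_types$type
  n_types <- length(types)
  n_genes <- nrow(annotation)

  lambda <- rlnorm(n_genes, config$gene_rate_meanlog, config$gene_rate_sdlog)
  broad <- logical(n_genes)
  marker_type <- rep(NA_character_, n_genes)
  boost <- rep(1, n_genes)
  active <- matrix(FALSE, n_genes, n_types, dimnames = list(annotation$gene_id, types))

  all_pairs <- utils::combn(types, 2)

  for (e in el$element) {
    idx <- which(annotation$element == e)
    idx <- sample(idx)  # random order within the element
    n_broad <- round(config$broad_fraction[[e]] * length(idx))
    b_idx <- idx[seq_len(n_broad)]
    r_idx <- setdiff(idx, b_idx)
    broad[b_idx] <- TRUE
    active[b_idx, ] <- TRUE
    # restricted genes: a fraction are single-type markers (boosted), the
    # rest are active in two types; assignments are balanced round-robin so
    # every element contributes active genes to every type.
    n_single <- round(config$marker_single_fraction * length(r_idx))
    s_idx <- r_idx[seq_len(n_single)]
    p_idx <- setdiff(r_idx, s_idx)
    if (length(s_idx)) {
      t_assign <- rep(sample(types), length.out = length(s_idx))
      for (k in seq_along(s_idx)) {
        marker_type[s_idx[k]] <- t_assign[k]
        active[s_idx[k], t_assign[k]] <- TRUE
      }
      boost[s_idx] <- rlnorm(length(s_idx), config$marker_boost_meanlog,
                             config$marker_boost_sdlog)
    }
    if (length(p_idx)) {
      pair_order <- sample(ncol(all_pairs))
      pair_assign <- rep(pair_order, length.out = length(p_idx))
      for (k in seq_along(p_idx)) {
        active[p_idx[k], all_pairs[, pair_assign[k]]] <- TRUE
      }
    }
  }

  # raw per-type weights; the marker boost applies only in the marker's own type
  w_boost <- matrix(1, n_genes, n_types)
  mk <- which(!is.na(marker_type))
  if (length(mk)) {
    w_boost[cbind(mk, match(marker_type[mk], types))] <- boost[mk]
  }
  w <- (lambda * w_boost) * active

  # standardize within (element, breadth class, type): mean over all genes of
  # the stratum equals 1, so dosage multipliers are the only systematic
  # driver of element-level mean expression.
  for (e in el$element) {
    for (cls in c(TRUE, FALSE)) {
      rows <- which(annotation$element == e & broad == cls)
      if (!length(rows)) next
      for (j in seq_len(n_types)) {
        s <- sum(w[rows, j])
        if (s > 0) w[rows, j] <- w[rows, j] * (length(rows) / s)
      }
    }
  }

  # apply copy number and dosage multipliers
  copies <- el$copies[match(annotation$element, el$element)]
  mult <- matrix(1, n_genes, n_types)
  for (i in seq_len(nrow(config$dosage))) {
    rows <- annotation$element == config$dosage$element[i]
    j <- match(config$dosage$type[i], types)
    mult[rows, j] <- config$dosage$multiplier[i]
  }
  rate <- w * copies * mult
  dimnames(rate) <- list(annotation$gene_id, types)

  list(
    rate = rate,
    genes = tibble(
      gene_id = annotation$gene_id,
      element = annotation$element,
      base_rate = lambda,
      broad = broad,
      marker_type = marker_type,
      active_types = lapply(seq_len(n_genes), function(i) types[active[i, ]])
    )
  )
}

#' Generate a synthetic single-cell UMI count matrix with known truth
#'
#' Draws cells of the configured types from the generative model described
#' in [sim_config()]. Counts are negative binomial (Poisson when
#' `dispersion = Inf`) around per-cell expected rates that encode the
#' configured per-copy dosage regimes; the returned truth carries the
#' per-cell type labels, per-gene breadth classes and base rates, and the
#' expected element:autosome ratios. When `config$doublet_rate > 0`,
#' doublet barcodes are appended via [inject_doublets()].
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()] for the same config.
#' @return A list with elements `counts` (sparse cells x genes integer
#'   matrix), `truth` (list: `cells`, `genes`, `expected_ratio` tibbles),
#'   and `annotation`.
#' @export
#' @examples
#' cfg <- sim_config(cell_types = tibble::tibble(
#'   type = c("A", "B"), lineage = c("soma", "soma"), n_cells = c(50, 50)),
#'   dosage = tidyr::expand_grid(element = default_elements()$element,
#'                               type = c("A", "B"), multiplier = 1),
#'   seed = 7)
#' sim <- generate_cells(cfg, generate_annotation(cfg))
#' dim(sim$counts)
generate_cells <- function(config, annotation = generate_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(sort(annotation$element[!duplicated(annotation$element)]),
                 sort(config$elements$element)) ||
      nrow(annotation) != sum(config$elements$n_genes)) {
    abort("`annotation` is inconsistent with `config`.")
  }

  out <- withr::with_seed(config$seed, {
    prog <- build_gene_program(config, annotation)
    types <- config$cell_types$type
    n_cells <- config$cell_types$n_cells
    total_cells <- sum(n_cells)
    type_of <- rep(types, n_cells)
    barcode <- sprintf("bc%06d", seq_len(total_cells))
    libsize <- rlnorm(total_cells, config$libsize_meanlog, config$libsize_sdlog)

    # expected pseudobulk rate: per-type cell numbers times per-type
    # within-cell rate shares (the generating rates of the experiment)
    p_mat <- apply(prog$rate, 2, rescale_to, total = 1)
    prog$genes$pseudobulk_rate <- as.vector(p_mat %*% n_cells)

    blocks <- vector("list", length(types))
    for (j in seq_along(types)) {
      cells_j <- which(type_of == types[j])
      if (!length(cells_j)) {
        blocks[[j]] <- NULL
        next
      }
      p <- rescale_to(prog$rate[, j], 1)
      mu <- outer(p, libsize[cells_j])  # genes x cells of this type
      n_draw <- length(mu)
      cnt <- if (is.finite(config$dispersion)) {
        rnbinom(n_draw, mu = as.vector(mu), size = config$dispersion)
      } else {
        rpois(n_draw, as.vector(mu))
      }
      m <- matrix(cnt, nrow = nrow(mu))
      dimnames(m) <- list(annotation$gene_id, barcode[cells_j])
      blocks[[j]] <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    }
    counts <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
    counts <- Matrix::t(counts[, barcode, drop = FALSE])  # cells x genes

    cells <- tibble(
      barcode = barcode, type = type_of, doublet = FALSE,
      type_a = type_of, type_b = NA_character_, heterotypic = FALSE,
      libsize = libsize
    )
    list(counts = counts, cells = cells, genes = prog$genes)
  })

  truth <- list(
    cells = out$cells,
    genes = out$genes,
    expected_ratio = expected_ratios(config)
  )
  sim <- list(counts = out$counts, truth = truth, annotation = annotation)

  if (config$doublet_rate > 0) {
    sim <- inject_doublets(sim$counts, sim$truth, rate = config$doublet_rate,
                           seed = config$seed + 1L)
    sim$annotation <- annotation
  }
  sim
}

#' Append synthetic doublet barcodes to a count matrix
#'
#' Each doublet is the sum of the count vectors of two distinct randomly
#' chosen real cells; the truth records both constituent types and flags
#' the doublet heterotypic when they differ.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param truth Truth list as produced by [generate_cells()].
#' @param rate Doublet fraction in \[0, 1): `round(rate * n_cells)` doublets
#'   are appended.
#' @param seed Integer seed.
#' @param kind `"any"` pairs cells at random; `"homotypic"` /
#'   `"heterotypic"` force the constituents to share / differ in type.
#' @return A list with updated `counts` and `truth`.
#' @export
inject_doublets <- function(counts, truth, rate, seed = 1L,
                            kind = c("any", "homotypic", "heterotypic")) {
  kind <- match.arg(kind)
  counts <- assert_counts(counts, integer = TRUE)
  if (rate < 0 || rate >= 1) abort("doublet `rate` must be in [0, 1).")
  n <- nrow(counts)
  n_d <- round(rate * n)
  if (n_d == 0) return(list(counts = counts, truth = truth))

  singlet <- !truth$cells$doublet
  pool <- which(singlet)
  types <- truth$cells$type
  pick <- withr::with_seed(seed, {
    t(vapply(seq_len(n_d), function(i) {
      first <- sample(pool, 1)
      mates <- switch(kind,
        any = setdiff(pool, first),
        homotypic = setdiff(pool[types[pool] == types[first]], first),
        heterotypic = pool[types[pool] != types[first]]
      )
      if (!length(mates)) abort("no admissible partner cell for requested doublet kind.")
      c(first, if (length(mates) == 1) mates else sample(mates, 1))
    }, integer(2)))
  })
  d_counts <- counts[pick[, 1], , drop = FALSE] + counts[pick[, 2], , drop = FALSE]
  rownames(d_counts) <- sprintf("doublet%05d", seq_len(n_d))

  ta <- truth$cells$type[pick[, 1]]
  tb <- truth$cells$type[pick[, 2]]
  d_cells <- tibble(
    barcode = rownames(d_counts),
    type = ifelse(ta == tb, ta, NA_character_),
    doublet = TRUE, type_a = ta, type_b = tb,
    barcode_a = truth$cells$barcode[pick[, 1]],
    barcode_b = truth$cells$barcode[pick[, 2]],
    heterotypic = ta != tb,
    libsize = truth$cells$libsize[pick[, 1]] + truth$cells$libsize[pick[, 2]]
  )
  truth$cells <- bind_rows(truth$cells, d_cells)
  list(counts = rbind(counts, d_counts), truth = truth)
}
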