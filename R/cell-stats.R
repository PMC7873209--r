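#' Per-cell chromosome-element to autosome expression ratio
#'
#' The central measure: for each cell c and gene set S,
#' R_c = (sum over S-and-focal genes of cpm / |S-and-focal|) /
#'       (sum over S-and-autosome genes of cpm / |S-and-autosome|),
#' i.e. element expression per annotated set gene, relative to the major
#' autosomes. Gene counts are the sizes of the gene-set intersections (not
#' per-cell detected genes), so the normalization varies with the active
#' gene set exactly as the subset does. Cells with zero autosomal
#' expression are marked invalid.
#'
#' @param norm Normalized (cpm) cells x genes matrix.
#' @param annotation Gene annotation tibble (`gene_id`, `element`).
#' @param gene_set Character vector of gene ids defining the active set S
#'   (e.g. all expressed genes, or the CTSP set).
#' @param focal Focal element (e.g. `"X"` or `"4"`).
#' @param autosomes Elements forming the autosomal reference.
#' @param set_name Label stored in the output.
#' @return A tibble (one row per cell): `barcode`, `gene_set`, `focal`,
#'   `ratio`, `n_focal_genes`, `n_autosome_genes`, `valid`.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = c("x1", "x2", "a1", "a2", "a3", "a4"),
#'                       element = c("X", "X", "2L", "2R", "3L", "3R"))
#' m <- Matrix::Matrix(matrix(10, 1, 6, dimnames = list("c1", ann$gene_id)),
#'                     sparse = TRUE)
#' chromosome_ratio(m, ann, ann$gene_id)$ratio  # 1
chromosome_ratio <- function(norm, annotation, gene_set, focal = "X",
                             autosomes = c("2L", "2R", "3L", "3R"),
                             set_name = "all") {
  norm <- assert_counts(norm)
  gene_set <- intersect(gene_set, colnames(norm))
  focal_genes <- intersect(gene_set, annotation$gene_id[annotation$element == focal])
  auto_genes <- intersect(gene_set,
                          annotation$gene_id[annotation$element %in% autosomes])
  if (!length(focal_genes)) {
    abort(sprintf("gene set has no genes on focal element '%s'.", focal))
  }
  if (!length(auto_genes)) abort("gene set has no genes on the autosomal reference.")

  num <- unname(Matrix::rowSums(norm[, focal_genes, drop = FALSE])) / length(focal_genes)
  den <- unname(Matrix::rowSums(norm[, auto_genes, drop = FALSE])) / length(auto_genes)
  valid <- den > 0
  tibble(
    barcode = rownames(norm), gene_set = set_name, focal = focal,
    ratio = ifelse(valid, num / den, NA_real_),
    n_focal_genes = length(focal_genes),
    n_autosome_genes = length(auto_genes),
    valid = valid
  )
}

#' Per-cell total expression of one element (or genome-wide)
#'
#' @param norm Normalized (cpm) cells x genes matrix.
#' @param annotation Gene annotation tibble.
#' @param element Element name, or `"genome"` for the total over all genes.
#' @return A tibble: `barcode`, `element`, `total`.
#' @export
element_expression <- function(norm, annotation, element) {
  norm <- assert_counts(norm)
  if (element == "genome") {
    genes <- intersect(annotation$gene_id, colnames(norm))
  } else {
    if (!element %in% annotation$element) {
      abort(sprintf("unknown element '%s'.", element))
    }
    genes <- intersect(annotation$gene_id[annotation$element == element],
                       colnames(norm))
  }
  tot <- if (length(genes)) Matrix::rowSums(norm[, genes, drop = FALSE]) else
    rep(0, nrow(norm))
  tibble(barcode = rownames(norm), element = element, total = as.vector(tot))
}

# running-sum enrichment score for one ranked expression vector. Internal.
es_running_sum <- function(expr, is_hit, weight) {
  ord <- order(expr, names(expr), decreasing = c(TRUE, FALSE), method = "radix")
  hit <- is_hit[ord]
  w <- abs(expr[ord])^weight
  hit_w <- w * hit
  denom_hit <- sum(hit_w)
  p_hit <- if (denom_hit > 0) cumsum(hit_w) / denom_hit else cumsum(hit) * 0
  p_miss <- cumsum(!hit) / (length(expr) - sum(is_hit))
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Per-cell gene-set enrichment score (GSEA running sum)
#'
#' For each cell, genes are ranked by expression (descending; ties broken
#' by gene id) and a weighted Kolmogorov-Smirnov running sum is computed:
#' hits advance in proportion to |expression|^weight (normalized to 1),
#' misses by 1/(N - |S|). The enrichment score is the signed maximum
#' deviation, in \[-1, 1\]: positive when set genes concentrate at the top
#' of the cell's ranking.
#'
#' @param norm Normalized (cpm) cells x genes matrix.
#' @param gene_set Character vector of gene ids (non-empty, not all genes).
#' @param weight Rank weighting exponent: 1 (default, canonical weighted
#'   form) or 0 (classic Kolmogorov-Smirnov).
#' @param set_name Label stored in the output.
#' @return A tibble: `barcode`, `gene_set`, `es`.
#' @export
gsea_cell_score <- function(norm, gene_set, weight = 1, set_name = "set") {
  norm <- assert_counts(norm)
  genes <- colnames(norm)
  gene_set <- intersect(gene_set, genes)
  if (!length(gene_set)) abort("`gene_set` is empty (after intersection).")
  if (length(gene_set) >= length(genes)) {
    abort("`gene_set` must be a strict subset of the genes.")
  }
  is_hit <- genes %in% gene_set
  names(is_hit) <- genes
  x <- as.matrix(norm)
  es <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    names(v) <- genes
    es_running_sum(v, is_hit, weight)
  }, numeric(1))
  tibble(barcode = rownames(norm), gene_set = set_name, es = es)
}

#' Summarize a per-cell measure by cell type
#'
#' Median, interquartile range (linear-interpolation quartiles, type 7),
#' notch-style 95% CI of the median (median +/- 1.57 IQR / sqrt(n)) and n,
#' over valid cells only. Types with no valid cells get an all-`NA` row.
#'
#' @param table Per-cell tibble with a `barcode` column and the value
#'   column, e.g. from [chromosome_ratio()] or [gsea_cell_score()].
#' @param labels Tibble with `barcode` and `type` columns (or a named
#'   vector of types).
#' @param value Name of the value column (default `"ratio"`).
#' @return A tibble: `type`, `n`, `median`, `q1`, `q3`, `iqr`, `ci_lo`,
#'   `ci_hi`.
#' @export
summarize_by_type <- function(table, labels, value = "ratio") {
  if (!is.data.frame(labels)) {
    labels <- tibble(barcode = names(labels), type = as.vector(labels))
  }
  if (!all(table$barcode %in% labels$barcode)) {
    abort("`labels` must cover every barcode in `table`.")
  }
  tab <- table %>% left_join(labels[, c("barcode", "type")], by = "barcode")
  v <- tab[[value]]
  ok <- !is.na(v) & (if ("valid" %in% names(tab)) tab$valid else TRUE)
  q_or_na <- function(x, i) {
    x <- x[!is.na(x)]
    if (length(x)) quartiles(x)[i] else NA_real_
  }
  tab %>%
    mutate(.v = ifelse(ok, v, NA_real_)) %>%
    group_by(.data$type) %>%
    summarise(
      n = sum(!is.na(.data$.v)),
      median = q_or_na(.data$.v, 2),
      q1 = q_or_na(.data$.v, 1),
      q3 = q_or_na(.data$.v, 3),
      .groups = "drop"
    ) %>%
    mutate(
      iqr = .data$q3 - .data$q1,
      ci_lo = .data$median - 1.57 * .data$iqr / sqrt(pmax(.data$n, 1)),
      ci_hi = .data$median + 1.57 * .data$iqr / sqrt(pmax(.data$n, 1))
    )
}
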