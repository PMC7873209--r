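#' Genes detectably expressed in a single-cell experiment
#'
#' @param counts Sparse cells x genes count matrix.
#' @param min_cells A gene is expressed when it has count > 0 in at least
#'   this many cells.
#' @return A tibble: `gene_id`, `n_cells_detected`, `expressed`.
#' @export
expressed_genes <- function(counts, min_cells = 3) {
  counts <- assert_counts(counts)
  det <- Matrix::colSums(counts > 0)
  tibble(gene_id = colnames(counts), n_cells_detected = as.integer(det),
         expressed = det >= min_cells)
}

# tissue means of a genes x samples matrix, one column per tissue
tissue_means <- function(panel, sample_meta, transform = identity) {
  if (!all(c("sample", "tissue") %in% names(sample_meta))) {
    abort("`sample_meta` must have columns `sample` and `tissue`.")
  }
  miss <- setdiff(colnames(panel), sample_meta$sample)
  if (length(miss)) abort("`sample_meta` must cover every panel sample.")
  tis <- sample_meta$tissue[match(colnames(panel), sample_meta$sample)]
  u <- unique(tis)
  if (length(u) < 2) abort("need at least 2 tissues.")
  x <- transform(as.matrix(panel))
  means <- do.call(cbind, lapply(u, function(t) {
    rowMeans(x[, tis == t, drop = FALSE])
  }))
  dimnames(means) <- list(rownames(panel), u)
  means
}

#' Tau tissue-specificity index
#'
#' Per gene, tissue means of log2(TPM + 1) are rescaled by the maximum and
#' tau = sum(1 - x_hat) / (N - 1): 0 for a uniform profile, 1 for strict
#' single-tissue expression. Genes with an all-zero profile are returned as
#' `NA`.
#'
#' @param panel Genes x samples TPM matrix.
#' @param sample_meta Tibble with columns `sample`, `tissue`.
#' @param transform `"log2"` (default; log2(TPM + 1) before averaging) or
#'   `"linear"`.
#' @return A tibble: `gene_id`, `tau`.
#' @export
compute_tau <- function(panel, sample_meta, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  f <- if (transform == "log2") function(x) log2(x + 1) else identity
  m <- tissue_means(panel, sample_meta, f)
  mx <- apply(m, 1, max)
  n <- ncol(m)
  tau <- ifelse(mx > 0, rowSums(1 - m / pmax(mx, .Machine$double.xmin)) / (n - 1), NA_real_)
  tibble(gene_id = rownames(panel), tau = as.vector(tau))
}

#' TSPS tissue-specificity score
#'
#' Per gene, the tissue shares p_i of the linear tissue-mean TPM give
#' TSPS = sum(p_i * log2(p_i * N)) — the relative entropy of the profile
#' against a uniform one, in bits. 0 for uniform expression, log2(N) for
#' strict single-tissue expression; zero shares contribute 0. All-zero
#' genes are returned as `NA`.
#'
#' @inheritParams compute_tau
#' @return A tibble: `gene_id`, `tsps`.
#' @export
compute_tsps <- function(panel, sample_meta) {
  m <- tissue_means(panel, sample_meta)
  tot <- rowSums(m)
  n <- ncol(m)
  p <- m / ifelse(tot > 0, tot, 1)
  terms <- ifelse(p > 0, p * log2(p * n), 0)
  tsps <- ifelse(tot > 0, rowSums(terms), NA_real_)
  tibble(gene_id = rownames(panel), tsps = as.vector(tsps))
}

#' CTSP: cell-level detection breadth
#'
#' Per gene, the fraction of (QC-passing) cells with count > 0; a gene is a
#' CTSP member when that fraction reaches `fraction` (default 1/3 — genes
#' expressed in at least 33% of cells).
#'
#' @param counts Sparse cells x genes count matrix (QC-passing cells).
#' @param fraction Membership threshold in (0, 1].
#' @return A tibble: `gene_id`, `ctsp_fraction`, `ctsp`.
#' @export
compute_ctsp <- function(counts, fraction = 1 / 3) {
  counts <- assert_counts(counts)
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  frac <- Matrix::colSums(counts > 0) / nrow(counts)
  tibble(gene_id = colnames(counts), ctsp_fraction = as.vector(frac),
         ctsp = frac >= fraction)
}

#' Assemble the per-gene specificity table
#'
#' Joins the expressed flag, tau, TSPS and CTSP fraction into one table
#' with membership flags at the conventional thresholds (expressed; tau <=
#' 0.5; TSPS <= 1; detected in >= 33% of cells). Genes whose tau/TSPS are
#' undefined (no adult expression) are not members of those sets.
#'
#' @param counts Sparse cells x genes single-cell count matrix.
#' @param panel Genes x samples bulk TPM matrix (tissue panel).
#' @param sample_meta Tibble with `sample`, `tissue` for `panel`.
#' @param min_cells Detection threshold for the expressed set.
#' @param tau_max,tsps_max,ctsp_fraction Membership thresholds.
#' @return A tibble: per gene, `expressed`, `tau`, `tsps`,
#'   `ctsp_fraction`, and logical set flags `set_expressed`, `set_tau`,
#'   `set_tsps`, `set_ctsp`.
#' @export
specificity_table <- function(counts, panel, sample_meta, min_cells = 3,
                              tau_max = 0.5, tsps_max = 1,
                              ctsp_fraction = 1 / 3) {
  ex <- expressed_genes(counts, min_cells)
  ct <- compute_ctsp(counts, ctsp_fraction)
  ta <- compute_tau(panel, sample_meta)
  ts <- compute_tsps(panel, sample_meta)
  ex %>%
    left_join(ct, by = "gene_id") %>%
    left_join(ta, by = "gene_id") %>%
    left_join(ts, by = "gene_id") %>%
    mutate(
      set_expressed = .data$expressed,
      set_tau = .data$expressed & !is.na(.data$tau) & .data$tau <= tau_max,
      set_tsps = .data$expressed & !is.na(.data$tsps) & .data$tsps <= tsps_max,
      set_ctsp = .data$expressed & .data$ctsp
    )
}

#' Default lineage map of the larval testis cell types
#'
#' Ordered chains: germline G -> E1 -> M1 -> L1; cyst C1 -> C2 -> C3 -> C4;
#' terminal epithelium (T) and pigment cells (P) as singleton groups.
#'
#' @return A tibble: `type`, `lineage`, `position` (1-based order within
#'   the lineage chain).
#' @export
lineage_map <- function() {
  tibble(
    type = c("G", "E1", "M1", "L1", "C1", "C2", "C3", "C4", "T", "P"),
    lineage = c(rep("germline", 4), rep("cyst", 4), "terminal", "pigment"),
    position = c(1:4, 1:4, 1L, 1L)
  )
}

# score one gene; helpers resolve types against the lineage map
score_one_gene <- function(biased, high, curated, lin) {
  resolve <- function(tt) {
    tt <- unique(tt[!is.na(tt)])
    bad <- setdiff(tt, lin$type)
    if (length(bad)) abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
    tt
  }
  biased <- resolve(biased); high <- resolve(high); curated <- resolve(curated)
  lineages <- function(tt) unique(lin$lineage[match(tt, lin$type)])
  pos <- function(t) lin$position[match(t, lin$type)]
  # curated expression downstream of predicted bias in the same chain counts
  # as a match: protein may lag transcription.
  later_same_chain <- function(pred, cur) {
    length(pred) > 0 && length(cur) > 0 &&
      all(vapply(cur, function(ct) {
        any(vapply(pred, function(pt) {
          lin$lineage[match(pt, lin$type)] == lin$lineage[match(ct, lin$type)] &&
            pos(ct) >= pos(pt)
        }, logical(1)))
      }, logical(1)))
  }
  if (length(curated) && length(biased) &&
      (setequal(biased, curated) || later_same_chain(biased, curated))) return(4L)
  if (length(curated) && length(high) && setequal(high, curated)) return(3L)
  if (length(intersect(lineages(biased), lineages(curated)))) return(2L)
  if (length(intersect(lineages(high), lineages(curated)))) return(1L)
  0L
}

#' Concordance score between predicted and curated expression (0-4)
#'
#' Scores each gene's predicted single-cell expression pattern against
#' curated image-based expression domains: 4 = cell-type-biased expression
#' in exactly the curated types, or curated expression later in the same
#' lineage chain (protein lags transcription); 3 = highly expressed (not
#' biased) in exactly the curated types; 2 = biased in the same lineage;
#' 1 = highly expressed in the same lineage; 0 = no overlap.
#'
#' @param predicted Tibble with `gene_id` and list-columns `biased_types`
#'   (cell types where the gene is in the differential set) and
#'   `high_types` (cell types where the gene is highly expressed).
#' @param curated Tibble with `gene_id` and list-column `domains` (curated
#'   expression cell types).
#' @param lineage Lineage map as [lineage_map()].
#' @return A tibble: `gene_id`, `score` (integer 0-4).
#' @export
concordance_score <- function(predicted, curated, lineage = lineage_map()) {
  tab <- predicted %>% left_join(curated, by = "gene_id")
  tab$score <- vapply(seq_len(nrow(tab)), function(i) {
    score_one_gene(tab$biased_types[[i]], tab$high_types[[i]],
                   tab$domains[[i]] %||% character(0), lineage)
  }, integer(1))
  tab %>% select("gene_id", "score")
}
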