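#' Mann-Whitney U test
#'
#' U for `x` over `y` with midrank ties. The p-value is exact when
#' min(n) <= 8 and there are no ties, otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return A tibble: `u`, `p_value`, `method`, `n_x`, `n_y`.
#' @export
#' @examples
#' mwu(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mwu <- function(x, y) {
  if (!length(x) || !length(y)) abort("`x` and `y` must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  p <- wt$p.value
  if (is.na(p)) p <- 1  # zero-variance rank configuration (all values tied)
  tibble(
    u = unname(wt$statistic),
    p_value = min(p, 1),
    method = if (exact) "exact" else "normal approximation",
    n_x = length(x), n_y = length(y)
  )
}

# U statistic from pooled midranks for the units in `idx` (group x).
u_from_ranks <- function(ranks, idx, n_x) {
  sum(ranks[idx]) - n_x * (n_x + 1) / 2
}

# two-sided normal-approximation p (tie + continuity corrected); internal
# fast path used inside permutation loops.
mwu_p_normal <- function(pooled, idx_x) {
  n <- length(pooled)
  n1 <- length(idx_x)
  n2 <- n - n1
  r <- rank(pooled)
  u <- u_from_ranks(r, idx_x, n1)
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

# extract a per-cell value vector (validity-filtered) from a stats table
values_by_barcode <- function(table, value) {
  v <- table[[value]]
  if (is.null(v)) abort(sprintf("column '%s' not found.", value))
  ok <- !is.na(v)
  if ("valid" %in% names(table)) ok <- ok & table$valid
  setNames(v[ok], table$barcode[ok])
}

#' Cell-label permutation test for a pairwise cell-type comparison
#'
#' Computes the observed Mann-Whitney U between the per-cell values of cell
#' types `a` and `b`, then permutes the pooled cell-type labels `n_iter`
#' times, recomputing U each time. The permutation p-value is the add-one
#' fraction of permutations at least as extreme as the observed test,
#' two-sided on |U - E\[U\]| by default.
#'
#' @param table Per-cell tibble (e.g. from [chromosome_ratio()]) with a
#'   `barcode` column; invalid/NA cells are dropped.
#' @param labels Tibble with `barcode`, `type` (or a named type vector).
#' @param a,b Cell-type names to compare (distinct; >= 2 valid cells each).
#' @param value Name of the value column.
#' @param n_iter Number of permutations.
#' @param alternative `"two_sided"` on |U - E\[U\]|, or `"greater"` /
#'   `"less"` on U itself.
#' @param seed Integer seed.
#' @return A one-row tibble: `comparison`, `n_a`, `n_b`, `u`, `p_mwu`
#'   (analytic two-sided p), `p_perm`, `n_iter`, `seed`.
#' @export
pairwise_permutation_test <- function(table, labels, a, b, value = "ratio",
                                      n_iter = 10000,
                                      alternative = c("two_sided", "greater", "less"),
                                      seed = 1L) {
  alternative <- match.arg(alternative)
  if (identical(a, b)) abort("`a` and `b` must be distinct cell types.")
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  if (!is.data.frame(labels)) {
    labels <- tibble(barcode = names(labels), type = as.vector(labels))
  }
  v <- values_by_barcode(table, value)
  type <- labels$type[match(names(v), labels$barcode)]
  xa <- v[which(type == a)]
  xb <- v[which(type == b)]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("both cell types need at least 2 valid cells.")
  }

  pooled <- c(xa, xb)
  n1 <- length(xa)
  n <- length(pooled)
  ranks <- rank(pooled)
  u_obs <- u_from_ranks(ranks, seq_len(n1), n1)
  e_u <- n1 * (n - n1) / 2

  u_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      u_from_ranks(ranks, sample.int(n, n1), n1)
    }, numeric(1))
  })
  extreme <- switch(alternative,
    two_sided = abs(u_perm - e_u) >= abs(u_obs - e_u),
    greater = u_perm >= u_obs,
    less = u_perm <= u_obs
  )
  tibble(
    comparison = paste(a, "vs", b),
    n_a = n1, n_b = n - n1,
    u = u_obs,
    p_mwu = mwu(xa, xb)$p_value,
    p_perm = (1 + sum(extreme)) / (n_iter + 1),
    n_iter = n_iter, seed = as.integer(seed)
  )
}

#' Cell-type vs random-sample permutation test (mean comparison)
#'
#' Compares the per-cell values of one cell type against repeated uniform
#' random samples of the same size drawn from all cells in the experiment,
#' via the Mann-Whitney U test. Reports the fraction of iterations in which
#' the type differed at `alpha` (the "significant fraction") and declares
#' the type different when that fraction reaches `decision`.
#'
#' @inheritParams pairwise_permutation_test
#' @param type Cell type to test (>= 2 valid cells; fewer than the total).
#' @param alpha Per-iteration significance level.
#' @param decision Significant-fraction threshold for the overall call.
#' @return A one-row tibble: `type`, `n`, `n_total`, `significant_fraction`,
#'   `different`, `alpha`, `n_iter`, `seed`.
#' @export
mean_permutation_test <- function(table, labels, type, value = "ratio",
                                  n_iter = 10000, alpha = 0.01,
                                  decision = 0.95, seed = 1L) {
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  if (!is.data.frame(labels)) {
    labels <- tibble(barcode = names(labels), type = as.vector(labels))
  }
  v <- values_by_barcode(table, value)
  tl <- labels$type[match(names(v), labels$barcode)]
  xt <- v[which(tl == type)]
  n_t <- length(xt)
  if (n_t < 2) abort("the cell type needs at least 2 valid cells.")
  if (n_t >= length(v)) abort("the cell type must be smaller than the experiment.")

  sig <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      samp <- v[sample.int(length(v), n_t)]
      mwu_p_normal(c(xt, samp), seq_len(n_t)) <= alpha
    }, logical(1))
  })
  frac <- mean(sig)
  tibble(
    type = type, n = n_t, n_total = length(v),
    significant_fraction = frac, different = frac >= decision,
    alpha = alpha, n_iter = n_iter, seed = as.integer(seed)
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up q-values: monotone, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return A numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; requires every expected count to be positive.
#'
#' @param table Counts matrix (r x c).
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_independence(matrix(c(20, 10, 10, 20), 2))  # chi2 = 6.667
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("counts must be non-negative.")
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("degenerate table: independence needs at least 2 rows and 2 columns.")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    abort("some expected counts are zero; merge degenerate categories first.")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric vector (n >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed.
#' @return A one-row tibble: `mean`, `ci_lo`, `ci_hi`, `level`, `n_boot`.
#' @export
bootstrap_ci_mean <- function(values, n_boot = 1000, level = 0.95, seed = 1L) {
  if (length(values) < 2) abort("need at least 2 values.")
  if (level <= 0 || level >= 1) abort("`level` must lie strictly in (0, 1).")
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7, names = FALSE)
  tibble(mean = mean(values), ci_lo = qs[1], ci_hi = qs[2],
         level = level, n_boot = n_boot)
}

#' Per-sample mean expression of each chromosome element
#'
#' For each sample and element: the summed TPM of the element's expressed
#' genes divided by the number of expressed genes on that arm.
#'
#' @param bulk_tpm Genes x samples TPM matrix.
#' @param annotation Gene annotation tibble (`gene_id`, `element`).
#' @param expressed Character vector of expressed gene ids.
#' @return A tibble: `sample`, `element`, `mean_tpm`, `n_genes`.
#' @export
arm_mean_expression <- function(bulk_tpm, annotation, expressed) {
  genes <- intersect(rownames(bulk_tpm), expressed)
  ann <- annotation[annotation$gene_id %in% genes, ]
  out <- lapply(split(ann$gene_id, ann$element), function(g) {
    colMeans(as.matrix(bulk_tpm[g, , drop = FALSE]))
  })
  bind_rows(lapply(names(out), function(e) {
    tibble(sample = colnames(bulk_tpm), element = e, mean_tpm = out[[e]],
           n_genes = sum(ann$element == e))
  }))
}

#' Per-arm sex-bias statistics for a bulk panel
#'
#' For every chromosome element: per-sex mean of the per-sample arm means
#' (summed TPM over expressed genes / number of expressed genes), a
#' percentile bootstrap CI of each sex's mean, a Welch two-sided t-test of
#' male vs female across replicates, Benjamini-Hochberg correction across
#' elements, and a flag for elements with significantly reduced male
#' expression (q <= `q_max` and male < female). Elements with no expressed
#' genes are omitted.
#'
#' @param bulk_tpm Genes x samples TPM matrix (one tissue).
#' @param annotation Gene annotation tibble.
#' @param sample_meta Tibble with `sample`, `sex` (`"male"`/`"female"`; >=
#'   2 replicates per sex).
#' @param expressed Character vector of expressed gene ids.
#' @param q_max Significance threshold on the BH-corrected q-value.
#' @param n_boot,level,seed Bootstrap parameters.
#' @return A tibble: per element, per-sex means with CIs, `t`, `p_value`,
#'   `q_value`, `male_reduced`.
#' @export
arm_sex_bias <- function(bulk_tpm, annotation, sample_meta, expressed,
                         q_max = 0.01, n_boot = 1000, level = 0.95, seed = 1L) {
  if (!all(c("sample", "sex") %in% names(sample_meta))) {
    abort("`sample_meta` must have columns `sample` and `sex`.")
  }
  sex <- sample_meta$sex[match(colnames(bulk_tpm), sample_meta$sample)]
  if (anyNA(sex)) abort("`sample_meta` must cover every sample.")
  if (sum(sex == "male") < 2 || sum(sex == "female") < 2) {
    abort("need at least 2 replicates per sex.")
  }
  arms <- arm_mean_expression(bulk_tpm, annotation, expressed)
  arms$sex <- sex[match(arms$sample, colnames(bulk_tpm))]

  res <- arms %>%
    group_by(.data$element) %>%
    summarise(
      n_genes = .data$n_genes[1],
      mean_female = mean(.data$mean_tpm[.data$sex == "female"]),
      mean_male = mean(.data$mean_tpm[.data$sex == "male"]),
      female_ci_lo = bootstrap_ci_mean(.data$mean_tpm[.data$sex == "female"],
                                       n_boot, level, seed)$ci_lo,
      female_ci_hi = bootstrap_ci_mean(.data$mean_tpm[.data$sex == "female"],
                                       n_boot, level, seed)$ci_hi,
      male_ci_lo = bootstrap_ci_mean(.data$mean_tpm[.data$sex == "male"],
                                     n_boot, level, seed + 1L)$ci_lo,
      male_ci_hi = bootstrap_ci_mean(.data$mean_tpm[.data$sex == "male"],
                                     n_boot, level, seed + 1L)$ci_hi,
      t = t.test(.data$mean_tpm[.data$sex == "male"],
                 .data$mean_tpm[.data$sex == "female"])$statistic,
      p_value = t.test(.data$mean_tpm[.data$sex == "male"],
                       .data$mean_tpm[.data$sex == "female"])$p.value,
      .groups = "drop"
    ) %>%
    mutate(
      q_value = bh_fdr(.data$p_value),
      male_reduced = .data$q_value <= q_max & .data$mean_male < .data$mean_female
    )
  res
}

#' Contingency table of sex-bias classes by chromosome element
#'
#' Counts of `male` / `female` / `unbiased` genes on each element, in the
#' shape [chi2_independence()] expects.
#'
#' @param de_labels Tibble with `gene_id` and `class` (one of `"male"`,
#'   `"female"`, `"unbiased"`).
#' @param annotation Gene annotation tibble.
#' @return An elements x classes integer matrix.
#' @export
sex_bias_classes <- function(de_labels, annotation) {
  ok <- c("male", "female", "unbiased")
  bad <- setdiff(unique(de_labels$class), ok)
  if (length(bad)) {
    abort(paste0("unknown sex-bias class(es): ", paste(bad, collapse = ", ")))
  }
  el <- annotation$element[match(de_labels$gene_id, annotation$gene_id)]
  if (anyNA(el)) abort("`annotation` must cover every labeled gene.")
  tab <- table(element = el, class = factor(de_labels$class, levels = ok))
  m <- as.matrix(unclass(tab))
  m[, colSums(m) > 0, drop = FALSE]
}
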