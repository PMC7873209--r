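#' Flag low-content barcodes
#'
#' A barcode is flagged when it expresses (count > 0) fewer than
#' `min_genes` genes — the first pass that removes likely-empty droplets.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param min_genes Minimum number of detected genes.
#' @return A tibble: `barcode`, `n_genes`, `low_content`.
#' @export
filter_low_content <- function(counts, min_genes) {
  counts <- assert_counts(counts)
  if (min_genes < 0) abort("`min_genes` must be >= 0.")
  n_genes <- Matrix::rowSums(counts > 0)
  tibble(barcode = rownames(counts), n_genes = as.integer(n_genes),
         low_content = n_genes < min_genes)
}

# log-normalized expression (log1p of counts-per-million) restricted to the
# `n_var_genes` most variable genes. Internal; returns a dense matrix.
log_variable_matrix <- function(counts, n_var_genes) {
  norm <- normalize_counts(counts, "cpm")
  ln <- norm
  ln@x <- log1p(ln@x)
  if (n_var_genes < ncol(ln)) {
    mu <- Matrix::colMeans(ln)
    ex2 <- Matrix::colMeans(ln^2)
    v <- ex2 - mu^2
    keep <- order(v, decreasing = TRUE)[seq_len(n_var_genes)]
    ln <- ln[, sort(keep), drop = FALSE]
  } else if (n_var_genes > ncol(ln)) {
    warn("fewer genes than `n_var_genes`; using all genes.")
  }
  as.matrix(ln)
}

# chunked brute-force k nearest neighbours in a low-dimensional embedding
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  k <- min(k, n - 1)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * emb[rows, , drop = FALSE] %*% t(emb)
    for (i in seq_along(rows)) {
      d2[i, rows[i]] <- Inf
      idx[rows[i], ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  idx
}

#' Cluster cells by community detection on a nearest-neighbour graph
#'
#' The standard recipe: log-normalize (log1p of cpm), keep the most
#' variable genes, embed by principal components, build a k-nearest-
#' neighbour graph, and partition it by modularity-based community
#' detection (Louvain) at the given resolution. Deterministic given `seed`.
#'
#' @param counts Sparse cells x genes count matrix (>= 2 cells).
#' @param n_var_genes Number of most-variable genes retained.
#' @param resolution Modularity resolution (higher = more clusters).
#' @param n_pcs Number of principal components.
#' @param k Neighbours per cell in the graph.
#' @param seed Integer seed.
#' @return A named integer vector of cluster labels (one per cell).
#' @export
cluster_cells <- function(counts, n_var_genes = 2000, resolution = 0.3,
                          n_pcs = 20, k = 15, seed = 1L) {
  counts <- assert_counts(counts)
  n <- nrow(counts)
  if (n < 2) abort("clustering needs at least 2 cells.")
  x <- log_variable_matrix(counts, n_var_genes)
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0) {
    return(setNames(rep(1L, n), rownames(counts)))  # all cells identical
  }
  x <- scale(x)
  n_pcs <- min(n_pcs, ncol(x) - 1, n - 1)
  emb <- withr::with_seed(seed, {
    if (n_pcs < 1) {
      x
    } else if (min(dim(x)) > 3 * n_pcs) {
      irlba::prcomp_irlba(x, n = n_pcs, center = FALSE, scale. = FALSE)$x
    } else {
      stats::prcomp(x, center = FALSE, scale. = FALSE)$x[, seq_len(max(n_pcs, 1)), drop = FALSE]
    }
  })
  nn <- knn_indices(emb, k)
  edges <- cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr::with_seed(seed, {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  setNames(as.integer(igraph::membership(comm)), rownames(counts))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: (Index - Expected) /
#' (Max - Expected) over the contingency table of the two labelings. 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return A single numeric value in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("labelings must have equal length.")
  n <- length(a)
  if (n < 2) abort("need at least 2 items.")
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  expected <- si * sj / (n * (n - 1) / 2)
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)
  (sij - expected) / (maximum - expected)
}

#' Select an upper expressed-gene threshold by clustering stability
#'
#' Homotypic multiplets sit at the top of the per-cell expressed-gene
#' distribution, but a hard cap risks discarding genuinely high-content cell
#' types. This grid search drops, for each candidate threshold, the cells
#' whose expressed-gene count exceeds it, re-clusters the remainder, and
#' compares labelings by adjusted Rand index on the cells common to all
#' usable thresholds. The selected threshold is the smallest whose labeling
#' has ARI >= `stability` against the most permissive threshold's labeling
#' (the reference); if none qualifies the reference threshold is returned.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param thresholds Candidate expressed-gene caps (>= 2 values).
#' @param stability Minimum ARI against the reference labeling.
#' @param min_cells Thresholds retaining fewer cells are skipped with a
#'   warning.
#' @param seed Integer seed (passed to [cluster_cells()]).
#' @param ... Further arguments to [cluster_cells()].
#' @return A `grid_search_report`: list with `summary` (tibble: threshold,
#'   cells retained/removed, ARI vs reference), `ari` (pairwise matrix),
#'   `selected`, `removed` (barcodes dropped at the selected threshold) and
#'   `labels`.
#' @export
select_upper_threshold <- function(counts, thresholds = c(4000, 5000, 6000),
                                   stability = 0.95, min_cells = 50,
                                   seed = 1L, ...) {
  counts <- assert_counts(counts)
  if (length(thresholds) < 2) abort("need at least 2 thresholds.")
  thresholds <- sort(thresholds)
  n_genes <- Matrix::rowSums(counts > 0)

  usable <- logical(length(thresholds))
  retained <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    keep <- which(n_genes <= thresholds[i])
    if (length(keep) < min_cells) {
      warn(sprintf("threshold %g retains %d cells (< %d); skipped.",
                   thresholds[i], length(keep), min_cells))
      next
    }
    usable[i] <- TRUE
    retained[[i]] <- keep
  }
  if (!any(usable)) abort("every threshold was skipped; no usable grid point.")

  labels <- vector("list", length(thresholds))
  for (i in which(usable)) {
    labels[[i]] <- cluster_cells(counts[retained[[i]], , drop = FALSE],
                                 seed = seed, ...)
  }

  common <- rownames(counts)[Reduce(intersect, retained[usable])]
  ui <- which(usable)
  ari <- matrix(NA_real_, length(thresholds), length(thresholds),
                dimnames = list(thresholds, thresholds))
  for (i in ui) for (j in ui) {
    ari[i, j] <- if (i == j) 1 else
      adjusted_rand_index(labels[[i]][common], labels[[j]][common])
  }

  ref <- max(ui)  # most permissive usable threshold
  ok <- ui[ari[ui, ref] >= stability]
  selected <- thresholds[if (length(ok)) min(ok) else ref]
  sel_i <- match(selected, thresholds)
  removed <- rownames(counts)[n_genes > selected]

  structure(list(
    summary = tibble(
      threshold = thresholds,
      usable = usable,
      n_retained = vapply(retained, function(r) length(r %||% integer()), integer(1)),
      n_removed = nrow(counts) - vapply(retained, function(r) length(r %||% integer()), integer(1)),
      ari_vs_reference = ari[, ref],
      selected = thresholds == selected
    ),
    ari = ari, selected = selected, stability = stability,
    removed = removed, labels = labels[[sel_i]]
  ), class = "grid_search_report")
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat("<grid_search_report> selected threshold:", x$selected,
      "(stability >=", x$stability, "vs most permissive)\n")
  print(x$summary)
  invisible(x)
}

#' Flag heterotypic multiplets by in-silico mixing of cluster centroids
#'
#' Heterotypic doublets look like intermediates between two cell types. For
#' every unordered cluster pair and mixing fraction f, a mixture profile
#' f * centroid_a + (1 - f) * centroid_b is formed from the clusters' mean
#' cpm profiles on the variable-gene set — in linear space, because a
#' doublet is a sum of two cells' counts — and compared on the log1p scale:
#' a cell is flagged when its best Pearson correlation to any mixture of two
#' pure clusters exceeds its best correlation to any pure centroid by more
#' than `margin`.
#'
#' Doublets numerous enough to be granted their own cluster would otherwise
#' hide behind their own centroid, so with three or more clusters the
#' centroids are screened first: a cluster whose centroid correlates better
#' with a mixture of two *other* clusters than with any single other
#' cluster is mixture-like, and is removed from the pure reference set
#' (at least the two least mixture-like clusters are always kept).
#'
#' @param counts Sparse cells x genes count matrix.
#' @param labels Cluster labels (named vector covering the barcodes, >= 2
#'   clusters).
#' @param fractions Mixing fractions in (0, 1).
#' @param margin Required advantage of the best mixture over the best pure
#'   centroid.
#' @param n_var_genes Number of most-variable genes used for profiles.
#' @return A list: `flags` (tibble: barcode, cluster, best pure / mixture
#'   correlations, `heterotypic`) and `model` (centroid and mixture
#'   profiles plus the cluster screen).
#' @export
detect_heterotypic <- function(counts, labels, fractions = 0.5, margin = 0,
                               n_var_genes = 2000) {
  counts <- assert_counts(counts)
  if (any(fractions <= 0 | fractions >= 1)) abort("fractions must lie in (0, 1).")
  labels <- labels[rownames(counts)]
  if (anyNA(labels)) abort("`labels` must cover every barcode.")
  cl <- as.character(sort(unique(labels)))
  if (length(cl) < 2) abort("need at least 2 clusters for in-silico mixing.")

  x <- log_variable_matrix(counts, n_var_genes)
  lin <- expm1(x)  # linear cpm on the variable-gene set
  centroids_lin <- vapply(cl, function(g) colMeans(lin[labels == g, , drop = FALSE]),
                          numeric(ncol(lin)))
  colnames(centroids_lin) <- cl
  centroids <- log1p(centroids_lin)

  mix_of <- function(a, b, f) log1p(f * centroids_lin[, a] + (1 - f) * centroids_lin[, b])

  # centroid screen: is cluster c itself better explained as a mixture of
  # two other clusters than as (close to) any single other cluster?
  mix_excess <- rep(-Inf, length(cl))
  names(mix_excess) <- cl
  if (length(cl) >= 3) {
    for (c_i in cl) {
      others <- setdiff(cl, c_i)
      bp <- max(cor(centroids[, c_i], centroids[, others]))
      bm <- -Inf
      op <- utils::combn(others, 2)
      for (p in seq_len(ncol(op))) {
        for (f in fractions) {
          bm <- max(bm, cor(centroids[, c_i], mix_of(op[1, p], op[2, p], f)))
        }
      }
      mix_excess[c_i] <- bm - bp
    }
  }
  mixture_like <- mix_excess > margin
  if (sum(!mixture_like) < 2) {  # always keep >= 2 pure clusters
    keep <- names(sort(mix_excess))[1:2]
    mixture_like[keep] <- FALSE
  }
  pure_cl <- cl[!mixture_like]

  pairs <- utils::combn(pure_cl, 2)
  mix_names <- character(0)
  mixtures <- matrix(0, nrow(centroids), ncol(pairs) * length(fractions))
  k <- 0
  for (p in seq_len(ncol(pairs))) {
    for (f in fractions) {
      k <- k + 1
      mixtures[, k] <- mix_of(pairs[1, p], pairs[2, p], f)
      mix_names[k] <- sprintf("%s:%s@%.2f", pairs[1, p], pairs[2, p], f)
    }
  }
  colnames(mixtures) <- mix_names

  cor_pure <- cor(t(x), centroids[, pure_cl, drop = FALSE])
  cor_mix <- cor(t(x), mixtures)
  best_pure <- apply(cor_pure, 1, max)
  best_mix_i <- apply(cor_mix, 1, which.max)
  best_mix <- cor_mix[cbind(seq_len(nrow(x)), best_mix_i)]

  flags <- tibble(
    barcode = rownames(counts),
    cluster = as.vector(labels),
    best_pure_cor = as.vector(best_pure),
    best_mixture_cor = as.vector(best_mix),
    best_mixture = mix_names[best_mix_i],
    heterotypic = as.vector(best_mix - best_pure > margin)
  )
  model <- structure(list(
    centroids = centroids, mixtures = mixtures, fractions = fractions,
    margin = margin,
    cluster_screen = tibble(cluster = cl, mixture_excess = as.vector(mix_excess),
                            mixture_like = as.vector(mixture_like))
  ), class = "mixture_model")
  list(flags = flags, model = model)
}
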