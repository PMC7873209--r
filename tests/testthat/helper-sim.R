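# shared fixtures, built in code

# a flat two-type configuration (no dosage signal unless overridden)
two_type_config <- function(n_each = 200, seed = 3, dosage_multiplier = 1,
                            types = c("A", "B"), ...) {
  ct <- tibble::tibble(type = types, lineage = "soma",
                       n_cells = rep(n_each, length(types)))
  dos <- tidyr::expand_grid(element = default_elements()$element,
                            type = types, multiplier = dosage_multiplier)
  sim_config(cell_types = ct, dosage = dos, seed = seed, ...)
}

# a deterministic dense fixture matrix (cells x genes)
tiny_counts <- function(values, barcodes, genes) {
  m <- matrix(values, nrow = length(barcodes), byrow = TRUE,
              dimnames = list(barcodes, genes))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# annotation for tiny fixtures: first `n_x` genes on X, the rest split over
# the major arms
tiny_annotation <- function(genes, n_x = 2) {
  majors <- rep(c("2L", "2R", "3L", "3R"), length.out = length(genes) - n_x)
  tibble::tibble(gene_id = genes,
                 element = c(rep("X", n_x), majors),
                 length = 1000)
}

# brute-force pair-counting adjusted Rand index (independent oracle)
ari_oracle <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_ab <- s_ab + (same_a && same_b)
      s_a <- s_a + same_a
      s_b <- s_b + same_b
    }
  }
  total <- n * (n - 1) / 2
  expected <- s_a * s_b / total
  maximum <- (s_a + s_b) / 2
  if (maximum == expected) return(1)
  (s_ab - expected) / (maximum - expected)
}

# brute-force exact two-sided Mann-Whitney p by enumeration of all label
# assignments (independent oracle; no ties assumed)
mwu_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_idx <- utils::combn(length(pooled), n1)
  us <- apply(all_idx, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# brute-force GSEA running-sum oracle (plain loop over the ranking)
es_oracle <- function(expr, gene_set, weight) {
  genes <- names(expr)
  ord <- genes[order(-expr, genes)]
  hit <- ord %in% gene_set
  w <- abs(expr[ord])^weight
  nh <- sum(w[hit])
  n_miss <- length(genes) - sum(hit)
  run <- 0; best <- 0
  for (i in seq_along(ord)) {
    run <- run + if (hit[i]) w[i] / nh else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}
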