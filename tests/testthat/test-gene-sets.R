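make_panel <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("expressed-gene detection follows the min-cells rule", {
  m <- tiny_counts(c(1, 0, 2, 0, 3, 0, 0, 0), paste0("c", 1:4), c("gA", "gB"))
  ex <- expressed_genes(m, min_cells = 3)
  expect_true(ex$expressed[ex$gene_id == "gA"])   # detected in exactly 3 cells
  expect_false(ex$expressed[ex$gene_id == "gB"])  # all-zero gene
  one <- tiny_counts(c(0, 2), "c1", c("g1", "g2"))
  ex1 <- expressed_genes(one, min_cells = 1)
  expect_equal(sum(ex1$expressed), 1)
})

test_that("tau hits its closed forms", {
  meta <- tibble::tibble(sample = paste0("s", 1:3), tissue = paste0("t", 1:3))
  uni <- make_panel(rep(7, 3), "g1", meta$sample)
  expect_equal(compute_tau(uni, meta)$tau, 0)

  solo <- make_panel(c(9, 0, 0), "g1", meta$sample)
  expect_equal(compute_tau(solo, meta)$tau, 1)

  # normalized log profile (1, 0.5, 0): tau = ((0) + (0.5) + (1)) / 2 = 0.75
  prof <- make_panel(c(2^8 - 1, 2^4 - 1, 0), "g1", meta$sample)
  expect_equal(compute_tau(prof, meta)$tau, 0.75)

  zero <- make_panel(rep(0, 3), "g1", meta$sample)
  expect_true(is.na(compute_tau(zero, meta)$tau))
  expect_error(compute_tau(uni[, 1, drop = FALSE], meta[1, ]), "2 tissues")
})

test_that("TSPS hits its closed forms and is exactly scale-invariant", {
  meta <- tibble::tibble(sample = paste0("s", 1:4), tissue = paste0("t", 1:4))
  expect_equal(compute_tsps(make_panel(rep(5, 4), "g1", meta$sample), meta)$tsps, 0)
  expect_equal(compute_tsps(make_panel(c(8, 0, 0, 0), "g1", meta$sample), meta)$tsps, 2)
  expect_equal(compute_tsps(make_panel(c(4, 4, 0, 0), "g1", meta$sample), meta)$tsps, 1)

  x <- c(3, 1, 7, 2)
  expect_equal(compute_tsps(make_panel(x, "g1", meta$sample), meta)$tsps,
               compute_tsps(make_panel(1000 * x, "g1", meta$sample), meta)$tsps)
})

test_that("tau (linear mode) is invariant to positive scaling of a profile", {
  meta <- tibble::tibble(sample = paste0("s", 1:4), tissue = paste0("t", 1:4))
  x <- c(6, 2, 1, 0)
  t1 <- compute_tau(make_panel(x, "g1", meta$sample), meta, transform = "linear")$tau
  t2 <- compute_tau(make_panel(50 * x, "g1", meta$sample), meta, transform = "linear")$tau
  expect_equal(t1, t2)
})

test_that("tau and TSPS match brute-force evaluation on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    genes <- paste0("g", 1:10)
    meta <- tibble::tibble(sample = paste0("s", 1:10),
                           tissue = rep(paste0("t", 1:5), each = 2))
    m <- make_panel(rpois(100, 20) * rbinom(100, 1, 0.8), genes, meta$sample)
    tau <- compute_tau(m, meta)
    tsps <- compute_tsps(m, meta)
    for (g in genes) {
      prof <- vapply(unique(meta$tissue), function(t) {
        mean(log2(as.numeric(m[g, meta$sample[meta$tissue == t]]) + 1))
      }, numeric(1))
      want_tau <- if (max(prof) > 0) sum(1 - prof / max(prof)) / (length(prof) - 1)
                  else NA_real_
      expect_equal(tau$tau[tau$gene_id == g], want_tau, tolerance = 1e-12)

      lin <- vapply(unique(meta$tissue), function(t) {
        mean(as.numeric(m[g, meta$sample[meta$tissue == t]]))
      }, numeric(1))
      want_tsps <- if (sum(lin) > 0) {
        p <- lin / sum(lin)
        sum(ifelse(p > 0, p * log2(p * length(p)), 0))
      } else NA_real_
      expect_equal(tsps$tsps[tsps$gene_id == g], want_tsps, tolerance = 1e-12)
    }
  }
})

test_that("CTSP fraction and membership follow the detection threshold", {
  m <- tiny_counts(c(1, 0, 1,  1, 0, 1,  0, 0, 1,  0, 0, 2,  0, 1, 1,  0, 0, 3),
                   paste0("c", 1:6), c("gA", "gB", "gC"))
  # gA detected in 2/6 cells = 0.333...: member at threshold 1/3
  ct <- compute_ctsp(m, fraction = 1 / 3)
  expect_true(ct$ctsp[ct$gene_id == "gA"])
  expect_equal(ct$ctsp_fraction[ct$gene_id == "gA"], 2 / 6)
  # gB detected in 1/6: non-member; gC in all cells: fraction 1
  expect_false(ct$ctsp[ct$gene_id == "gB"])
  expect_equal(ct$ctsp_fraction[ct$gene_id == "gC"], 1)
  expect_true(ct$ctsp[ct$gene_id == "gC"])
  # invariant to cell order
  ct2 <- compute_ctsp(m[sample(6), ], fraction = 1 / 3)
  expect_equal(dplyr::arrange(ct, gene_id), dplyr::arrange(ct2, gene_id))
  expect_error(compute_ctsp(m, fraction = 0), "fraction")
})

test_that("specificity table flags are consistent with the thresholds", {
  cfg <- two_type_config(n_each = 60, seed = 15)
  sim <- generate_cells(cfg)
  panel <- generate_bulk_panel(cfg, n_tissues = 4, n_reps = 2, seed = 3)
  tpm <- normalize_counts(panel$counts, "length_tpm",
                          lengths = setNames(panel$annotation$length,
                                             panel$annotation$gene_id),
                          margin = 2)
  st <- specificity_table(sim$counts, tpm, panel$samples)
  expect_true(all(st$tau[st$set_tau] <= 0.5, na.rm = TRUE))
  expect_true(all(st$tsps[st$set_tsps] <= 1, na.rm = TRUE))
  expect_true(all(st$ctsp_fraction[st$set_ctsp] >= 1 / 3))
  expect_true(all(st$set_ctsp == (st$expressed & st$ctsp)))
})

test_that("concordance rubric scores exact, lagged, lineage and disjoint patterns", {
  lin <- lineage_map()
  score <- function(biased, high, curated) {
    concordance_score(
      tibble::tibble(gene_id = "g", biased_types = list(biased),
                     high_types = list(high)),
      tibble::tibble(gene_id = "g", domains = list(curated)), lin)$score
  }
  expect_equal(score("G", character(0), "G"), 4L)         # exact match
  expect_equal(score("E1", character(0), "L1"), 4L)       # protein lags in chain
  expect_equal(score("C1", character(0), "T"), 0L)        # disjoint lineages
  expect_equal(score(character(0), "M1", "M1"), 3L)       # high, exact types
  expect_equal(score("C2", character(0), "C4"), 4L)       # later in cyst chain
  expect_equal(score("L1", character(0), "G"), 2L)        # same lineage, earlier
  expect_equal(score(character(0), "C1", "C3"), 1L)       # high, same lineage
  expect_equal(score(character(0), character(0), "P"), 0L)
  expect_error(score("Q9", character(0), "G"), "unknown cell type")
})
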