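test_that("Mann-Whitney U: hand values, symmetry, degenerate ties", {
  r <- mwu(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")

  same <- mwu(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)

  x <- c(3, 9, 1, 7); y <- c(2, 8, 4)
  a <- mwu(x, y); b <- mwu(y, x)
  expect_equal(a$u, length(x) * length(y) - b$u)
  expect_equal(a$p_value, b$p_value)
  expect_error(mwu(numeric(0), 1), "non-empty")
})

test_that("exact-path p equals brute-force enumeration for n <= 6 per group", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)  # no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mwu(x, y)$p_value, mwu_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("pairwise permutation test: extreme separation, add-one floor, errors", {
  tab <- tibble::tibble(barcode = paste0("c", 1:40),
                        ratio = c(rnorm(20, 10), rnorm(20, 0)), valid = TRUE)
  labs <- tibble::tibble(barcode = tab$barcode, type = rep(c("a", "b"), each = 20))
  res <- pairwise_permutation_test(tab, labs, "a", "b", n_iter = 999, seed = 7)
  expect_equal(res$u, 400)  # complete separation
  expect_equal(res$p_perm, 1 / 1000)
  expect_gte(res$p_perm, 1 / (res$n_iter + 1))
  expect_error(pairwise_permutation_test(tab, labs, "a", "a"), "distinct")

  # label-independent values: permutation p is not extreme
  tab0 <- tibble::tibble(barcode = paste0("c", 1:60), ratio = rnorm(60),
                         valid = TRUE)
  labs0 <- tibble::tibble(barcode = tab0$barcode, type = rep(c("a", "b"), 30))
  res0 <- pairwise_permutation_test(tab0, labs0, "a", "b", n_iter = 499, seed = 1)
  expect_gt(res0$p_perm, 0.01)
})

test_that("permutation p is reproducible given the seed", {
  tab <- tibble::tibble(barcode = paste0("c", 1:30), ratio = rnorm(30), valid = TRUE)
  labs <- tibble::tibble(barcode = tab$barcode, type = rep(c("a", "b"), 15))
  p1 <- pairwise_permutation_test(tab, labs, "a", "b", n_iter = 200, seed = 5)$p_perm
  p2 <- pairwise_permutation_test(tab, labs, "a", "b", n_iter = 200, seed = 5)$p_perm
  expect_identical(p1, p2)
})

test_that("mean-comparison test: null type blends in, shifted type stands out", {
  set.seed(41)
  n <- 600
  vals <- rnorm(n)
  tab <- tibble::tibble(barcode = paste0("c", seq_len(n)), ratio = vals,
                        valid = TRUE)
  labs <- tibble::tibble(barcode = tab$barcode,
                         type = rep(c("t", "rest"), c(200, n - 200)))
  null_res <- mean_permutation_test(tab, labs, "t", n_iter = 400, seed = 2)
  expect_lte(null_res$significant_fraction, 0.05)
  expect_false(null_res$different)

  tab2 <- tab
  tab2$ratio[1:200] <- tab2$ratio[1:200] + 3  # 3 pooled SDs
  shift_res <- mean_permutation_test(tab2, labs, "t", n_iter = 400, seed = 2)
  expect_gte(shift_res$significant_fraction, 0.95)
  expect_true(shift_res$different)

  expect_error(mean_permutation_test(tab, labs, "t", n_iter = 0), "n_iter")
  labs_all <- tibble::tibble(barcode = tab$barcode, type = "t")
  expect_error(mean_permutation_test(tab, labs_all, "t"), "smaller")
})

test_that("BH correction: hand cases and the step-up oracle", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(51)
  for (rep in 1:20) {
    p <- round(runif(sample(1:20, 1)), 3)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("chi-squared independence: null table, hand value, degenerate input", {
  flat <- chi2_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  r <- chi2_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)

  # identical class proportions across elements: statistic 0
  prop <- chi2_independence(matrix(c(10, 20, 30, 5, 10, 15), ncol = 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)

  expect_error(chi2_independence(matrix(c(5, 5, 0, 0), 2)), "expected")
})

test_that("bootstrap CI of the mean: degenerate input, reproducibility, coverage", {
  const <- bootstrap_ci_mean(rep(3, 10), n_boot = 200, seed = 1)
  expect_equal(const$ci_lo, 3)
  expect_equal(const$ci_hi, 3)
  expect_error(bootstrap_ci_mean(1:10, level = 1), "level")
  expect_error(bootstrap_ci_mean(5), "2 values")

  # reproducibility for the same data and seed
  x <- withr::with_seed(4, rnorm(30))
  expect_identical(bootstrap_ci_mean(x, n_boot = 100, seed = 9),
                   bootstrap_ci_mean(x, n_boot = 100, seed = 9))

  # coverage of the true mean for standard normal samples (n = 100)
  set.seed(61)
  hits <- vapply(seq_len(1000), function(i) {
    ci <- bootstrap_ci_mean(rnorm(100), n_boot = 1000, seed = i)
    ci$ci_lo <= 0 && 0 <= ci$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.97)
})

test_that("arm sex bias: identical panels are quiet, a halved male X is flagged", {
  cfg <- sim_config(seed = 33)
  ann <- generate_annotation(cfg)
  lengths <- setNames(ann$length, ann$gene_id)

  pan <- generate_bulk_panel(cfg, n_tissues = 2, n_reps = 4, seed = 8,
                             male_element_factor = c(X = 0.5),
                             sex_biased_fraction = 0)
  g1 <- pan$samples$sample[pan$samples$tissue == "tissue01"]
  tpm <- normalize_counts(pan$counts[, g1], "length_tpm", lengths = lengths,
                          margin = 2)
  meta <- pan$samples[pan$samples$tissue == "tissue01", ]
  expressed <- rownames(tpm)[Matrix::rowSums(tpm > 0) >= 2]
  bias <- arm_sex_bias(tpm, ann, meta, expressed, seed = 3)
  expect_true(bias$male_reduced[bias$element == "X"])
  majors <- bias$element %in% c("2L", "2R", "3L", "3R")
  expect_false(any(bias$male_reduced[majors]))
  expect_true(all(bias$female_ci_lo <= bias$mean_female &
                    bias$mean_female <= bias$female_ci_hi))

  # identical replicate panels for both sexes: nothing can be flagged
  m <- pan$counts[, g1[1:4]]
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:8)
  meta2 <- tibble::tibble(sample = colnames(dup),
                          sex = rep(c("female", "male"), each = 4))
  tpm2 <- normalize_counts(dup, "length_tpm", lengths = lengths, margin = 2)
  bias2 <- arm_sex_bias(tpm2, ann, meta2, expressed, seed = 3)
  expect_false(any(bias2$male_reduced))

  meta1 <- meta[c(1, 5), ]
  expect_error(arm_sex_bias(tpm[, meta1$sample], ann, meta1, expressed),
               "2 replicates")
})

test_that("sex-bias class tables conserve counts and expose non-random placement", {
  ann <- tibble::tibble(gene_id = paste0("g", 1:300),
                        element = rep(c("X", "2L", "2R"), each = 100))
  set.seed(71)
  class <- c(sample(c("male", "unbiased"), 100, TRUE, prob = c(0.02, 0.98)),
             sample(c("male", "unbiased"), 200, TRUE, prob = c(0.35, 0.65)))
  de <- tibble::tibble(gene_id = ann$gene_id, class = class)
  tab <- sex_bias_classes(de, ann)
  expect_equal(sum(tab), 300)
  expect_lte(chi2_independence(tab)$p_value, 0.01)  # X depleted of male bias

  expect_error(sex_bias_classes(tibble::tibble(gene_id = "g1", class = "both"),
                                ann), "unknown sex-bias class")
  # all genes unbiased: single informative class, chi-squared degenerates
  de0 <- tibble::tibble(gene_id = ann$gene_id, class = "unbiased")
  tab0 <- sex_bias_classes(de0, ann)
  expect_error(chi2_independence(tab0), "degenerate")
})
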