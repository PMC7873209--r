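test_that("annotation has one record per configured gene, unique ids, positive lengths", {
  cfg <- sim_config(seed = 1)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 1242)  # sum of default element gene counts
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$length > 0))
  expect_equal(sort(unique(ann$element)), sort(default_elements()$element))
})

test_that("invalid configurations are rejected", {
  el <- default_elements()
  el$n_genes[1] <- 0L
  expect_error(sim_config(elements = el), "positive gene count")
  el2 <- default_elements()
  el2$element[2] <- "X"
  expect_error(sim_config(elements = el2), "duplicate element")
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  dos <- default_dosage()
  dos$element[1] <- "5L"
  expect_error(sim_config(dosage = dos), "unknown element")
})

test_that("generation is deterministic given the config", {
  cfg <- two_type_config(n_each = 60, seed = 11)
  s1 <- generate_cells(cfg)
  s2 <- generate_cells(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$truth$cells, s2$truth$cells)
})

test_that("expected ratios follow copies x multiplier over the autosomal reference", {
  cfg <- sim_config(seed = 1)
  er <- expected_ratios(cfg)
  # X with per-copy multiplier 2 on one copy vs two autosomal copies: 1.0
  expect_equal(er$expected_ratio[er$element == "X" & er$type == "C1"], 1.0)
  # X with multiplier 1 in late spermatocytes: 0.5
  expect_equal(er$expected_ratio[er$element == "X" & er$type == "L1"], 0.5)
  expect_equal(er$expected_ratio[er$element == "4" & er$type == "M1"], 0.85)
  expect_equal(er$expected_ratio[er$element == "2L" & er$type == "G"], 1.0)
})

test_that("counts are non-negative integers and Poisson mode works", {
  cfg <- two_type_config(n_each = 30, seed = 2, dispersion = Inf)
  sim <- generate_cells(cfg)
  x <- sim$counts@x
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
})

test_that("doublet injection appends the right number with summed depths and exact flags", {
  cfg <- two_type_config(n_each = 500, seed = 4)
  sim <- generate_cells(cfg)
  inj <- inject_doublets(sim$counts, sim$truth, rate = 0.05, seed = 9)
  expect_equal(nrow(inj$counts), 1050)
  tr <- inj$truth$cells
  doub <- tr[tr$doublet, ]
  expect_equal(nrow(doub), 50)
  # heterotypic flag is exactly (constituent types differ)
  expect_identical(doub$heterotypic, doub$type_a != doub$type_b)
  # a doublet's count vector is the sum of its two constituent cells
  for (i in head(seq_len(nrow(doub)), 5)) {
    expect_equal(
      as.numeric(inj$counts[doub$barcode[i], ]),
      as.numeric(sim$counts[doub$barcode_a[i], ] + sim$counts[doub$barcode_b[i], ])
    )
  }
  # injection is reproducible given the seed
  inj2 <- inject_doublets(sim$counts, sim$truth, rate = 0.05, seed = 9)
  expect_identical(as.matrix(inj$counts), as.matrix(inj2$counts))
  # rate 0 leaves the matrix unchanged
  un <- inject_doublets(sim$counts, sim$truth, rate = 0, seed = 9)
  expect_identical(dim(un$counts), dim(sim$counts))
  expect_error(inject_doublets(sim$counts, sim$truth, rate = 1), "rate")
})

test_that("doublet count vectors are sums of two real cells", {
  cfg <- two_type_config(n_each = 40, seed = 6)
  sim <- generate_cells(cfg)
  inj <- inject_doublets(sim$counts, sim$truth, rate = 0.1, seed = 2,
                         kind = "heterotypic")
  tr <- inj$truth$cells
  d <- tr[tr$doublet, ]
  expect_true(all(d$heterotypic))
  # depth additivity: doublet libsize column records d1 + d2
  singles <- tr[!tr$doublet, ]
  tot <- Matrix::rowSums(inj$counts)
  # every doublet's UMI total must exceed the smaller constituent-type median
  expect_true(all(tot[d$barcode] > min(tot[singles$barcode])))
})

test_that("downstream median ratios recover the configured dosage (parameter recovery)", {
  ct <- tibble::tibble(type = c("S", "L"), lineage = c("soma", "germline"),
                       n_cells = c(1000L, 1000L))
  dos <- tidyr::expand_grid(element = default_elements()$element,
                            type = c("S", "L"), multiplier = 1)
  dos$multiplier[dos$element == "X" & dos$type == "S"] <- 2
  dos$multiplier[dos$element == "4" & dos$type == "L"] <- 0.85
  cfg <- sim_config(cell_types = ct, dosage = dos, seed = 8)
  sim <- generate_cells(cfg)
  norm <- normalize_counts(sim$counts, "cpm")
  ex <- expressed_genes(sim$counts)
  gene_set <- ex$gene_id[ex$expressed]
  truth <- sim$truth$expected_ratio

  for (focal in c("X", "4")) {
    rt <- chromosome_ratio(norm, sim$annotation, gene_set, focal = focal)
    med <- summarize_by_type(rt, sim$truth$cells[, c("barcode", "type")])
    for (tp in c("S", "L")) {
      want <- truth$expected_ratio[truth$element == focal & truth$type == tp]
      got <- med$median[med$type == tp]
      expect_lt(abs(got - want), 0.1)
    }
  }
})

test_that("bulk panel: broad genes everywhere, restricted genes concentrated, reproducible", {
  cfg <- sim_config(seed = 5)
  p1 <- generate_bulk_panel(cfg, n_tissues = 4, n_reps = 2, seed = 7)
  p2 <- generate_bulk_panel(cfg, n_tissues = 4, n_reps = 2, seed = 7)
  expect_identical(p1$counts, p2$counts)
  expect_error(generate_bulk_panel(cfg, n_tissues = 1, n_reps = 2), "n_tissues")
  expect_error(generate_bulk_panel(cfg, n_tissues = 4, n_reps = 1), "n_reps")

  tpm <- normalize_counts(p1$counts, "length_tpm",
                          lengths = setNames(p1$annotation$length,
                                             p1$annotation$gene_id),
                          margin = 2)
  tm <- vapply(unique(p1$samples$tissue), function(t) {
    Matrix::rowMeans(tpm[, p1$samples$sample[p1$samples$tissue == t], drop = FALSE])
  }, numeric(nrow(tpm)))
  broad <- p1$genes$broad
  # broad genes: nonzero mean in every tissue
  expect_true(all(tm[broad, ] > 0))
  # restricted genes active in exactly one tissue: zero-ish elsewhere
  one_tissue <- vapply(p1$genes$active_tissues, length, integer(1)) == 1
  expect_gt(sum(one_tissue), 0)
})
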