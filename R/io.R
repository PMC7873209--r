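#' Read a UMI count matrix from a 10x-style directory or a TSV table
#'
#' Directories must contain a MatrixMarket triplet — `matrix.mtx`,
#' `barcodes.tsv` and either `features.tsv` (v3 dialect) or `genes.tsv`
#' (v2) — each optionally gzip-compressed. On disk the matrix is genes x
#' cells; the returned matrix is cells x genes. A TSV path is read as a
#' gene x sample table (first column = gene ids) and returned genes x
#' samples.
#'
#' @param path Directory with the MatrixMarket triplet, or a TSV file.
#' @return A sparse `dgCMatrix` with ids as dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    find1 <- function(stem) {
      for (f in file.path(path, c(stem, paste0(stem, ".gz")))) {
        if (file.exists(f)) return(f)
      }
      NULL
    }
    mtx <- find1("matrix.mtx")
    bc <- find1("barcodes.tsv")
    ft <- find1("features.tsv") %||% find1("genes.tsv")
    if (is.null(mtx) || is.null(bc) || is.null(ft)) {
      abort("directory must contain matrix.mtx, barcodes.tsv and features.tsv/genes.tsv (optionally .gz).")
    }
    open_maybe_gz <- function(f) if (grepl("\\.gz$", f)) gzfile(f) else f
    # readMM may return a symmetric class (dsTMatrix) for numerically
    # symmetric matrices, which would force symmetric dimnames
    m <- as(Matrix::readMM(open_maybe_gz(mtx)), "generalMatrix")
    read_first_col <- function(f) {
      lines <- readLines(f)  # file() auto-detects gzip
      vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
    }
    barcodes <- read_first_col(bc)
    feats <- read_first_col(ft)
    if (nrow(m) != length(feats)) {
      abort(sprintf("matrix declares %d genes but features file has %d lines.",
                    nrow(m), length(feats)))
    }
    if (ncol(m) != length(barcodes)) {
      abort(sprintf("matrix declares %d cells but barcodes file has %d lines.",
                    ncol(m), length(barcodes)))
    }
    dimnames(m) <- list(feats, barcodes)
    counts <- Matrix::t(as(m, "CsparseMatrix"))
    assert_counts(counts, integer = TRUE)
  } else if (file.exists(path)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ids <- tab[[1]]
    if (anyDuplicated(ids)) abort("duplicate gene ids in TSV count table.")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    counts <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    assert_counts(counts, integer = TRUE)
  } else {
    abort(sprintf("path '%s' does not exist.", path))
  }
}

#' Write a count matrix as a 10x-style MatrixMarket triplet directory
#'
#' @param counts Sparse cells x genes matrix (the on-disk matrix is
#'   transposed to genes x cells, the 10x convention).
#' @param path Output directory (created if needed).
#' @param dialect `"v3"` writes `features.tsv` (three columns), `"v2"`
#'   writes `genes.tsv` (two columns).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, dialect = c("v3", "v2")) {
  dialect <- match.arg(dialect)
  counts <- assert_counts(counts)
  ids <- c(rownames(counts), colnames(counts))
  if (any(grepl("\t", ids))) abort("ids must not contain tab characters.")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    abort(sprintf("cannot create directory '%s'.", path))
  }
  Matrix::writeMM(Matrix::t(counts), file.path(path, "matrix.mtx"))
  writeLines(rownames(counts) %||% character(0), file.path(path, "barcodes.tsv"))
  genes <- colnames(counts) %||% character(0)
  if (dialect == "v3") {
    readr::write_tsv(tibble(id = genes, name = genes, type = "Gene Expression"),
                     file.path(path, "features.tsv"), col_names = FALSE)
  } else {
    readr::write_tsv(tibble(id = genes, name = genes),
                     file.path(path, "genes.tsv"), col_names = FALSE)
  }
  invisible(path)
}

#' Read a gene-to-chromosome-element annotation table
#'
#' Expects a TSV with columns `gene_id` and `element`, optionally `length`
#' (bp) and `domains` (comma-separated curated expression cell types).
#' Elements outside `known` are mapped to `"other"` with a warning.
#'
#' @param path TSV file (optionally gzipped).
#' @param known Recognized element names.
#' @return A tibble with one record per gene.
#' @export
read_gene_map <- function(path,
                          known = c("X", "Y", "2L", "2R", "3L", "3R", "4")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "element") %in% names(tab))) {
    abort("gene map must have columns `gene_id` and `element`.")
  }
  if (anyDuplicated(tab$gene_id)) abort("duplicate gene ids in gene map.")
  unknown <- setdiff(unique(tab$element), c(known, "other"))
  if (length(unknown)) {
    warn(paste0("unknown element(s) mapped to 'other': ",
                paste(unknown, collapse = ", ")))
    tab$element[tab$element %in% unknown] <- "other"
  }
  if ("length" %in% names(tab) && any(!is.na(tab$length) & tab$length <= 0)) {
    abort("gene lengths must be positive.")
  }
  if ("domains" %in% names(tab)) {
    tab$domains <- lapply(strsplit(tab$domains, ","), trimws)
  }
  as_tibble(tab)
}

#' Depth-normalize a count matrix (counts-per-million or length TPM)
#'
#' `cpm` scales every cell (or sample) to a total of 10^6 — the appropriate
#' "TPM" for 3' UMI data, where counts are not length-proportional.
#' `length_tpm` divides counts by gene length in kb before scaling, the
#' standard transcripts-per-million for full-length bulk libraries. Cells
#' with zero total are left at zero with a warning.
#'
#' @param counts Matrix; units along `margin` are normalized.
#' @param mode `"cpm"` or `"length_tpm"`.
#' @param lengths Named vector of gene lengths (bp), required for
#'   `length_tpm`; names must cover all genes.
#' @param margin 1 if units (cells/samples) are rows, 2 if columns.
#'   Single-cell matrices in this package are cells x genes (`margin = 1`);
#'   bulk tables are genes x samples (`margin = 2`).
#' @return A real-valued matrix of the same shape and class.
#' @export
normalize_counts <- function(counts, mode = c("cpm", "length_tpm"),
                             lengths = NULL, margin = 1) {
  mode <- match.arg(mode)
  counts <- assert_counts(counts)
  genes <- if (margin == 1) colnames(counts) else rownames(counts)
  if (mode == "length_tpm") {
    if (is.null(lengths)) abort("`length_tpm` requires gene `lengths`.")
    if (!all(genes %in% names(lengths))) {
      abort("`lengths` must cover every gene in the matrix.")
    }
    kb <- lengths[genes] / 1000
    counts <- if (margin == 1) {
      counts %*% Matrix::Diagonal(x = 1 / kb)
    } else {
      Matrix::Diagonal(x = 1 / kb) %*% counts
    }
    dimnames(counts) <- if (margin == 1) list(rownames(counts), genes) else list(genes, colnames(counts))
  }
  tot <- if (margin == 1) Matrix::rowSums(counts) else Matrix::colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("%d unit(s) have zero total; their normalized values are 0.",
                 sum(zero)))
    tot[zero] <- 1
  }
  scl <- Matrix::Diagonal(x = 1e6 / tot)
  out <- if (margin == 1) scl %*% counts else counts %*% scl
  dimnames(out) <- dimnames(counts)
  as(out, "CsparseMatrix")
}

#' Spearman correlation between pseudobulk and bulk profiles
#'
#' Sums single-cell UMI counts over all cells, normalizes both the
#' pseudobulk and every bulk sample as log10(per-million + 1), and returns
#' the Spearman rank correlation on the shared gene set.
#'
#' @param sc Sparse cells x genes count matrix.
#' @param bulk Genes x samples count matrix (or a named gene vector).
#' @return A tibble with columns `sample` and `rho`.
#' @export
pseudobulk_correlation <- function(sc, bulk) {
  sc <- assert_counts(sc)
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                         dimnames = list(names(bulk), "bulk"))
  pseudo <- Matrix::colSums(sc)
  shared <- intersect(names(pseudo), rownames(bulk))
  if (length(shared) < 10) abort("fewer than 10 shared genes between sc and bulk.")
  lt <- function(x) log10(rescale_to(x, 1e6) + 1)
  ps <- lt(pseudo[shared])
  tibble(
    sample = colnames(bulk),
    rho = vapply(seq_len(ncol(bulk)), function(j) {
      cor(ps, lt(bulk[shared, j]), method = "spearman")
    }, numeric(1))
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the 10x-style MatrixMarket triplet, the gene annotation and truth
#' tables as TSV, and the key generator parameters (including the seed) as
#' a plain-text key-value metadata file.
#'
#' @param sim Output of [generate_cells()].
#' @param path Output directory.
#' @param config The [sim_config()] used (recorded in the metadata file).
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path, config = NULL) {
  write_counts(sim$counts, path)
  readr::write_tsv(sim$annotation, file.path(path, "gene_map.tsv"))
  readr::write_tsv(sim$truth$cells, file.path(path, "truth_cells.tsv"))
  genes <- sim$truth$genes
  genes$active_types <- vapply(genes$active_types, paste, character(1), collapse = ",")
  readr::write_tsv(genes, file.path(path, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$expected_ratio, file.path(path, "truth_ratios.tsv"))
  if (!is.null(config)) {
    meta <- c(
      sprintf("seed\t%d", config$seed),
      sprintf("dispersion\t%s", format(config$dispersion)),
      sprintf("doublet_rate\t%s", format(config$doublet_rate)),
      sprintf("n_cells\t%d", sum(config$cell_types$n_cells)),
      sprintf("n_genes\t%d", sum(config$elements$n_genes)),
      "normalization\tcpm (UMI counts are not length-proportional)"
    )
    writeLines(meta, file.path(path, "metadata.tsv"))
  }
  invisible(path)
}
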