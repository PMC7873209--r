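#' Default chromosome-element layout of a male Drosophila genome
#'
#' Seven chromosome elements with configurable gene content and male copy
#' number: one X, one Y, two copies of each major autosomal arm (2L, 2R, 3L,
#' 3R) and two copies of the dot 4th chromosome. Gene counts are a reduced,
#' simulation-scale rendering of the real arms (gene-rich majors, gene-poor
#' Y and 4th).
#'
#' @return A tibble with columns `element`, `n_genes`, `copies`.
#' @export
default_elements <- function() {
  tibble(
    element = c("X", "Y", "2L", "2R", "3L", "3R", "4"),
    n_genes = c(200L, 12L, 250L, 250L, 250L, 250L, 30L),
    copies  = c(1L, 1L, 2L, 2L, 2L, 2L, 2L)
  )
}

#' Default cell-type composition of the simulated larval testis
#'
#' Ten cell types: the germline differentiation series (spermatogonia `G`,
#' early/middle/late primary spermatocytes `E1`, `M1`, `L1`) and six somatic
#' types (cyst lineage `C1`-`C4`, terminal epithelium `T`, pigment cells
#' `P`). Default cell numbers preserve the relative abundances of the ten
#' cell types recovered in the larval testis atlas, scaled to 8,000 cells.
#'
#' @return A tibble with columns `type`, `lineage` (`"germline"` or
#'   `"soma"`), `n_cells`.
#' @export
default_cell_types <- function() {
  tibble(
    type    = c("G", "E1", "M1", "L1", "C1", "C2", "C3", "C4", "T", "P"),
    lineage = c(rep("germline", 4), rep("soma", 6)),
    n_cells = c(449L, 534L, 1928L, 1125L, 1714L, 519L, 384L, 399L, 582L, 366L)
  )
}

#' Default per-copy dosage regimes
#'
#' Per-copy rate multipliers m(element, type). The defaults encode the
#' qualitative biology the simulator is meant to emulate:
#' * X is fully dosage compensated (m = 2 on the single X) in all somatic
#'   types and in spermatogonia, with compensation decaying through the
#'   primary spermatocyte series (1.4, 1.1, 1.0 in E1/M1/L1), so the
#'   expected X:A ratio falls from 1.0 to 0.5;
#' * the 4th behaves autosomally (m = 1) except for a mild spermatocyte
#'   repression (0.85 in M1/L1);
#' * Y is near-silent in soma (0.05), weakly active in spermatogonia (0.3)
#'   and fully active in spermatocytes (1.0);
#' * major autosomal arms are fixed at m = 1 everywhere (the reference).
#'
#' @return A tibble with columns `element`, `type`, `multiplier`.
#' @export
default_dosage <- function() {
  types <- default_cell_types()$type
  soma  <- c("C1", "C2", "C3", "C4", "T", "P")
  m <- expand.grid(element = default_elements()$element, type = types,
                   stringsAsFactors = FALSE)
  m <- as_tibble(m)
  m$multiplier <- 1
  m$multiplier[m$element == "X" & m$type %in% c(soma, "G")] <- 2.0
  m$multiplier[m$element == "X" & m$type == "E1"] <- 1.4
  m$multiplier[m$element == "X" & m$type == "M1"] <- 1.1
  m$multiplier[m$element == "X" & m$type == "L1"] <- 1.0
  m$multiplier[m$element == "4" & m$type %in% c("M1", "L1")] <- 0.85
  m$multiplier[m$element == "Y" & m$type %in% soma] <- 0.05
  m$multiplier[m$element == "Y" & m$type == "G"] <- 0.3
  m$multiplier[m$element == "Y" & m$type %in% c("E1", "M1", "L1")] <- 1.0
  m
}

#' Configure the synthetic testis dataset
#'
#' Bundles every parameter of the generative model: the chromosome-element
#' layout, the cell-type composition, the per-copy dosage regimes, the
#' log-normal gene base-rate and library-size distributions, the breadth
#' structure (broad vs restricted genes, per-type markers), count
#' overdispersion, the doublet rate and the seed.
#'
#' The generative model for a cell of type t: gene g has base rate
#' lambda_g ~ LogNormal(mu0, sigma0); its activity in t is 1 for broad
#' genes, a marker boost for t-exclusive markers, 1 for restricted genes
#' active in t, 0 otherwise. The per-gene rate is
#' lambda_g x activity x copies(e) x m(e, t), standardized to mean 1 within
#' each (element, breadth class, type) stratum so the configured dosage
#' multipliers are the only systematic driver of element-level ratios.
#' Rates are normalized within the cell and scaled by a log-normal library
#' size L_c; counts are negative binomial (`dispersion = Inf` gives
#' Poisson).
#'
#' @param elements Tibble as [default_elements()]: `element`, `n_genes`,
#'   `copies` (copies in 0, 1, 2).
#' @param cell_types Tibble as [default_cell_types()]: `type`, `lineage`,
#'   `n_cells`.
#' @param dosage Tibble as [default_dosage()]: `element`, `type`,
#'   `multiplier` (per-copy rate multiplier, >= 0).
#' @param gene_rate_meanlog,gene_rate_sdlog Log-normal parameters of the
#'   per-gene base rate lambda_g.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the
#'   per-cell library size (UMI); defaults give a median of 5,000 UMI.
#' @param broad_fraction Named numeric: fraction of each element's genes
#'   expressed in every cell type. Defaults: 30% for each autosomal arm and
#'   the 4th, 25% for X, 0% for Y (the Y carries no widely expressed genes).
#' @param marker_single_fraction Fraction of non-broad genes restricted to a
#'   single cell type and boosted as markers (the rest are active in two
#'   types). The default of 1 keeps every restricted gene below the CTSP
#'   detection bar by construction: no single cell type holds a third of the
#'   cells, so the widely-expressed set is exactly the broad-gene class.
#' @param marker_boost_meanlog,marker_boost_sdlog Log-normal fold boost for
#'   marker genes in their own type.
#' @param dispersion Negative-binomial size parameter; `Inf` means Poisson.
#' @param doublet_rate Fraction of doublet barcodes appended by
#'   [generate_cells()] (in \[0, 1)).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene lengths (bp)
#'   used for bulk length-normalized TPM.
#' @param seed Integer seed; all generator output is reproducible given the
#'   config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' sum(cfg$elements$n_genes)  # 1242 genes
sim_config <- function(elements = default_elements(),
                       cell_types = default_cell_types(),
                       dosage = default_dosage(),
                       gene_rate_meanlog = 0,
                       gene_rate_sdlog = 1,
                       libsize_meanlog = log(5000),
                       libsize_sdlog = 0.3,
                       broad_fraction = c(X = 0.25, Y = 0, `2L` = 0.3, `2R` = 0.3,
                                          `3L` = 0.3, `3R` = 0.3, `4` = 0.3),
                       marker_single_fraction = 1,
                       marker_boost_meanlog = log(4),
                       marker_boost_sdlog = 0.25,
                       dispersion = 10,
                       doublet_rate = 0,
                       gene_length_meanlog = log(2000),
                       gene_length_sdlog = 0.5,
                       seed = 1L) {
  elements <- as_tibble(elements)
  cell_types <- as_tibble(cell_types)
  dosage <- as_tibble(dosage)

  if (anyDuplicated(elements$element)) abort("duplicate element names in config.")
  if (any(elements$n_genes <= 0)) abort("every element must have a positive gene count.")
  if (!all(elements$copies %in% 0:2)) abort("copy numbers must be 0, 1 or 2.")
  if (anyDuplicated(cell_types$type)) abort("cell-type names must be unique.")
  if (any(cell_types$n_cells < 0)) abort("cell numbers must be non-negative.")
  if (!all(cell_types$lineage %in% c("germline", "soma"))) {
    abort("lineage must be 'germline' or 'soma'.")
  }
  if (any(dosage$multiplier < 0)) abort("dosage multipliers must be >= 0.")
  unknown <- setdiff(unique(dosage$element), elements$element)
  if (length(unknown)) {
    abort(paste0("dosage map names unknown element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  unknown_t <- setdiff(unique(dosage$type), cell_types$type)
  if (length(unknown_t)) {
    abort(paste0("dosage map names unknown cell type(s): ",
                 paste(unknown_t, collapse = ", ")))
  }
  if (doublet_rate < 0 || doublet_rate >= 1) abort("doublet_rate must be in [0, 1).")
  missing_bf <- setdiff(elements$element, names(broad_fraction))
  if (length(missing_bf)) {
    abort(paste0("broad_fraction missing element(s): ",
                 paste(missing_bf, collapse = ", ")))
  }
  if (any(broad_fraction < 0 | broad_fraction > 1)) {
    abort("broad_fraction values must lie in [0, 1].")
  }
  if (dispersion <= 0) abort("dispersion must be positive (Inf for Poisson).")

  structure(
    list(
      elements = elements, cell_types = cell_types, dosage = dosage,
      gene_rate_meanlog = gene_rate_meanlog, gene_rate_sdlog = gene_rate_sdlog,
      libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
      broad_fraction = broad_fraction,
      marker_single_fraction = marker_single_fraction,
      marker_boost_meanlog = marker_boost_meanlog,
      marker_boost_sdlog = marker_boost_sdlog,
      dispersion = dispersion, doublet_rate = doublet_rate,
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  elements: ", paste0(x$elements$element, "(", x$elements$n_genes, ")",
                             collapse = " "), "\n")
  cat("  cells:    ", sum(x$cell_types$n_cells), "in",
      nrow(x$cell_types), "types\n")
  cat("  dispersion:", x$dispersion, " doublet_rate:", x$doublet_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Expected element:autosome expression ratios implied by a configuration
#'
#' The simulation truth: for element e in cell type t the expected per-cell
#' gene-count-normalized ratio against the major autosomes is
#' (copies_e x m(e,t)) / (copies_A x m(A,t)), with the major-autosome
#' per-copy multiplier fixed at 1 and copies_A = 2.
#'
#' @param config A [sim_config()].
#' @param majors Elements forming the autosomal reference.
#' @return A tibble with columns `element`, `type`, `expected_ratio`.
#' @export
expected_ratios <- function(config, majors = c("2L", "2R", "3L", "3R")) {
  stopifnot(inherits(config, "sim_config"))
  el <- config$elements
  d <- config$dosage
  d$copies <- el$copies[match(d$element, el$element)]
  ref <- d %>%
    filter(.data$element %in% majors) %>%
    group_by(.data$type) %>%
    summarise(ref = mean(.data$copies * .data$multiplier), .groups = "drop")
  d %>%
    left_join(ref, by = "type") %>%
    mutate(expected_ratio = .data$copies * .data$multiplier / .data$ref) %>%
    select("element", "type", "expected_ratio")
}
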