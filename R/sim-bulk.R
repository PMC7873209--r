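#' Generate a multi-tissue, two-sex bulk expression panel
#'
#' Emulates an adult tissue panel at reduced scale: broad genes are
#' expressed at similar levels in every tissue, restricted genes are
#' concentrated in one or two tissues, a designated fraction of genes
#' carries sex-biased fold changes, and optional per-element male
#' multipliers (e.g. a halved male X) can be imposed. Counts are negative
#' binomial with read rates proportional to expression times gene length,
#' so length-normalized TPM ([normalize_counts()] with `mode =
#' "length_tpm"`) recovers the underlying expression.
#'
#' @param config A [sim_config()] (supplies the gene/element layout and
#'   base-rate distribution).
#' @param n_tissues Number of tissues (>= 2).
#' @param n_reps Replicates per tissue and sex (>= 2).
#' @param seed Integer seed.
#' @param male_element_factor Optional named numeric; multiplies the male
#'   expression of every gene on the named elements (e.g. `c(X = 0.5)`).
#' @param sex_biased_fraction Fraction of genes given an intrinsic
#'   sex-biased fold change (half male-, half female-biased).
#' @param sex_bias_fold Fold change applied to sex-biased genes.
#' @param libsize Mean library size (reads per sample).
#' @param dispersion Negative-binomial size for bulk counts.
#' @return A list: `counts` (genes x samples integer matrix), `samples`
#'   (tibble: `sample`, `tissue`, `sex`, `replicate`), `annotation`
#'   (with gene lengths), and `genes` (per-gene truth: tissues the gene is
#'   active in and its sex-bias class).
#' @export
generate_bulk_panel <- function(config, n_tissues = 8, n_reps = 4, seed = 1L,
                                male_element_factor = NULL,
                                sex_biased_fraction = 0.2,
                                sex_bias_fold = 4,
                                libsize = 2e6,
                                dispersion = 50) {
  stopifnot(inherits(config, "sim_config"))
  if (n_tissues < 2) abort("`n_tissues` must be >= 2.")
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  annotation <- generate_annotation(config)
  n_genes <- nrow(annotation)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))

  withr::with_seed(seed, {
    lambda <- rlnorm(n_genes, config$gene_rate_meanlog, config$gene_rate_sdlog)
    broad <- runif(n_genes) < config$broad_fraction[annotation$element]

    # tissue activity: broad genes everywhere (mild jitter); restricted genes
    # boosted in 1-2 tissues and silent elsewhere.
    expr <- matrix(0, n_genes, n_tissues, dimnames = list(annotation$gene_id, tissues))
    jitter <- matrix(rlnorm(n_genes * n_tissues, 0, 0.2), n_genes, n_tissues)
    expr[broad, ] <- lambda[broad] * jitter[broad, ]
    r_idx <- which(!broad)
    n_home <- sample(1:2, length(r_idx), replace = TRUE)
    boost <- rlnorm(length(r_idx), config$marker_boost_meanlog,
                    config$marker_boost_sdlog)
    for (k in seq_along(r_idx)) {
      home <- sample(n_tissues, n_home[k])
      expr[r_idx[k], home] <- lambda[r_idx[k]] * boost[k] * jitter[r_idx[k], home]
    }

    # sex bias: intrinsic fold changes on a designated gene fraction, plus
    # optional element-wide male multipliers.
    class <- rep("unbiased", n_genes)
    n_sb <- round(sex_biased_fraction * n_genes)
    sb <- sample(n_genes, n_sb)
    class[sb[seq_len(floor(n_sb / 2))]] <- "male"
    class[sb[seq((floor(n_sb / 2) + 1), length(sb))]] <- "female"
    male_fac <- ifelse(class == "male", sex_bias_fold,
                       ifelse(class == "female", 1 / sex_bias_fold, 1))
    if (!is.null(male_element_factor)) {
      for (e in names(male_element_factor)) {
        male_fac[annotation$element == e] <-
          male_fac[annotation$element == e] * male_element_factor[[e]]
      }
    }

    samples <- tidyr::expand_grid(tissue = tissues, sex = c("female", "male"),
                                  replicate = seq_len(n_reps))
    samples$sample <- sprintf("%s_%s_r%d", samples$tissue,
                              substr(samples$sex, 1, 1), samples$replicate)
    len_kb <- annotation$length / 1000

    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(annotation$gene_id, samples$sample))
    for (s in seq_len(nrow(samples))) {
      e <- expr[, samples$tissue[s]]
      if (samples$sex[s] == "male") e <- e * male_fac
      rate <- rescale_to(e * len_kb, 1)
      counts[, s] <- rnbinom(n_genes, mu = rate * libsize, size = dispersion)
    }

    list(
      counts = counts,
      samples = samples[, c("sample", "tissue", "sex", "replicate")],
      annotation = annotation,
      genes = tibble(
        gene_id = annotation$gene_id,
        element = annotation$element,
        broad = broad,
        sex_bias = class,
        active_tissues = lapply(seq_len(n_genes), function(i) tissues[expr[i, ] > 0])
      )
    )
  })
}
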