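#' Simulate phenotypes and expression from planted QTNs
#'
#' Each trait's genetic value is the sum of its planted additive QTN
#' effects times the true alternate-allele dosage; an independent normal
#' environmental deviate is added to every (sample, location, replicate)
#' observation, scaled so that the genetic fraction of the per-observation
#' variance equals `config$h2` (with `h2 = 1` the trait is an exact affine
#' function of dosage). Traits without a QTN are pure noise. The expression
#' table carries `config$n_replicates`-fold TPM replicates for every
#' pathway gene in a subset of samples; the planted expression gene shows a
#' fixed fold change between the allele groups of its linked SNP.
#'
#' @param population output of [simulate_population()] (or
#'   [simulate_study()]): list with `variants`, `clusters`, `truth`.
#' @param truth the truth set (defaults to `population$truth`); must carry
#'   `qtn` and `qtn_dosage`, and may carry `pathway_gene_ids`,
#'   `expression_gene` and `expression_snp` for the expression table.
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame `sample`, `trait`,
#'   `location`, `replicate`, `value`) and `expression` (data.frame
#'   `gene_id`, `sample`, `replicate`, `tpm`), plus `genetic_values`
#'   (matrix trait x sample) for variance audits.
#' @export
simulate_phenotypes_and_expression <- function(population,
                                               truth = population$truth,
                                               config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  samples <- sample_names(population$variants)
  qtn <- truth$qtn
  traits <- unique(c(qtn$trait, config$null_traits))
  gmat <- matrix(0, length(traits), length(samples),
                 dimnames = list(traits, samples))
  for (i in seq_len(nrow(qtn))) {
    dos <- truth$qtn_dosage[qtn$snp_id[i], samples]
    gmat[qtn$trait[i], ] <- gmat[qtn$trait[i], ] + qtn$effect[i] * dos
  }
  locations <- paste0("L", seq_len(config$n_locations))
  rows <- list()
  for (tr in traits) {
    base <- if (tr %in% names(config$trait_baseline))
      config$trait_baseline[[tr]] else 0
    g <- base + gmat[tr, ]
    var_g <- stats::var(g)
    sd_e <- if (var_g == 0) 1 else if (config$h2 == 1) 0 else
      sqrt(var_g * (1 - config$h2) / config$h2)
    for (loc in locations) {
      for (rep_i in seq_len(config$n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples, trait = tr, location = loc, replicate = rep_i,
          value = g + stats::rnorm(length(g), 0, sd_e),
          stringsAsFactors = FALSE)
      }
    }
  }
  phenotypes <- do.call(rbind, rows)
  rownames(phenotypes) <- NULL

  expression <- NULL
  genes <- truth$pathway_gene_ids
  if (is.null(genes) && nrow(qtn)) genes <- paste0("gene_", qtn$snp_id)
  if (!is.null(genes)) {
    expr_gene <- truth$expression_gene
    expr_snp <- truth$expression_snp
    if (is.null(expr_snp) && nrow(qtn)) expr_snp <- qtn$snp_id[1]
    if (is.null(expr_gene) && !is.null(expr_snp))
      expr_gene <- genes[1]
    # choose expression samples covering both allele groups when possible
    carriers <- character(0)
    if (!is.null(expr_snp) && expr_snp %in% rownames(truth$qtn_dosage)) {
      dos <- truth$qtn_dosage[expr_snp, samples]
      minor_is_alt <- mean(dos) / 2 <= 0.5
      carrier <- if (minor_is_alt) dos >= 1 else dos <= 1
      carriers <- samples[carrier]
    }
    half <- config$n_expression_samples %/% 2
    pick <- c(utils::head(carriers, half),
              utils::head(setdiff(samples, carriers),
                          config$n_expression_samples - min(half,
                                                            length(carriers))))
    pick <- utils::head(unique(pick), config$n_expression_samples)
    base <- stats::rlnorm(length(genes),
                          meanlog = log(config$expression_baseline_tpm),
                          sdlog = 0.6)
    names(base) <- genes
    erows <- list()
    for (g in genes) {
      mu <- rep(base[[g]], length(pick))
      if (!is.null(expr_gene) && g == expr_gene && length(carriers))
        mu[pick %in% carriers] <- mu[pick %in% carriers] *
          config$expression_fold_change
      for (rep_i in seq_len(config$n_replicates)) {
        erows[[length(erows) + 1L]] <- data.frame(
          gene_id = g, sample = pick, replicate = rep_i,
          tpm = mu * exp(stats::rnorm(length(pick), 0, 0.15)),
          stringsAsFactors = FALSE)
      }
    }
    expression <- do.call(rbind, erows)
    rownames(expression) <- NULL
  }
  list(phenotypes = phenotypes, expression = expression,
       genetic_values = gmat)
}
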