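#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator: a structured
#' population of diploid clusters simulated under the Balding-Nichols model,
#' a toy annotated genome with metabolic-pathway genes (a subset carrying EC
#' tags, the rest discoverable only through orthogroups), planted selective
#' sweeps, quantitative trait nucleotides (QTNs) and an allele-linked
#' expression signal.
#'
#' Defaults emulate the study conditions of a diploid greater-yam panel:
#' three genetic clusters (the K = 3 admixture solution) of 36 diploids each
#' (107-ish diploids total), mean sequencing depth 37x, 3-location field
#' trials with 3 replicates, a moderate background divergence (F = 0.05)
#' against strong divergence (F = 0.40) at swept loci, and an orthology-only
#' gene fraction of 48% of the keyword-annotated genes.
#'
#' @param n_samples_per_cluster diploid samples per cluster (default 36).
#' @param n_clusters number of clusters (default 3; labelled A, B, C, ...).
#' @param n_sites total SNP sites, including selected and planted QTN sites.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param background_F,selected_F Balding-Nichols divergence parameters in
#'   (0, 1) for background and swept loci; `selected_F > background_F`.
#' @param n_selected_loci number of swept (selected) loci.
#' @param n_sweeps number of sweep regions the selected loci cluster into.
#' @param sweep_width width of each sweep region in bp.
#' @param qtn_spec list of QTNs; each element a list with `trait`, `effect`
#'   (in trait units, additive per alt allele) and optionally `site` (a
#'   1-based index into the position-sorted site list; `NULL` lets the
#'   generator place the QTN inside a pathway gene as a stop-gain SNP).
#' @param null_traits measured traits with no planted QTN (pure noise).
#' @param trait_baseline named vector of trait intercepts (population
#'   baseline in trait units; e.g. a starch content around 78%); traits
#'   not listed get baseline 0. Baselines keep allele effects expressed as
#'   a percentage of the group mean on a realistic scale.
#' @param h2 narrow-sense heritability per trait, in (0, 1].
#' @param n_locations,n_replicates field locations and replicates per
#'   (sample, location).
#' @param missing_rate fraction of genotype calls set missing.
#' @param mean_depth,depth_dispersion negative-binomial per-call read depth
#'   (mean 37, echoing a 37x panel; dispersion gives realistic spread so
#'   depth filters have material to act on).
#' @param qual_mean,qual_sd site QUAL distribution (normal, floored at 1).
#' @param n_pathway_genes_annotated pathway genes carrying EC attributes.
#' @param n_pathway_genes_orthology_only pathway genes without EC attributes
#'   that share an orthogroup with an annotated gene (default 48% of the
#'   annotated count).
#' @param expression_fold_change planted fold change between allele groups
#'   at the expression-linked gene.
#' @param n_expression_samples samples with expression data (default 6).
#' @param expression_baseline_tpm median baseline TPM of pathway genes.
#' @param seed integer RNG seed; all generator stages derive their streams
#'   from it, so a fixed seed gives byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_per_cluster = 36,
                       n_clusters = 3,
                       n_sites = 1600,
                       chrom_lengths = c(chr1 = 1000000, chr2 = 1000000),
                       background_F = 0.05,
                       selected_F = 0.40,
                       n_selected_loci = 24,
                       n_sweeps = 3,
                       sweep_width = 40000,
                       qtn_spec = list(
                         list(trait = "starch_content", effect = 8),
                         list(trait = "hardness", effect = 15),
                         list(trait = "hue_index", effect = -40)),
                       null_traits = c("springiness", "cohesiveness"),
                       trait_baseline = c(starch_content = 78,
                                          hardness = 30, gumminess = 20,
                                          springiness = 1,
                                          cohesiveness = 0.6,
                                          total_area = 50,
                                          brown_index = 30,
                                          hue_index = 40),
                       h2 = 0.4,
                       n_locations = 3,
                       n_replicates = 3,
                       missing_rate = 0.05,
                       mean_depth = 37,
                       depth_dispersion = 8,
                       qual_mean = 60,
                       qual_sd = 25,
                       n_pathway_genes_annotated = 100,
                       n_pathway_genes_orthology_only = 48,
                       expression_fold_change = 4,
                       n_expression_samples = 6,
                       expression_baseline_tpm = 20,
                       seed = 1) {
  cfg <- list(n_samples_per_cluster = as.integer(n_samples_per_cluster),
              n_clusters = as.integer(n_clusters),
              n_sites = as.integer(n_sites),
              chrom_lengths = chrom_lengths,
              background_F = background_F, selected_F = selected_F,
              n_selected_loci = as.integer(n_selected_loci),
              n_sweeps = as.integer(n_sweeps),
              sweep_width = as.integer(sweep_width),
              qtn_spec = qtn_spec, null_traits = null_traits,
              trait_baseline = trait_baseline, h2 = h2,
              n_locations = as.integer(n_locations),
              n_replicates = as.integer(n_replicates),
              missing_rate = missing_rate, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              qual_mean = qual_mean, qual_sd = qual_sd,
              n_pathway_genes_annotated = as.integer(n_pathway_genes_annotated),
              n_pathway_genes_orthology_only =
                as.integer(n_pathway_genes_orthology_only),
              expression_fold_change = expression_fold_change,
              n_expression_samples = as.integer(n_expression_samples),
              expression_baseline_tpm = expression_baseline_tpm,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_samples_per_cluster", "n_clusters", "n_sites", "n_sweeps",
              "n_locations", "n_replicates")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  if (cfg$n_selected_loci < 0) stop("n_selected_loci must be >= 0")
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  for (F in c(cfg$background_F, cfg$selected_F))
    if (!is.numeric(F) || F <= 0 || F >= 1)
      stop("divergence parameters F must lie strictly inside (0, 1)")
  if (cfg$selected_F <= cfg$background_F)
    stop("selected_F must exceed background_F")
  if (cfg$n_selected_loci > cfg$n_sites)
    stop("n_selected_loci cannot exceed n_sites")
  if (!is.numeric(cfg$h2) || cfg$h2 <= 0 || cfg$h2 > 1)
    stop("h2 must lie in (0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  for (q in cfg$qtn_spec) {
    if (is.null(q$trait) || is.null(q$effect))
      stop("each qtn_spec entry needs trait and effect")
    if (!is.null(q$site) && (q$site < 1 || q$site > cfg$n_sites))
      stop("qtn site index must lie in [1, n_sites]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_clusters, "clusters x", x$n_samples_per_cluster,
      "samples,", x$n_sites, "sites on",
      length(x$chrom_lengths), "chromosome(s);",
      "F =", x$background_F, "background /", x$selected_F, "selected;",
      length(x$qtn_spec), "QTN(s); seed", x$seed, "\n")
  invisible(x)
}

cluster_labels <- function(cfg) LETTERS[seq_len(cfg$n_clusters)]

sim_sample_names <- function(cfg) {
  unlist(lapply(cluster_labels(cfg), function(cl)
    sprintf("%s%02d", cl, seq_len(cfg$n_samples_per_cluster))))
}
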