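#' Simulate a complete candidate-gene study with known ground truth
#'
#' Orchestrates the generator stages into one coherent study: an annotated
#' toy genome with pathway genes and orthogroups; selective sweeps centred
#' on one annotated pathway gene each (every SNP falling inside a sweep
#' region is simulated with `selected_F`); planted stop-gain QTN SNPs
#' inside the CDS of pathway genes — the first QTN lands in the first sweep
#' anchor gene, so that gene carries *both* divergence and a trait effect;
#' phenotypes and an expression table whose planted gene (the last QTN's
#' host, echoing an allele-linked pigment-pathway gene) shows a fixed fold
#' change between allele groups.
#'
#' @param config a [sim_config()].
#' @return list with `variants`, `clusters`, `truth`, `models`, `genome`,
#'   `og_table`, `pathway_table`, `gene_pathways`, `phenotypes`,
#'   `expression`, `config`. The truth set records selected site IDs, QTN
#'   effects and host genes, sweep regions and anchor genes, the
#'   orthology-only gene IDs and the planted expression gene/SNP.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  ann <- simulate_annotation_and_orthogroups(config)
  set.seed(config$seed + 13L)
  genes <- ann$gene_pathways
  pathways <- unique(genes$pathway)

  # sweep anchors: one annotated gene per sweep, cycling over pathways
  anchor_genes <- character(config$n_sweeps)
  for (j in seq_len(config$n_sweeps)) {
    pool <- genes$gene_id[genes$annotated &
                            genes$pathway == pathways[(j - 1) %% length(pathways) + 1] &
                            !genes$gene_id %in% anchor_genes]
    anchor_genes[j] <- sample(pool, 1)
  }
  gm <- ann$models$genes
  amid <- (gm$start + gm$end)[match(anchor_genes, gm$gene_id)] %/% 2L
  asq <- gm$seqname[match(anchor_genes, gm$gene_id)]
  sw_start <- pmax(1L, amid - config$sweep_width %/% 2L)
  sweep_regions <- data.frame(seqname = asq, start = sw_start,
                              end = sw_start + config$sweep_width - 1L,
                              anchor_gene = anchor_genes,
                              stringsAsFactors = FALSE)

  # QTN host genes: first QTN in the dual (sweep-anchored) gene, the rest
  # in annotated pathway genes outside the sweeps
  n_qtn <- length(config$qtn_spec)
  qtn_genes <- character(n_qtn)
  if (n_qtn) {
    qtn_genes[1] <- anchor_genes[1]
    pool <- genes$gene_id[genes$annotated &
                            !genes$gene_id %in% anchor_genes]
    if (n_qtn > 1) qtn_genes[2:n_qtn] <- sample(pool, n_qtn - 1)
  }
  planted <- list()
  for (i in seq_len(n_qtn)) {
    pl <- plant_stop_gain_site(ann, qtn_genes[i])
    ann <- pl$annotation
    planted[[i]] <- pl$site
  }

  # site placement aligned with the (mutated) genome
  lens <- config$chrom_lengths
  n_bg <- config$n_sites - config$n_selected_loci - n_qtn
  if (n_bg < 0) stop("n_sites too small for the selected loci and QTNs")
  share <- round(n_bg * lens / sum(lens))
  share[length(share)] <- n_bg - sum(share[-length(share)])
  seqname <- rep(names(lens), share)
  pos <- unlist(lapply(names(lens), function(sq)
    sample.int(lens[[sq]], share[[sq]])))
  per <- diff(round(seq(0, config$n_selected_loci,
                        length.out = config$n_sweeps + 1)))
  for (j in seq_len(config$n_sweeps)) {
    seqname <- c(seqname, rep(sweep_regions$seqname[j], per[j]))
    pos <- c(pos, sweep_regions$start[j] +
               sample.int(config$sweep_width, per[j]) - 1L)
  }
  qtn_index <- rep(NA_integer_, length(pos))
  for (i in seq_len(n_qtn)) {
    seqname <- c(seqname, planted[[i]]$seqname)
    pos <- c(pos, planted[[i]]$pos)
    qtn_index <- c(qtn_index, i)
  }
  key <- paste(seqname, pos)
  repeat {  # de-duplicate collisions, never moving a planted QTN site
    dup <- key %in% key[duplicated(key)]
    if (!any(dup)) break
    nudge <- rep(FALSE, length(key))
    for (kk in unique(key[dup])) {
      idx <- which(key == kk)
      keep <- if (any(!is.na(qtn_index[idx])))
        idx[!is.na(qtn_index[idx])][1] else idx[1]
      nudge[setdiff(idx, keep)] <- TRUE
    }
    pos[nudge] <- ifelse(pos[nudge] >= lens[seqname[nudge]],
                         pos[nudge] - 1L, pos[nudge] + 1L)
    key <- paste(seqname, pos)
  }
  o <- order(match(seqname, names(lens)), pos)
  sites <- data.frame(seqname = seqname[o], pos = pos[o],
                      qtn_index = qtn_index[o], stringsAsFactors = FALSE)
  in_sweep <- rep(FALSE, nrow(sites))
  for (j in seq_len(nrow(sweep_regions)))
    in_sweep <- in_sweep | (sites$seqname == sweep_regions$seqname[j] &
                              sites$pos >= sweep_regions$start[j] &
                              sites$pos <= sweep_regions$end[j])
  sites$selected <- in_sweep
  # reference alleles from the genome; alternates random except planted
  bases <- c("A", "C", "G", "T")
  sites$ref <- NA_character_
  for (sq in names(lens)) {
    i <- which(sites$seqname == sq)
    sites$ref[i] <- substring(as.character(ann$genome[[sq]]),
                              sites$pos[i], sites$pos[i])
  }
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1), "")
  for (i in seq_len(n_qtn)) {
    k <- which(sites$qtn_index == i)
    sites$ref[k] <- planted[[i]]$ref
    sites$alt[k] <- planted[[i]]$alt
  }
  attr(sites, "sweep_regions") <- sweep_regions[, c("seqname", "start", "end")]

  pop <- simulate_population(config, sites = sites)
  truth <- pop$truth
  truth$sweep_regions <- sweep_regions
  planted_ids <- vapply(planted, function(p) snp_id(p$seqname, p$pos), "")
  truth$qtn$gene_id <- qtn_genes[match(truth$qtn$snp_id, planted_ids)]
  truth$qtn_genes <- qtn_genes
  truth$anchor_genes <- anchor_genes
  truth$orthology_only_gene_ids <- ann$orthology_only_gene_ids
  truth$pathway_gene_ids <- sort(genes$gene_id)
  if (n_qtn) {
    truth$expression_gene <- qtn_genes[n_qtn]
    truth$expression_snp <- truth$qtn$snp_id[
      truth$qtn$gene_id == qtn_genes[n_qtn]][1]
  }
  pop$truth <- truth
  phen <- simulate_phenotypes_and_expression(pop, truth, config)
  list(variants = pop$variants, clusters = pop$clusters, truth = truth,
       models = ann$models, genome = ann$genome, og_table = ann$og_table,
       pathway_table = ann$pathway_table, gene_pathways = ann$gene_pathways,
       phenotypes = phen$phenotypes, expression = phen$expression,
       genetic_values = phen$genetic_values, config = config)
}
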