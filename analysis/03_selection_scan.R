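#!/usr/bin/env Rscript
# Stage 3: nucleotide diversity and the Fst-outlier selection scan.
# Per-site Weir-Cockerham components for every cluster pair, 50 kb / 10 kb
# weighted windows, a parametric fit (Weibull / normal / lognormal / gamma,
# AIC-selected) to each pair's window distribution, the top-5% quantile
# cutoff, outlier windows and their genes, and the regions shared by all
# pairwise comparisons.

library(tuberscan)

vt <- read_vcf("results/variants_popgen.vcf")
clusters_df <- read_tsv("results/inputs/clusters.tsv")
clusters <- setNames(clusters_df$cluster, clusters_df$sample)
models <- read_gff3("results/inputs/genes.gff3")
truth <- read_truth("results/inputs/truth.json")
chrom_lengths <- setNames(nchar(as.character(
  read_fasta("results/inputs/genome.fa"))),
  names(read_fasta("results/inputs/genome.fa")))

pi_hat <- site_pi(vt, denominator_bp = sum(chrom_lengths))
cat(sprintf("nucleotide diversity: mean pi per variant site %.4f, %.3e per bp\n",
            pi_hat$mean_pi, pi_hat$pi_per_bp))

fst <- pairwise_fst_sites(vt, clusters)
outlier_sets <- list()
outlier_genes <- list()
for (p in names(fst)) {
  w <- windowed_fst(fst[[p]], chrom_lengths, window = 50000, step = 10000,
                    pair = p)
  os <- outlier_windows(w, q = 0.95)
  outlier_sets[[p]] <- os
  outlier_genes[[p]] <- intersect_outliers_with_genes(os, models)
  cat(sprintf("%s: %d windows, best family %s, cutoff %.4f, %d outliers, %d genes\n",
              p, nrow(w), os$family, os$cutoff, nrow(os$windows),
              length(outlier_genes[[p]])))
  write_tsv(w, file.path("results", paste0("fst_windows_", p, ".tsv")))
  write_outlier_bed(os, file.path("results", paste0("fst_outliers_", p,
                                                    ".bed")))
}

common <- common_regions(outlier_sets)
cat("regions outlying in every pairwise comparison:", nrow(common), "\n")
write_tsv(common, "results/fst_common_regions.tsv")

all_genes <- sort(unique(unlist(outlier_genes)))
write_tsv(data.frame(gene_id = all_genes), "results/fst_outlier_genes.tsv")
write_tsv(do.call(rbind, lapply(names(outlier_genes), function(p)
  data.frame(pair = p, gene_id = outlier_genes[[p]]))),
  "results/fst_outlier_genes_by_pair.tsv")

# recovery audit against the planted truth
sel <- truth$selected_site_ids[truth$selected_site_ids %in% vt$sites$id]
selpos <- vt$sites[match(sel, vt$sites$id), c("seqname", "pos")]
covered <- rep(FALSE, length(sel))
for (os in outlier_sets)
  for (j in seq_len(nrow(os$windows)))
    covered <- covered | (selpos$seqname == os$windows$seqname[j] &
                            selpos$pos >= os$windows$start[j] &
                            selpos$pos <= os$windows$end[j])
cat(sprintf("planted selected loci inside outlier windows: %d / %d (%.0f%%)\n",
            sum(covered), length(covered), 100 * mean(covered)))

# enrichment of outlier genes for pathway membership
gp <- read_tsv("results/inputs/pathways.tsv")
models_ec <- gene_ec_table(models)
seeds <- lapply(unique(gp$pathway_id), function(pw)
  keyword_retrieval(models, gp, pw))
names(seeds) <- unique(gp$pathway_id)
og <- read_orthogroups("results/inputs/orthogroups.tsv")
annotation <- do.call(rbind, lapply(names(seeds), function(pw) {
  ex <- orthogroup_expansion(seeds[[pw]], og, "dalata")
  data.frame(gene_id = ex$gene_id, term = pw)
}))
enr <- enrichment_test(all_genes, models$genes$gene_id, annotation)
print(enr)
write_tsv(enr, "results/fst_outlier_enrichment.tsv")
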