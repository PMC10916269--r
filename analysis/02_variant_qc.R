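#!/usr/bin/env Rscript
# Stage 2: variant quality control and consequence annotation.
# Reads results/inputs/, applies the QC gates (minQ 30, DP 10-200,
# call rate >= 0.5) and the population-genetics site filter (biallelic,
# MAF >= 0.01, 10 bp thinning), classifies every surviving SNP against the
# gene models, and writes the filtered VCF plus a consequence TSV.

library(tuberscan)

vt <- read_vcf("results/inputs/variants.vcf")
cat("input sites:", n_sites(vt), "\n")

vt_qc <- filter_variants(vt, min_qual = 30, min_dp = 10, max_dp = 200,
                         min_call_rate = 0.5)
cat("after QC filter:", n_sites(vt_qc), "sites\n")

vt_pg <- popgen_site_filter(vt_qc, maf = 0.01, thin_bp = 10)
cat("after popgen site filter:", n_sites(vt_pg), "sites\n")

models <- read_gff3("results/inputs/genes.gff3")
genome <- read_fasta("results/inputs/genome.fa")
cons <- suppressWarnings(classify_consequence(vt_qc, models, genome))
cat("\nconsequence classes over", length(unique(cons$snp_id)), "SNPs:\n")
print(table(cons$category))

high <- select_high_impact(cons)
cat("\nhigh-impact SNP records:", nrow(high), "\n")

write_vcf(vt_qc, "results/variants_qc.vcf")
write_vcf(vt_pg, "results/variants_popgen.vcf")
write_tsv(cons, "results/consequences.tsv")
write_tsv(high, "results/consequences_high_impact.tsv")
cat("\nwrote results/variants_qc.vcf, results/variants_popgen.vcf,\n",
    "results/consequences.tsv, results/consequences_high_impact.tsv\n")
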