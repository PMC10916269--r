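#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth and write
# the input file set (VCF, GFF3, FASTA, orthogroups, pathway ECs,
# phenotypes, expression, cluster assignments, truth JSON) under
# results/inputs/. Later stages start from these files, exactly as a real
# analysis would start from a sequencing project's deliverables.

library(tuberscan)

cfg <- sim_config(seed = 20260928)
print(cfg)
st <- simulate_study(cfg)

dir.create("results", showWarnings = FALSE)
write_study_inputs(st, "results/inputs")

cat("\nWrote results/inputs/ with:\n")
cat(" -", n_sites(st$variants), "SNP sites x", n_samples(st$variants),
    "samples in", length(unique(st$clusters)), "clusters\n")
cat(" -", nrow(st$models$genes), "gene models (",
    sum(lengths(st$models$ec) > 0), "EC-annotated,",
    length(st$truth$orthology_only_gene_ids), "orthology-only )\n")
cat(" -", length(st$truth$selected_site_ids),
    "selected loci in", nrow(st$truth$sweep_regions), "sweep regions\n")
cat(" -", nrow(st$truth$qtn), "planted QTNs:\n")
print(st$truth$qtn)
cat(" - planted expression gene:", st$truth$expression_gene,
    "(allele-linked fold change", cfg$expression_fold_change, "x)\n")
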