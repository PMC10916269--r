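#!/usr/bin/env Rscript
# Stage 4: metabolic-pathway gene retrieval.
# EC-number keyword search per pathway, orthogroup expansion to recover
# pathway genes that carry no EC tag, UpSet-style presence/absence tallies
# across species, and extraction of the high-impact candidate SNPs within
# the transcribed units of the pathway genes.

library(tuberscan)

models <- read_gff3("results/inputs/genes.gff3")
catalog <- read_tsv("results/inputs/pathways.tsv")
og <- read_orthogroups("results/inputs/orthogroups.tsv")
cons <- read_tsv("results/consequences.tsv")

expanded <- list()
for (pw in unique(catalog$pathway_id)) {
  seeds <- keyword_retrieval(models, catalog, pw)
  ex <- orthogroup_expansion(seeds, og, "dalata")
  expanded[[pw]] <- ex
  cat(sprintf("%s: %d keyword genes + %d by orthology = %d (+%.0f%%)\n",
              pw, sum(ex$provenance == "keyword"),
              sum(ex$provenance == "orthology"), nrow(ex),
              100 * sum(ex$provenance == "orthology") /
                sum(ex$provenance == "keyword")))
  write_tsv(ex, file.path("results", paste0("pathway_genes_", pw, ".tsv")))
}
total_kw <- sum(vapply(expanded, function(e) sum(e$provenance == "keyword"),
                       0))
total <- sum(vapply(expanded, nrow, 0))
cat(sprintf("all pathways: %d -> %d genes (+%.0f%%)\n", total_kw, total,
            100 * (total - total_kw) / total_kw))

pa <- presence_absence(og, c("dalata", "drotundata", "dzingiberensis"))
cat("\northogroup presence/absence (UpSet tallies):\n")
print(pa$tallies)
cat("orthogroups shared by all species:", pa$shared_all, "\n")
write_tsv(pa$tallies, "results/orthogroup_upset_tallies.tsv")

cand <- candidate_snp_extraction(cons, expanded)
cat("\nhigh-impact candidate SNPs per pathway:\n")
print(attr(cand, "counts"))
cat("of which in orthology-only genes:",
    sum(cand$provenance == "orthology"), "\n")
write_tsv(cand, "results/candidate_snps.tsv")
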