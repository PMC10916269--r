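# Fixtures built in code at test time.

# variant_table from a dosage matrix (rows = sites, cols = samples)
mk_vt <- function(dosage, seqname = "chr1",
                  pos = seq(100, by = 100, length.out = nrow(dosage)),
                  ref = "A", alt = "T", qual = 50, dp = 30) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(m))
  gt <- matrix(NA_character_, n, m, dimnames = dimnames(dosage))
  gt[!is.na(dosage)] <- c("0/0", "0/1", "1/1")[dosage[!is.na(dosage)] + 1L]
  variant_table(rep(seqname, length.out = n), pos,
                rep(ref, length.out = n), rep(alt, length.out = n),
                rep(qual, length.out = n), gt,
                matrix(dp, n, m, dimnames = dimnames(dosage)))
}

# Hand-built two-exon gene on a 400 bp toy chromosome (plus strand), with
# known codons so each consequence class has a planted SNP:
#   exon1 101-160 (5'UTR 101-130, CDS 131-160), intron 161-220 (GT..AG),
#   exon2 221-310 (CDS 221-280, 3'UTR 281-310); 30 codons, TAA stop.
#   codon2 = TGG (Trp), codon3 = GCT (Ala), codon4 = CTG (Leu).
toy_gene_fixture <- function() {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  codons <- c("ATG", "TGG", "GCT", "CTG",
              sample(sense, 25, replace = TRUE), "TAA")
  cds_seq <- paste(codons, collapse = "")
  chrT <- sample(bases, 400, replace = TRUE)
  chrT[131:160] <- strsplit(substr(cds_seq, 1, 30), "")[[1]]
  chrT[221:280] <- strsplit(substr(cds_seq, 31, 90), "")[[1]]
  chrT[161:162] <- c("G", "T")
  chrT[219:220] <- c("A", "G")
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste(chrT, collapse = ""),
    chrU = paste(sample(bases, 200, replace = TRUE), collapse = "")))
  models <- gene_model_set(
    genes = data.frame(gene_id = "gX", seqname = "chrT", strand = "+",
                       start = 101L, end = 310L),
    exons = data.frame(gene_id = "gX", start = c(101L, 221L),
                       end = c(160L, 310L)),
    cds = data.frame(gene_id = "gX", start = c(131L, 221L),
                     end = c(160L, 280L)),
    ec = list(gX = "4.2.2.1"))
  list(models = models, genome = genome, codons = codons)
}

# Mirror a toy fixture: reverse-complement every chromosome and flip the
# gene coordinates/strand, so classifications must be identical.
flip_fixture <- function(fx) {
  lens <- Biostrings::width(fx$genome)
  names(lens) <- names(fx$genome)
  genome <- Biostrings::reverseComplement(fx$genome)
  names(genome) <- names(fx$genome)
  mirror <- function(df) {
    L <- lens[fx$models$genes$seqname[match(df$gene_id,
                                            fx$models$genes$gene_id)]]
    out <- df
    out$start <- as.integer(L - df$end + 1)
    out$end <- as.integer(L - df$start + 1)
    out
  }
  genes <- mirror(fx$models$genes)
  genes$strand <- ifelse(fx$models$genes$strand == "+", "-", "+")
  genes$seqname <- fx$models$genes$seqname
  models <- gene_model_set(genes, mirror(fx$models$exons),
                           mirror(fx$models$cds), fx$models$ec)
  list(models = models, genome = genome, lens = lens)
}

# Ten hand-written sites whose survivors under every quoted filter were
# enumerated by hand before the filters were implemented:
#   QC survivors (minQ 30, DP 10/200 masking, call rate >= 0.5):
#     sites 1,2,4,5,7,8,9,10  (site 3 fails QUAL, site 6 fails call rate)
#   popgen survivors (biallelic, MAF >= 0.01, thin 10):
#     chr1:100, chr1:118, chr1:155, chr2:103
toy_filter_vcf <- function() {
  samples <- sprintf("s%d", 1:6)
  site <- function(seqname, pos, qual, gt, dp, alt = "T") {
    list(seqname = seqname, pos = pos, qual = qual, gt = gt,
         dp = rep(dp, length.out = 6), alt = alt)
  }
  sites <- list(
    site("chr1", 100, 50, rep("0/1", 6), 30),
    site("chr1", 105, 50, c("0/1", rep("0/0", 5)), 30),
    site("chr1", 112, 29.9, rep("0/1", 6), 30),
    site("chr1", 118, 35, c("0/0", "0/0", "0/0", "0/1", "0/0", "0/0"),
         c(5, 5, 5, 50, 50, 50)),
    site("chr1", 125, 40, c(NA, rep("0/0", 5)), 30),
    site("chr1", 140, 60, rep("0/1", 6), c(250, 250, 250, 250, 30, 30)),
    site("chr1", 150, 45, c("0/1", "0/2", "1/2", "0/0", "0/0", "0/0"), 30,
         alt = "T,G"),
    site("chr1", 155, 45, c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0"), 30),
    site("chr2", 100, 80, rep("1/1", 6), 30),
    site("chr2", 103, 80, rep("0/1", 6), 30))
  gt <- do.call(rbind, lapply(sites, `[[`, "gt"))
  colnames(gt) <- samples
  dp <- do.call(rbind, lapply(sites, `[[`, "dp"))
  variant_table(vapply(sites, `[[`, "", "seqname"),
                vapply(sites, function(s) s$pos, 0),
                rep("A", 10), vapply(sites, `[[`, "", "alt"),
                vapply(sites, function(s) s$qual, 0), gt, dp)
}

# small config for fast generator runs in unit tests
small_config <- function(...) {
  sim_config(n_samples_per_cluster = 12, n_sites = 300,
             chrom_lengths = c(chr1 = 300000, chr2 = 200000),
             n_selected_loci = 12, n_sweeps = 2, sweep_width = 20000,
             n_pathway_genes_annotated = 12,
             n_pathway_genes_orthology_only = 6, ...)
}
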