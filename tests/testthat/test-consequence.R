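cons_of <- function(fx, pos, ref, alt, flank = 5000) {
  snps <- data.frame(seqname = "chrT", pos = pos, ref = ref, alt = alt)
  classify_consequence(snps, fx$models, fx$genome, flank = flank)
}

test_that("planted SNPs receive every consequence class", {
  fx <- toy_gene_fixture()
  # codon2 TGG -> TGA: stop gained, Trp at protein position 2
  r <- cons_of(fx, 136, "G", "A")
  expect_equal(r$category, "stop_gained")
  expect_equal(r$impact, "HIGH")
  expect_equal(r$notation, "p.Trp2>STOP")
  # initiator ATG -> ACG: start lost
  r <- cons_of(fx, 132, "T", "C")
  expect_equal(r$category, "start_lost")
  expect_equal(r$notation, "p.Met1?")
  # TAA stop -> CAA Gln: stop lost
  r <- cons_of(fx, 278, "T", "C")
  expect_equal(r$category, "stop_lost")
  expect_equal(r$impact, "HIGH")
  # GCT Ala -> ACT Thr: missense, MODERATE
  r <- cons_of(fx, 137, "G", "A")
  expect_equal(r$category, "missense")
  expect_equal(r$impact, "MODERATE")
  expect_equal(r$notation, "p.Ala3Thr")
  # CTG -> CTC: synonymous Leu
  r <- cons_of(fx, 142, "G", "C")
  expect_equal(r$category, "synonymous")
  expect_equal(r$impact, "LOW")
  # first two intronic bases = donor; last two = acceptor
  expect_equal(cons_of(fx, 161, "G", "A")$category, "splice_donor_variant")
  expect_equal(cons_of(fx, 162, "T", "C")$category, "splice_donor_variant")
  expect_equal(cons_of(fx, 219, "A", "C")$category, "splice_acceptor_variant")
  expect_equal(cons_of(fx, 220, "G", "C")$category, "splice_acceptor_variant")
  # acceptor 2 bp before the exon follows the c.{n}-2 pattern
  expect_match(cons_of(fx, 219, "A", "C")$notation, "^c\\.3[01]-2")
  expect_equal(cons_of(fx, 190,
                       substr(as.character(fx$genome[["chrT"]]), 190, 190),
                       "A")$category, "intron")
  # UTRs, flanks and intergenic
  g <- function(p) substr(as.character(fx$genome[["chrT"]]), p, p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), g(p))[1]
  expect_equal(cons_of(fx, 110, g(110), alt_of(110))$category, "5_prime_UTR")
  expect_equal(cons_of(fx, 290, g(290), alt_of(290))$category, "3_prime_UTR")
  expect_equal(cons_of(fx, 50, g(50), alt_of(50))$category, "upstream")
  expect_equal(cons_of(fx, 350, g(350), alt_of(350))$category, "downstream")
  u <- substr(as.character(fx$genome[["chrU"]]), 100, 100)
  r <- classify_consequence(data.frame(seqname = "chrU", pos = 100, ref = u,
                                       alt = setdiff(c("A", "C", "G", "T"),
                                                     u)[1]),
                            fx$models, fx$genome)
  expect_equal(r$category, "intergenic")
})

test_that("reference mismatches against the genome are rejected", {
  fx <- toy_gene_fixture()
  base <- substr(as.character(fx$genome[["chrT"]]), 136, 136)
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  expect_error(cons_of(fx, 136, wrong, base), "mismatch")
})

test_that("classification is symmetric under strand flip", {
  fx <- toy_gene_fixture()
  fl <- flip_fixture(fx)
  L <- fl$lens[["chrT"]]
  for (pos in c(136, 132, 278, 137, 142, 161, 220, 190, 110, 290, 50)) {
    base <- substr(as.character(fx$genome[["chrT"]]), pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    fwd <- cons_of(fx, pos, base, alt)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rev <- classify_consequence(
      data.frame(seqname = "chrT", pos = L - pos + 1,
                 ref = comp[[base]], alt = comp[[alt]]),
      fl$models, fl$genome)
    expect_equal(rev$category, fwd$category, label = paste("pos", pos))
  }
})

test_that("coding calls agree with a whole-CDS re-translation oracle", {
  cfg <- small_config(seed = 5)
  ann <- simulate_annotation_and_orthogroups(cfg)
  set.seed(99)
  cds <- ann$models$cds
  picks <- cds[sample.int(nrow(cds), 120, replace = TRUE), ]
  pos <- picks$start + vapply(picks$end - picks$start + 1,
                              function(w) sample.int(w, 1) - 1L, 0L)
  for (i in seq_along(pos)) {
    sq <- ann$models$genes$seqname[ann$models$genes$gene_id ==
                                     picks$gene_id[i]]
    ref <- substr(as.character(ann$genome[[sq]]), pos[i], pos[i])
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_consequence(
      data.frame(seqname = sq, pos = pos[i], ref = ref, alt = alt),
      ann$models, ann$genome)
    got <- got[!is.na(got$gene_id) & got$gene_id == picks$gene_id[i], ]
    want <- coding_oracle(ann$models, ann$genome, picks$gene_id[i],
                          pos[i], ref, alt)
    expect_equal(got$category, want,
                 label = paste(picks$gene_id[i], pos[i], ref, ">", alt))
  }
})

test_that("high-impact selection keeps exactly the chosen categories", {
  cons <- data.frame(snp_id = paste0("S1_", 1:6), gene_id = "g",
                     category = c("stop_gained", "missense", "synonymous",
                                  "splice_donor_variant", "intron",
                                  "start_lost"),
                     impact = "x", stringsAsFactors = FALSE)
  kept <- select_high_impact(cons)
  expect_setequal(kept$category,
                  c("stop_gained", "splice_donor_variant", "start_lost"))
  with_mis <- select_high_impact(cons,
                                 high_impact_categories(include_missense = TRUE))
  expect_true("missense" %in% with_mis$category)
  expect_error(select_high_impact(cons, character(0)), "empty")
})
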