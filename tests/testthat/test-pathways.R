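toy_pathway_fixture <- function() {
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD"), seqname = "chr1",
                      strand = "+", start = c(1L, 1001L, 2001L, 3001L),
                      end = c(500L, 1500L, 2500L, 3500L))
  models <- gene_model_set(genes,
                           data.frame(gene_id = genes$gene_id,
                                      start = genes$start, end = genes$end),
                           data.frame(gene_id = character(0),
                                      start = integer(0), end = integer(0)),
                           ec = list(gA = "2.4.1.34", gC = "3.2.1.4"))
  catalog <- data.frame(pathway_id = c("map00500", "map00500", "map00941"),
                        ec = c("2.4.1.34", "2.4.1.-", "1.14.11.9"))
  og <- data.frame(og_id = c("OG1", "OG1", "OG1", "OG2"),
                   species = c("dalata", "dalata", "drotundata", "dalata"),
                   gene_id = c("gA", "gB", "drot_1", "gC"))
  list(models = models, catalog = catalog, og = og)
}

test_that("EC keyword retrieval matches exact and prefix codes", {
  fx <- toy_pathway_fixture()
  r <- keyword_retrieval(fx$models, fx$catalog, "map00500")
  expect_equal(r$gene_id, "gA")
  expect_equal(r$provenance, "keyword")
  # prefix (dash) codes match by prefix
  cat2 <- data.frame(pathway_id = "mapX", ec = "3.2.1.-")
  expect_equal(keyword_retrieval(fx$models, cat2, "mapX")$gene_id, "gC")
  # gene without EC attribute is never keyword-retrieved
  expect_false("gB" %in% r$gene_id)
  expect_error(keyword_retrieval(fx$models, fx$catalog, "nope"),
               "unknown pathway")
})

test_that("orthogroup expansion adds focal co-members with inherited ECs", {
  fx <- toy_pathway_fixture()
  seeds <- keyword_retrieval(fx$models, fx$catalog, "map00500")
  ex <- orthogroup_expansion(seeds, fx$og, "dalata")
  expect_setequal(ex$gene_id, c("gA", "gB"))
  expect_equal(ex$ec[ex$gene_id == "gB"], "2.4.1.34")
  expect_equal(ex$provenance[ex$gene_id == "gB"], "orthology")
  # non-focal members are never pulled in
  expect_false("drot_1" %in% ex$gene_id)
  # monotone and idempotent
  expect_true(all(seeds$gene_id %in% ex$gene_id))
  ex2 <- orthogroup_expansion(ex, fx$og, "dalata")
  expect_setequal(ex2$gene_id, ex$gene_id)
  # seeds with no extra OG members expand to themselves
  seeds_c <- data.frame(gene_id = "gC", ec = "3.2.1.4",
                        provenance = "keyword")
  expect_equal(orthogroup_expansion(seeds_c, fx$og, "dalata")$gene_id, "gC")
  # a seed absent from the table is kept as a singleton
  seeds_x <- data.frame(gene_id = "gX", ec = "9.9.9.9",
                        provenance = "keyword")
  expect_message(exx <- orthogroup_expansion(seeds_x, fx$og, "dalata"),
                 "singleton")
  expect_equal(exx$gene_id, "gX")
})

test_that("planted orthology-only genes produce the expected gain", {
  cfg <- small_config(seed = 3)
  ann <- simulate_annotation_and_orthogroups(cfg)
  all_seeds <- do.call(rbind, lapply(unique(ann$pathway_table$pathway_id),
                                     function(pw)
                                       keyword_retrieval(ann$models,
                                                         ann$pathway_table,
                                                         pw)))
  expect_equal(nrow(all_seeds), cfg$n_pathway_genes_annotated)
  ex <- orthogroup_expansion(all_seeds, ann$og_table, ann$focal_species)
  expect_equal(nrow(ex),
               cfg$n_pathway_genes_annotated +
                 cfg$n_pathway_genes_orthology_only)
  expect_setequal(ex$gene_id[ex$provenance == "orthology"],
                  ann$orthology_only_gene_ids)
})

test_that("presence/absence tallies follow UpSet semantics", {
  og <- data.frame(og_id = c("o1", "o1", "o1", "o2", "o2", "o3"),
                   species = c("a", "b", "c", "a", "b", "a"),
                   gene_id = paste0("g", 1:6))
  pa <- presence_absence(og, c("a", "b", "c"))
  expect_equal(pa$shared_all, 1)
  expect_equal(pa$tallies$n_og[pa$tallies$combination == "a&b"], 1)
  expect_equal(pa$tallies$n_og[pa$tallies$combination == "a"], 1)
  expect_equal(sum(pa$tallies$n_og), 3)
  # one species: tallies equal row count
  pa1 <- presence_absence(og, "a")
  expect_equal(sum(pa1$tallies$n_og), 3)
  expect_error(presence_absence(og, c("a", "zz")), "absent")
})

test_that("random tallies match the subset-enumeration oracle", {
  set.seed(13)
  sp <- letters[1:4]
  og <- do.call(rbind, lapply(1:80, function(i) {
    members <- sample(sp, sample.int(4, 1))
    data.frame(og_id = sprintf("og%03d", i), species = members,
               gene_id = paste0("g", i, "_", members))
  }))
  pa <- presence_absence(og, sp)
  want <- upset_oracle(og, sp)
  got <- setNames(pa$tallies$n_og, pa$tallies$combination)
  for (cmb in names(want)) {
    key <- paste(sp[sp %in% strsplit(cmb, "&", fixed = TRUE)[[1]]],
                 collapse = "&")
    expect_equal(unname(got[key]), unname(want[cmb]), label = cmb)
  }
  expect_equal(sum(pa$tallies$n_og), length(unique(og$og_id)))
})

test_that("candidate SNP extraction keeps transcribed high-impact SNPs", {
  cons <- data.frame(
    snp_id = paste0("S1_", 1:6),
    gene_id = c("gA", "gA", "gB", "gB", "gZ", "gA"),
    category = c("stop_gained", "upstream", "splice_donor_variant",
                 "synonymous", "stop_gained", "intron"),
    impact = c("HIGH", "MODIFIER", "HIGH", "LOW", "HIGH", "MODIFIER"),
    stringsAsFactors = FALSE)
  sets <- list(map00500 = data.frame(gene_id = c("gA", "gB"),
                                     provenance = c("keyword", "orthology")))
  r <- candidate_snp_extraction(cons, sets)
  # upstream SNP excluded even in a pathway gene; gZ not in the pathway
  expect_setequal(r$snp_id, c("S1_1", "S1_3"))
  # provenance travels with the host gene (orthology-found genes included)
  expect_equal(r$provenance[r$snp_id == "S1_3"], "orthology")
  expect_equal(unname(attr(r, "counts")["map00500"]), 2L)
})
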