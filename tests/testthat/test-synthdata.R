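test_that("config invariants are enforced", {
  expect_error(sim_config(selected_F = 0.05, background_F = 0.05),
               "exceed")
  expect_error(sim_config(background_F = 0), "inside \\(0, 1\\)")
  expect_error(sim_config(selected_F = 1), "inside \\(0, 1\\)")
  expect_error(sim_config(n_sites = 10, n_selected_loci = 11),
               "cannot exceed")
  expect_error(sim_config(h2 = 0), "h2")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(qtn_spec = list(list(trait = "x", effect = 1,
                                               site = 9999))),
               "site index")
  expect_error(sim_config(n_clusters = 0), "n_clusters")
})

test_that("a fixed seed reproduces the VCF byte for byte", {
  cfg <- small_config(seed = 123)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_population(cfg)$variants, f1)
  write_vcf(simulate_population(cfg)$variants, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  cfg2 <- small_config(seed = 124)
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_population(cfg2)$variants, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("selected loci show elevated per-site Fst", {
  mean_sel_bg <- function(seed) {
    cfg <- small_config(seed = seed)
    pop <- simulate_population(cfg)
    cl <- pop$clusters
    f <- wc_fst_sites(pop$variants, names(cl)[cl == "A"],
                      names(cl)[cl == "B"])
    sel <- f$id %in% pop$truth$selected_site_ids
    c(sel = mean(f$theta[sel]), bg = mean(f$theta[!sel]))
  }
  m <- vapply(1:12, mean_sel_bg, c(sel = 0, bg = 0))
  expect_gt(mean(m["sel", ]), mean(m["bg", ]))
  expect_gt(mean(m["sel", ]), 0.2)
  expect_lt(mean(m["bg", ]), 0.1)
})

test_that("realised Fst increases monotonically with configured F", {
  realised <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(F) {
    mean(vapply(1:6, function(s) {
      cfg <- small_config(seed = s, background_F = F,
                          selected_F = min(0.9, F + 0.1))
      cfg$n_selected_loci <- 0L
      pop <- simulate_population(cfg)
      cl <- pop$clusters
      f <- wc_fst_sites(pop$variants, names(cl)[cl == "A"],
                        names(cl)[cl == "B"])
      sum(f$a) / sum(f$a + f$b + f$c)
    }, 0))
  }, 0)
  expect_true(all(diff(realised) > 0))
})

test_that("phenotype variance partitions to the configured heritability", {
  cfg <- sim_config(n_samples_per_cluster = 200, n_clusters = 3,
                    n_sites = 40,
                    chrom_lengths = c(chr1 = 100000),
                    n_selected_loci = 0, n_sweeps = 1, missing_rate = 0,
                    qtn_spec = list(list(trait = "starch_content",
                                         effect = 5, site = 20)),
                    h2 = 0.6, seed = 9)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes_and_expression(pop, config = cfg)
  g <- ph$genetic_values["starch_content", ]
  y <- ph$phenotypes$value[ph$phenotypes$trait == "starch_content"]
  h2_hat <- var(g) / var(y)
  expect_lt(abs(h2_hat - 0.6), 0.1)
})

test_that("h2 = 1 makes the trait an exact affine function of dosage", {
  cfg <- small_config(h2 = 1, missing_rate = 0, seed = 33,
                      qtn_spec = list(list(trait = "starch_content",
                                           effect = 4, site = 50)))
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes_and_expression(pop, config = cfg)
  snp <- pop$truth$qtn$snp_id[1]
  dos <- pop$truth$qtn_dosage[snp, ]
  y <- phenotype_means(ph$phenotypes, "starch_content", "L1")
  base <- cfg$trait_baseline[["starch_content"]]
  expect_equal(as.numeric(y[names(dos)]), as.numeric(base + 4 * dos),
               tolerance = 1e-12)
  vt <- pop$variants
  r <- suppressWarnings(glm_association(vt, ph$phenotypes, "starch_content",
                                        "L1", snp_ids = snp))
  expect_lt(r$p_value, 1e-10)
})

test_that("the planted expression gene is flagged and others are not", {
  cfg <- small_config(seed = 44)
  st <- simulate_study(cfg)
  r <- expression_by_allele(st$expression, st$variants,
                            st$truth$expression_snp,
                            st$truth$expression_gene)
  expect_true(r$flagged)
  # fold orientation depends on which allele is minor within the
  # expression subset; the planted 4x contrast shows either way
  expect_true(r$fold_change >= 2 || r$fold_change <= 0.5)
  others <- setdiff(unique(st$expression$gene_id), st$truth$expression_gene)
  flags <- vapply(others[1:10], function(g)
    expression_by_allele(st$expression, st$variants,
                         st$truth$expression_snp, g)$flagged, TRUE)
  expect_lt(mean(flags), 0.2)
})

test_that("study truth is coherent and round-trips through JSON", {
  cfg <- small_config(seed = 55)
  st <- simulate_study(cfg)
  # QTN SNPs are stop-gain SNPs inside their host genes
  cons <- classify_consequence(
    st$variants$sites[st$variants$sites$id %in% st$truth$qtn$snp_id, ],
    st$models, st$genome)
  planted <- cons[!is.na(cons$gene_id) &
                    paste(cons$snp_id, cons$gene_id) %in%
                    paste(st$truth$qtn$snp_id, st$truth$qtn$gene_id), ]
  expect_equal(nrow(planted), nrow(st$truth$qtn))
  expect_true(all(planted$category == "stop_gained"))
  # the first QTN's host gene is the sweep anchor (dual evidence)
  expect_equal(st$truth$qtn_genes[1], st$truth$anchor_genes[1])
  # truth serialisation round-trip
  f <- tempfile(fileext = ".json")
  write_truth(st$truth, f)
  tr <- read_truth(f)
  expect_setequal(tr$selected_site_ids, st$truth$selected_site_ids)
  expect_equal(tr$qtn$snp_id, st$truth$qtn$snp_id)
  expect_equal(tr$qtn_dosage, st$truth$qtn_dosage)
  # planted IDs are disjoint from non-planted ones
  expect_false(any(st$truth$orthology_only_gene_ids %in%
                     names(st$models$ec)[lengths(st$models$ec) > 0]))
})

test_that("annotation rejects gene sets that cannot be placed", {
  cfg <- small_config()
  cfg$chrom_lengths <- c(chr1 = 20000)
  expect_error(simulate_annotation_and_orthogroups(cfg), "cannot place")
})
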