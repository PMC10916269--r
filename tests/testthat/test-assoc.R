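mk_pheno <- function(values, trait = "starch_content", location = "L1") {
  do.call(rbind, lapply(1:2, function(rep_i)
    data.frame(sample = names(values), trait = trait, location = location,
               replicate = rep_i, value = unname(values))))
}

test_that("association SNP filter applies the inclusive/strict boundaries", {
  # MAF exactly 0.05 retained: 1 alt allele among 10 diploids = 0.05
  d1 <- matrix(c(1L, rep(0L, 9)), 1, 10)
  # missing rate exactly 0.20 removed: 2 of 10 calls missing
  d2 <- matrix(c(NA, NA, rep(1L, 8)), 1, 10)
  d <- rbind(d1, d2)
  vt <- mk_vt(d)
  kept <- assoc_snp_filter(vt, colnames(vt$gt))
  expect_equal(kept, vt$sites$id[1])
  expect_error(assoc_snp_filter(vt, c("zz1", "zz2")), "no phenotyped")
})

test_that("association filter survivors match hand enumeration on 20 SNPs", {
  set.seed(77)
  n <- 40
  d <- matrix(rbinom(20 * n, 2, rep(runif(20, 0.02, 0.5), n)), 20, n)
  d[matrix(runif(20 * n) < 0.15, 20, n)] <- NA
  vt <- mk_vt(d)
  kept <- assoc_snp_filter(vt, colnames(vt$gt))
  by_hand <- vapply(seq_len(20), function(i) {
    g <- d[i, ]
    miss <- mean(is.na(g))
    p <- sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
    min(p, 1 - p) >= 0.05 && miss < 0.2
  }, TRUE)
  expect_setequal(kept, vt$sites$id[by_hand])
})

test_that("noise-free dosage phenotype gives a vanishing p-value", {
  set.seed(19)
  g <- rbinom(45, 2, 0.4)
  vt <- mk_vt(rbind(g))
  ph <- mk_pheno(setNames(3 + 2 * g, colnames(vt$gt)))
  r <- suppressWarnings(glm_association(vt, ph, "starch_content", "L1"))
  expect_lt(r$p_value, 1e-10)
  expect_true(r$retained)
  expect_match(r$qtn, "^qSC1\\.1$")
})

test_that("constant phenotypes and degenerate inputs are handled", {
  g <- rbinom(30, 2, 0.5)
  vt <- mk_vt(rbind(g))
  ph <- mk_pheno(setNames(rep(5, 30), colnames(vt$gt)))
  expect_error(glm_association(vt, ph, "starch_content", "L1"),
               "distinct phenotype")
  # constant phenotype with >2 tied-but-distinct values: F undefined -> p 1
  ph2 <- mk_pheno(setNames(c(rep(5, 28), 5.1, 4.9), colnames(vt$gt)))
  vt0 <- mk_vt(rbind(rep(0:1, 15)))
  r <- glm_association(vt0, ph2, "starch_content", "L1")
  expect_true(r$p_value > 0.05 || !r$retained)
})

test_that("null markers are retained at the nominal rate with uniform p", {
  set.seed(47)
  n <- 60
  d <- matrix(rbinom(2000 * n, 2, rep(runif(2000, 0.1, 0.9), n)), 2000, n)
  vt <- mk_vt(d)
  ph <- mk_pheno(setNames(rnorm(n), colnames(vt$gt)))
  r <- glm_association(vt, ph, "starch_content", "L1")
  expect_lt(sum(r$retained), qbinom(0.999, 2000, 0.001) + 1)
  expect_gt(suppressWarnings(ks.test(r$p_value, "punif")$p.value), 0.01)
})

test_that("allele effects match the t-oracle and the stated definition", {
  set.seed(53)
  g <- c(rep(0L, 12), rep(1L, 5), rep(2L, 3))
  vt <- mk_vt(rbind(g))
  y <- setNames(10 + 5 * (g >= 1) + rnorm(20, 0, 0.5), colnames(vt$gt))
  ph <- mk_pheno(y)
  ae <- allele_effect(vt, ph, vt$sites$id[1], "starch_content", "L1")
  o <- welch_oracle(y[g >= 1], y[g == 0])
  expect_equal(ae$t, unname(o["t"]), tolerance = 1e-10)
  expect_equal(ae$p_value, unname(o["p"]), tolerance = 1e-10)
  expect_equal(ae$effect_pct,
               100 * (mean(y[g >= 1]) - mean(y[g == 0])) /
                 abs(mean(y[g == 0])), tolerance = 1e-10)
  # 1.5x group mean gives +50%
  y2 <- setNames(ifelse(g >= 1, 15, 10), colnames(vt$gt))
  suppressWarnings({
    ae2 <- allele_effect(vt, mk_pheno(y2), vt$sites$id[1],
                         "starch_content", "L1")
  })
  expect_equal(ae2$effect_pct, 50)
  # identical groups: t = 0, p = 1, effect 0
  y3 <- setNames(rep(7, 20), colnames(vt$gt))
  ae3 <- allele_effect(vt, mk_pheno(y3), vt$sites$id[1],
                       "starch_content", "L1")
  expect_equal(ae3$t, 0)
  expect_equal(ae3$p_value, 1)
  expect_equal(ae3$effect_pct, 0)
})

test_that("expression summaries transform and flag as documented", {
  # TPM replicates (4,4,4): mean 4, log2(mean+1) = log2 5
  expr <- data.frame(gene_id = "gE", sample = rep(c("s01", "s02", "s03",
                                                    "s04"), each = 3),
                     replicate = rep(1:3, 4),
                     tpm = rep(c(4, 4, 16, 16), each = 3))
  vt <- mk_vt(rbind(c(0L, 0L, 2L, 2L)))
  r <- expression_by_allele(expr, vt, vt$sites$id[1], "gE")
  expect_equal(r$per_sample$mean_tpm[r$per_sample$sample == "s01"], 4)
  expect_equal(r$per_sample$log2_tpm[r$per_sample$sample == "s01"], log2(5))
  expect_equal(r$fold_change, 4)
  expect_true(r$flagged)
  # identical groups: fold 1, not flagged
  expr1 <- transform(expr, tpm = 4)
  r1 <- expression_by_allele(expr1, vt, vt$sites$id[1], "gE")
  expect_equal(r1$fold_change, 1)
  expect_false(r1$flagged)
  # missing replicate warns and averages the rest
  expect_warning(expression_by_allele(expr[-1, ], vt, vt$sites$id[1], "gE"),
                 "replicates")
  expect_error(expression_by_allele(expr, vt, vt$sites$id[1], "nope"),
               "absent")
})

test_that("cross-referencing returns the intersection with labels", {
  hits <- data.frame(gene_id = c("g1", "g2", "g3"), trait = "hardness")
  out <- list(A_vs_B = c("g2", "g9"), B_vs_C = c("g2", "g3"))
  r <- cross_reference_selection(hits, out)
  expect_setequal(r$gene_id, c("g2", "g3"))
  expect_equal(r$pairs[r$gene_id == "g2"], "A_vs_B,B_vs_C")
  expect_equal(r$traits[r$gene_id == "g2"], "hardness")
  expect_equal(nrow(cross_reference_selection(hits,
                                              list(A_vs_B = character(0)))),
               0)
})

test_that("optional BH adjustment gates on adjusted p-values", {
  set.seed(83)
  n <- 50
  d <- matrix(rbinom(50 * n, 2, rep(runif(50, 0.2, 0.8), n)), 50, n)
  g <- d[1, ]
  vt <- mk_vt(d, pos = seq_len(50) * 100)
  ph <- mk_pheno(setNames(g + rnorm(n, 0, 0.1), colnames(vt$gt)))
  raw <- suppressWarnings(glm_association(vt, ph, "starch_content", "L1"))
  bh <- suppressWarnings(glm_association(vt, ph, "starch_content", "L1",
                                         adjust = "BH"))
  expect_true(all(bh$p_adjust >= bh$p_value))
  expect_true(all(bh$retained == (bh$p_adjust <= 0.001)))
  expect_true(bh$retained[1])  # the true signal survives adjustment
  expect_lte(sum(bh$retained), sum(raw$retained))
})
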