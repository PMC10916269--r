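test_that("AIC model selection recovers the generating family", {
  set.seed(17)
  gens <- list(
    weibull = function(n) rweibull(n, shape = 1.5, scale = 0.1),
    norm = function(n) rnorm(n, 0.3, 0.05),
    lnorm = function(n) rlnorm(n, log(0.1), 0.4),
    gamma = function(n) rgamma(n, shape = 3, rate = 20))
  for (fam in names(gens)) {
    wins <- 0
    for (rep_i in 1:20) {
      fit <- fit_fst_distribution(gens[[fam]](3000))
      wins <- wins + (fit$best == fam)
    }
    expect_gte(wins, 19)
  }
})

test_that("normal log-likelihood matches the closed form", {
  set.seed(23)
  x <- rnorm(500, 0.2, 0.03)
  fit <- fit_fst_distribution(x)
  n <- length(x)
  mu <- mean(x)
  s2 <- var(x) * (n - 1) / n
  ll <- -n / 2 * log(2 * pi * s2) - n / 2
  expect_equal(fit$fits$norm$loglik, ll, tolerance = 1e-9)
  expect_equal(fit$fits$norm$aic, 4 - 2 * ll, tolerance = 1e-9)
})

test_that("too few positive values raise the empirical-quantile advice", {
  expect_error(fit_fst_distribution(c(rep(-1, 40), runif(10))), "empirical")
})

test_that("Weibull quantile cutoffs match the analytic forms", {
  mk_fit <- function(shape, scale) {
    structure(list(fits = list(weibull = list(
      family = "weibull", estimate = c(shape = shape, scale = scale),
      loglik = 0, aic = 0, n_obs = 100)), best = "weibull"),
      class = "fst_distribution_fit")
  }
  lam <- 0.07
  expect_equal(outlier_cutoff(mk_fit(1, lam)), lam * log(20),
               tolerance = 1e-9)
  expect_equal(outlier_cutoff(mk_fit(2, lam)), lam * sqrt(log(20)),
               tolerance = 1e-9)
  expect_error(outlier_cutoff(mk_fit(1, lam), q = 1.2), "\\(0, 1\\)")
  # Monte-Carlo convergence of the empirical quantile to the analytic one
  set.seed(29)
  err <- vapply(c(1e3, 1e4, 1e5), function(n)
    abs(quantile(rweibull(n, 1, lam), 0.95) - lam * log(20)), 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.005)
})

test_that("outlier windows respect the inclusive cutoff", {
  set.seed(5)
  w <- data.frame(seqname = "chr1", start = seq(1, by = 10000,
                                                length.out = 200),
                  end = seq(50000, by = 10000, length.out = 200),
                  n_variants = 10,
                  weighted_fst = rweibull(200, 1.5, 0.05),
                  truncated = FALSE, pair = "A_vs_B")
  os <- outlier_windows(w, q = 0.95)
  expect_true(all(os$windows$weighted_fst >= os$cutoff))
  expect_true(all(w$weighted_fst[!paste(w$start) %in%
                                   paste(os$windows$start)] < os$cutoff))
})

test_that("gene intersection honours 1 bp overlaps and seqname checks", {
  # g1 shares exactly its first base with the window; g2 starts one base
  # past the window end and must not be reported
  models <- gene_model_set(
    genes = data.frame(gene_id = c("g1", "g2"), seqname = "chr1",
                       strand = "+", start = c(60000L, 60001L),
                       end = c(61000L, 71000L)),
    exons = data.frame(gene_id = c("g1", "g2"), start = c(60000L, 60001L),
                       end = c(61000L, 71000L)),
    cds = data.frame(gene_id = character(0), start = integer(0),
                     end = integer(0)))
  w <- data.frame(seqname = "chr1", start = 10001, end = 60000,
                  n_variants = 5, weighted_fst = 0.5, truncated = FALSE,
                  pair = "A_vs_B")
  expect_equal(intersect_outliers_with_genes(w, models), "g1")
  w59999 <- transform(w, end = 59999)
  expect_equal(length(intersect_outliers_with_genes(w59999, models)), 0)
  wbad <- transform(w, seqname = "chrX")
  expect_error(intersect_outliers_with_genes(wbad, models), "chrX")
})

test_that("gene intersection matches a brute-force overlap oracle", {
  set.seed(41)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      seqname = sample(c("chr1", "chr2"), 60, TRUE),
                      strand = "+",
                      start = sample.int(200000, 60))
  genes$end <- genes$start + sample.int(5000, 60)
  models <- gene_model_set(genes,
                           data.frame(gene_id = genes$gene_id,
                                      start = genes$start, end = genes$end),
                           data.frame(gene_id = character(0),
                                      start = integer(0), end = integer(0)))
  w <- data.frame(seqname = sample(c("chr1", "chr2"), 15, TRUE),
                  start = sample.int(200000, 15))
  w$end <- w$start + 49999
  w$n_variants <- 1
  w$weighted_fst <- 0.1
  w$truncated <- FALSE
  w$pair <- "A_vs_B"
  got <- intersect_outliers_with_genes(w, models)
  want <- genes$gene_id[overlap_oracle(genes, w)]
  expect_setequal(got, want)
})

test_that("common regions are the three-way overlaps, merged", {
  mk <- function(start, end) data.frame(seqname = rep("chr1", length(start)),
                                        start = start, end = end,
                                        n_variants = rep(1, length(start)),
                                        weighted_fst = rep(1, length(start)),
                                        truncated = rep(FALSE, length(start)),
                                        pair = rep("x", length(start)))
  sets <- list(mk(c(1, 100000), c(50000, 150000)),
               mk(40000, 90000),
               mk(45000, 120000))
  cr <- common_regions(sets)
  expect_equal(cr$start, 45000)
  expect_equal(cr$end, 50000)
  # a pair with no outlier windows empties the intersection
  sets2 <- c(sets, list(mk(integer(0), integer(0))))
  expect_equal(nrow(common_regions(sets2)), 0)
})

test_that("hypergeometric enrichment equals exact tail enumeration", {
  background <- sprintf("g%03d", 1:100)
  annotation <- data.frame(gene_id = background[1:10], term = "T")
  selection <- c(background[1:5], background[90:94])
  r <- enrichment_test(selection, background, annotation)
  expect_equal(r$p_value, hyper_tail_oracle(5, 10, 100, 10),
               tolerance = 1e-12)
  # selection = background gives p = 1
  r2 <- enrichment_test(background, background, annotation)
  expect_equal(r2$p_value, 1)
  # selection without annotated genes gives p = 1
  r3 <- enrichment_test(background[50:59], background, annotation)
  expect_equal(r3$p_value, 1)
  expect_error(enrichment_test("not_there", background, annotation),
               "subset")
})
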