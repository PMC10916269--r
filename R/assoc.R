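#' Association-panel SNP filter
#'
#' Keeps candidate SNPs with minor allele frequency at or above `maf`
#' (computed over non-missing alleles among the phenotyped samples;
#' inclusive boundary) and per-site missing rate strictly below
#' `max_missing_rate`.
#'
#' @param vt a biallelic `variant_table`.
#' @param samples phenotyped sample names; must intersect the genotyped
#'   samples.
#' @param snp_ids optional subset of SNP IDs to consider.
#' @param maf minimum minor allele frequency (default 0.05, inclusive).
#' @param max_missing_rate maximum missing-call fraction (default 0.2,
#'   strict).
#' @return character vector of retained SNP IDs.
#' @export
assoc_snp_filter <- function(vt, samples, snp_ids = NULL, maf = 0.05,
                             max_missing_rate = 0.2) {
  samples <- intersect(samples, sample_names(vt))
  if (!length(samples))
    stop("no phenotyped sample is present in the genotype table")
  vt <- subset_samples(vt, samples)
  if (!is.null(snp_ids)) vt <- subset_sites(vt, vt$sites$id %in% snp_ids)
  keep <- site_maf(vt) >= maf & rowMeans(is.na(vt$gt)) < max_missing_rate
  vt$sites$id[keep]
}

#' Average phenotype replicates per sample and location
#'
#' @param phenotypes data.frame with columns `sample`, `trait`, `location`,
#'   `replicate`, `value`.
#' @param trait,location trait name and location to extract.
#' @return named numeric vector of per-sample means.
#' @export
phenotype_means <- function(phenotypes, trait, location) {
  ph <- phenotypes[phenotypes$trait == trait &
                     phenotypes$location == location, , drop = FALSE]
  if (!nrow(ph)) stop("no phenotype rows for trait '", trait,
                      "' at location '", location, "'")
  tapply(ph$value, ph$sample, mean)
}

trait_abbrev <- function(trait) {
  known <- c(hardness = "H", gumminess = "G", springiness = "Sp",
             cohesiveness = "C", total_area = "Ta", starch_content = "SC",
             brown_index = "BI", hue_index = "HI", yellow_index = "YI",
             whiteness_index = "WI")
  ifelse(trait %in% names(known), known[trait],
         toupper(substr(gsub("[^A-Za-z]", "", trait), 1, 2)))
}

#' Candidate-gene GLM association scan
#'
#' For each SNP, fits an ordinary least-squares model of the per-sample
#' trait mean on the genotype written as a class factor (2-3 classes; empty
#' classes dropped) and reports the overall F-test p-value, one analysis per
#' location with no covariates. SNPs with `p <= p_max` are flagged as
#' retained. Quantitative-trait-nucleotide names are assigned to retained
#' hits as `q<TraitAbbrev><chrom>.<rank>` in genomic order per chromosome.
#'
#' @param vt a biallelic `variant_table` (already MAF/missingness filtered).
#' @param phenotypes phenotype table (`sample`, `trait`, `location`,
#'   `replicate`, `value`).
#' @param trait,location trait and location analysed.
#' @param snp_ids optional subset of SNP IDs to test.
#' @param p_max retention threshold on the F-test p-value (default 0.001,
#'   inclusive).
#' @param encoding `"factor"` (genotype classes; default) or `"dosage"`
#'   (additive 0/1/2 regression).
#' @param adjust `"none"` (default: retention uses the raw p-values and the
#'   fixed `p_max` gate alone) or `"BH"` (Benjamini-Hochberg adjustment
#'   across the tested SNPs before the gate).
#' @return data.frame with one row per tested SNP: `snp_id`, `trait`,
#'   `location`, `n`, `n_classes`, `p_value`, `retained`, `major`, `minor`,
#'   `qtn` (NA unless retained).
#' @export
glm_association <- function(vt, phenotypes, trait, location, snp_ids = NULL,
                            p_max = 0.001, encoding = c("factor", "dosage"),
                            adjust = c("none", "BH")) {
  encoding <- match.arg(encoding)
  adjust <- match.arg(adjust)
  y_all <- phenotype_means(phenotypes, trait, location)
  samples <- intersect(names(y_all), sample_names(vt))
  if (!length(samples))
    stop("no phenotyped sample is present in the genotype table")
  if (length(unique(round(y_all[samples], 12))) < 3)
    stop("fewer than 3 distinct phenotype values for trait '", trait, "'")
  vt <- subset_samples(vt, samples)
  if (!is.null(snp_ids)) vt <- subset_sites(vt, vt$sites$id %in% snp_ids)
  d <- gt_dosage(vt)
  y <- y_all[samples]
  rows <- vector("list", n_sites(vt))
  for (i in seq_len(n_sites(vt))) {
    g <- d[i, ]
    ok <- !is.na(g)
    gi <- g[ok]
    yi <- y[ok]
    p_alt <- mean(gi) / 2
    alleles <- c(vt$sites$ref[i], vt$sites$alt[i])
    major <- if (p_alt > 0.5) alleles[2] else alleles[1]
    minor <- setdiff(alleles, major)[1]
    classes <- length(unique(gi))
    if (classes < 2 || stats::var(yi) == 0) {
      pv <- 1
    } else {
      x <- if (encoding == "factor") factor(gi) else gi
      fit <- stats::lm(yi ~ x)
      an <- stats::anova(fit)
      pv <- an[["Pr(>F)"]][1]
      if (is.na(pv)) pv <- 1
    }
    rows[[i]] <- data.frame(
      snp_id = vt$sites$id[i], seqname = vt$sites$seqname[i],
      pos = vt$sites$pos[i], trait = trait, location = location,
      n = sum(ok), n_classes = classes, p_value = pv,
      retained = pv <= p_max, major = major, minor = minor,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out$retained <- out$p_adjust <= p_max
  }
  out$qtn <- NA_character_
  if (any(out$retained)) {
    ret <- which(out$retained)
    ord <- ret[order(out$seqname[ret], out$pos[ret])]
    chrom <- gsub("[^0-9]", "", out$seqname[ord])
    chrom[chrom == ""] <- out$seqname[ord][chrom == ""]
    rank <- stats::ave(seq_along(ord), chrom, FUN = seq_along)
    out$qtn[ord] <- paste0("q", trait_abbrev(trait), chrom, ".", rank)
  }
  rownames(out) <- NULL
  out
}

#' Allele-group effect at a SNP
#'
#' Compares the trait between samples carrying the minor allele and samples
#' homozygous for the major allele with a two-tailed t-test, and reports the
#' group-difference effect as a percentage of the major-group mean:
#' `100 * (mean_minor - mean_major) / |mean_major|` (sign preserved).
#'
#' @param vt a biallelic `variant_table`.
#' @param phenotypes phenotype table.
#' @param snp SNP ID.
#' @param trait,location trait and location.
#' @param var_equal passed to [stats::t.test()] (`FALSE` = Welch, default).
#' @return list with `group_means` (named: major, minor), `n` (named
#'   counts), `t`, `p_value`, `effect_pct`, `major`, `minor`.
#' @export
allele_effect <- function(vt, phenotypes, snp, trait, location,
                          var_equal = FALSE) {
  i <- match(snp, vt$sites$id)
  if (is.na(i)) stop("SNP ", snp, " not found")
  y_all <- phenotype_means(phenotypes, trait, location)
  samples <- intersect(names(y_all), sample_names(vt))
  g <- gt_dosage(subset_samples(subset_sites(vt, i), samples))[1, ]
  ok <- !is.na(g) & !is.na(y_all[samples])
  g <- g[ok]
  y <- as.numeric(y_all[samples])[ok]
  p_alt <- mean(g) / 2
  minor_is_alt <- p_alt <= 0.5
  carrier <- if (minor_is_alt) g >= 1 else g <= 1
  alleles <- c(vt$sites$ref[i], vt$sites$alt[i])
  major <- if (minor_is_alt) alleles[1] else alleles[2]
  minor <- setdiff(alleles, major)[1]
  if (sum(carrier) < 2 || sum(!carrier) < 2)
    stop("each allele group needs >= 2 samples at ", snp)
  m_major <- mean(y[!carrier])
  m_minor <- mean(y[carrier])
  if (stats::var(y[carrier]) == 0 && stats::var(y[!carrier]) == 0) {
    # both groups constant: the t statistic degenerates
    tt <- if (m_minor == m_major) list(statistic = c(t = 0), p.value = 1)
    else list(statistic = c(t = sign(m_minor - m_major) * Inf), p.value = 0)
  } else {
    tt <- stats::t.test(y[carrier], y[!carrier], var.equal = var_equal)
  }
  list(group_means = c(major = m_major, minor = m_minor),
       n = c(major = sum(!carrier), minor = sum(carrier)),
       t = unname(tt$statistic), p_value = tt$p.value,
       effect_pct = 100 * (m_minor - m_major) / abs(m_major),
       major = major, minor = minor)
}

#' Expression-by-allele comparison for one gene
#'
#' Summarises expression per sample as the mean TPM over replicates and its
#' `log2(mean + 1)` transform, then compares the allele groups at a SNP
#' (minor-allele carriers vs major homozygotes) by the ratio of group mean
#' TPMs. Genes whose fold change (in either direction) reaches
#' `fold_threshold` are flagged.
#'
#' @param expression data.frame with columns `gene_id`, `sample`,
#'   `replicate`, `tpm`.
#' @param vt a biallelic `variant_table`.
#' @param snp SNP ID defining the allele groups.
#' @param gene gene ID present in the expression table.
#' @param fold_threshold flagging threshold on the fold change (default 2).
#' @param expected_replicates replicate count per sample; fewer triggers a
#'   warning and the mean is taken over the available ones.
#' @return list with `per_sample` (data.frame `sample`, `mean_tpm`,
#'   `log2_tpm`, `group`), `group_means`, `fold_change` (minor over major),
#'   `flagged`, `major`, `minor`.
#' @export
expression_by_allele <- function(expression, vt, snp, gene,
                                 fold_threshold = 2, expected_replicates = 3) {
  ex <- expression[expression$gene_id == gene, , drop = FALSE]
  if (!nrow(ex)) stop("gene ", gene, " absent from the expression table")
  nrep <- table(ex$sample)
  if (any(nrep < expected_replicates))
    warning("sample(s) with fewer than ", expected_replicates,
            " replicates for ", gene, "; averaging available replicates")
  mean_tpm <- tapply(ex$tpm, ex$sample, mean)
  i <- match(snp, vt$sites$id)
  if (is.na(i)) stop("SNP ", snp, " not found")
  samples <- intersect(names(mean_tpm), sample_names(vt))
  g <- gt_dosage(subset_samples(subset_sites(vt, i), samples))[1, ]
  p_alt <- mean(g, na.rm = TRUE) / 2
  minor_is_alt <- p_alt <= 0.5
  carrier <- if (minor_is_alt) g >= 1 else g <= 1
  alleles <- c(vt$sites$ref[i], vt$sites$alt[i])
  per <- data.frame(sample = samples,
                    mean_tpm = as.numeric(mean_tpm[samples]),
                    log2_tpm = log2(as.numeric(mean_tpm[samples]) + 1),
                    group = ifelse(carrier, "minor", "major"),
                    stringsAsFactors = FALSE)
  per <- per[!is.na(g), , drop = FALSE]
  gm <- tapply(per$mean_tpm, per$group, mean)
  fold <- if (all(c("major", "minor") %in% names(gm)) && gm[["major"]] > 0)
    gm[["minor"]] / gm[["major"]] else NA_real_
  list(per_sample = per, group_means = gm, fold_change = fold,
       flagged = isTRUE(fold >= fold_threshold | fold <= 1 / fold_threshold),
       major = if (minor_is_alt) alleles[1] else alleles[2],
       minor = if (minor_is_alt) alleles[2] else alleles[1])
}

#' Genes supported by both the selection scan and the association scan
#'
#' @param hits association results (rows of [glm_association()] joined to a
#'   gene column, or any data.frame with `gene_id` and optionally `trait`).
#' @param outlier_genes named list mapping cluster-pair label to the gene
#'   IDs overlapping that pair's outlier windows.
#' @return data.frame with columns `gene_id`, `pairs` (comma-joined cluster
#'   pairs with divergence evidence), `traits` (comma-joined associated
#'   traits).
#' @export
cross_reference_selection <- function(hits, outlier_genes) {
  sel <- unique(unlist(outlier_genes))
  genes <- unique(stats::na.omit(hits$gene_id))
  both <- intersect(genes, sel)
  if (!length(both))
    return(data.frame(gene_id = character(0), pairs = character(0),
                      traits = character(0)))
  rows <- lapply(both, function(g) {
    prs <- names(outlier_genes)[vapply(outlier_genes,
                                       function(x) g %in% x, TRUE)]
    trs <- if ("trait" %in% names(hits))
      sort(unique(hits$trait[!is.na(hits$gene_id) & hits$gene_id == g]))
    else character(0)
    data.frame(gene_id = g, pairs = paste(prs, collapse = ","),
               traits = paste(trs, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
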