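#' In-memory table of biallelic-capable SNP genotypes
#'
#' A `variant_table` holds per-site records (seqname, 1-based position, ref
#' allele, alt allele(s), site QUAL) together with an unphased diploid
#' genotype matrix (entries such as `"0/0"`, `"0/1"`; `NA` = missing call)
#' and a per-call read-depth (DP) matrix. It is the container every
#' downstream stage (QC filters, consequence annotation, diversity and Fst
#' estimation, association) operates on.
#'
#' @param seqname character vector of sequence names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles; `alt` may contain
#'   comma-joined alternates for multi-allelic sites.
#' @param qual numeric site qualities (Phred-scaled).
#' @param gt character matrix (sites x samples) of unphased genotypes;
#'   `"./."` is normalised to `NA`.
#' @param dp integer matrix (sites x samples) of per-call depths.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(seqname, pos, ref, alt, qual, gt, dp) {
  n <- length(pos)
  stopifnot(length(seqname) == n, length(ref) == n, length(alt) == n,
            length(qual) == n, nrow(gt) == n, nrow(dp) == n,
            ncol(gt) == ncol(dp))
  if (any(pos < 1)) stop("positions must be >= 1")
  if (any(ref == alt)) stop("ref allele equal to alt allele at site ",
                            which(ref == alt)[1])
  gt <- as.matrix(gt)
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  bad <- !is.na(gt) & !grepl("^[0-9]+[/|][0-9]+$", gt)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed genotype '", gt[bad][1], "' at site ",
         seqname[i[1]], ":", pos[i[1]])
  }
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  amax <- suppressWarnings(apply(gt, 1, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(0L)
    max(as.integer(unlist(strsplit(g, "[/|]"))))
  }))
  if (any(amax > n_alt)) {
    i <- which(amax > n_alt)[1]
    stop("genotype allele index exceeds alternate count at site ",
         seqname[i], ":", pos[i])
  }
  if (is.null(colnames(gt))) colnames(gt) <- paste0("sample", seq_len(ncol(gt)))
  dimnames(dp) <- dimnames(gt)
  structure(list(
    sites = data.frame(seqname = as.character(seqname), pos = as.integer(pos),
                       id = snp_id(seqname, pos), ref = ref, alt = alt,
                       qual = as.numeric(qual), stringsAsFactors = FALSE),
    gt = gt, dp = dp), class = "variant_table")
}

#' SNP identifiers of the form `S{chrom-number}_{pos}`
#'
#' Matches the field convention for naming SNPs after the chromosome number
#' and physical position (e.g. `S4_20715506`). Non-digit characters in the
#' seqname are dropped; a seqname without digits is used verbatim.
#'
#' @param seqname,pos vectors of sequence names and 1-based positions.
#' @return character vector of SNP IDs.
#' @export
snp_id <- function(seqname, pos) {
  num <- gsub("[^0-9]", "", seqname)
  num <- ifelse(num == "", seqname, sub("^0+(?=.)", "", num, perl = TRUE))
  paste0("S", num, "_", as.integer(pos))
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", ncol(x$gt), "samples on",
      length(unique(x$sites$seqname)), "sequence(s)\n")
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt a `variant_table`.
#' @return integer count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) ncol(vt$gt)

#' @rdname n_sites
#' @export
sample_names <- function(vt) colnames(vt$gt)

#' Subset a variant table by site index or sample names
#' @param vt a `variant_table`.
#' @param i integer or logical site index.
#' @param samples character vector of sample names to keep.
#' @return a `variant_table`.
#' @export
subset_sites <- function(vt, i) {
  vt$sites <- vt$sites[i, , drop = FALSE]
  rownames(vt$sites) <- NULL
  vt$gt <- vt$gt[i, , drop = FALSE]
  vt$dp <- vt$dp[i, , drop = FALSE]
  vt
}

#' @rdname subset_sites
#' @export
subset_samples <- function(vt, samples) {
  miss <- setdiff(samples, colnames(vt$gt))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  vt$gt <- vt$gt[, samples, drop = FALSE]
  vt$dp <- vt$dp[, samples, drop = FALSE]
  vt
}

is_biallelic <- function(vt) !grepl(",", vt$sites$alt, fixed = TRUE)

#' Alternate-allele dosage matrix
#'
#' Converts unphased diploid genotype strings of a biallelic table to
#' 0/1/2 counts of the alternate allele (`NA` = missing call).
#'
#' @param vt a biallelic `variant_table`.
#' @return integer matrix, sites x samples.
#' @export
gt_dosage <- function(vt) {
  if (!all(is_biallelic(vt))) stop("gt_dosage requires a biallelic table")
  g <- vt$gt
  d <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  d[g %in% c("0/0", "0|0")] <- 0L
  d[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[g %in% c("1/1", "1|1")] <- 2L
  left <- !is.na(g) & is.na(d)
  if (any(left)) stop("unexpected biallelic genotype string: ", g[left][1])
  d
}

#' Per-site call rate and minor allele frequency
#'
#' MAF is computed over non-missing alleles only; monomorphic sites have
#' MAF 0. Multi-allelic sites return `NA` (they are removed before MAF
#' matters in this pipeline).
#'
#' @param vt a `variant_table`.
#' @return numeric vector, one value per site.
#' @export
site_call_rate <- function(vt) rowMeans(!is.na(vt$gt))

#' @rdname site_call_rate
#' @export
site_maf <- function(vt) {
  out <- rep(NA_real_, n_sites(vt))
  bi <- is_biallelic(vt)
  if (any(bi)) {
    d <- gt_dosage(subset_sites(vt, which(bi)))
    nn <- rowSums(!is.na(d)) * 2
    ac <- rowSums(d, na.rm = TRUE)
    p <- ifelse(nn > 0, ac / nn, NA_real_)
    out[bi] <- pmin(p, 1 - p)
  }
  out
}
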