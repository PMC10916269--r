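#' Per-site nucleotide diversity
#'
#' Unbiased per-site pairwise diversity for biallelic SNPs: with `n`
#' non-missing alleles of which `c_ref` are reference and `c_alt` alternate,
#' `pi = c_ref * c_alt / choose(n, 2)`. Sites with fewer than two non-missing
#' alleles are skipped with a warning.
#'
#' @param vt a biallelic `variant_table`.
#' @param denominator_bp optional total sequence length; when given, the
#'   summary also reports mean diversity per bp over that denominator (the
#'   usual convention when the table covers a region rather than only
#'   variable sites).
#' @return list with `sites` (data.frame seqname, pos, id, pi),
#'   `mean_pi` over usable sites and, if requested, `pi_per_bp`.
#' @export
site_pi <- function(vt, denominator_bp = NULL) {
  d <- gt_dosage(vt)
  n <- rowSums(!is.na(d)) * 2L
  c_alt <- rowSums(d, na.rm = TRUE)
  c_ref <- n - c_alt
  usable <- n >= 2
  if (any(!usable))
    warning(sum(!usable), " site(s) with < 2 non-missing alleles skipped")
  pi <- ifelse(usable, c_ref * c_alt / choose(n, 2), NA_real_)
  out <- list(sites = data.frame(seqname = vt$sites$seqname,
                                 pos = vt$sites$pos, id = vt$sites$id,
                                 pi = pi, stringsAsFactors = FALSE),
              mean_pi = mean(pi[usable]))
  if (!is.null(denominator_bp))
    out$pi_per_bp <- sum(pi[usable]) / denominator_bp
  out
}

#' Per-site Weir-Cockerham Fst variance components for two populations
#'
#' Direct evaluation of the Weir & Cockerham (1984) two-level estimator for
#' diploids at biallelic sites: variance components `a` (among populations),
#' `b` (among individuals within populations) and `c` (within individuals),
#' with the per-site estimate `theta = a / (a + b + c)`. Missing calls are
#' excluded per site; sites monomorphic across both populations, or with
#' fewer than two non-missing genotypes in either population, are excluded.
#'
#' @param vt a biallelic `variant_table`.
#' @param pop1,pop2 character vectors of sample names forming the two
#'   populations; must be non-empty and disjoint.
#' @return data.frame with columns `seqname`, `pos`, `id`, `a`, `b`, `c`,
#'   `theta` (one row per retained site).
#' @export
wc_fst_sites <- function(vt, pop1, pop2) {
  if (!length(pop1) || !length(pop2)) stop("both populations must be non-empty")
  if (length(intersect(pop1, pop2))) stop("populations must be disjoint")
  d1 <- gt_dosage(subset_samples(vt, pop1))
  d2 <- gt_dosage(subset_samples(vt, pop2))
  n1 <- rowSums(!is.na(d1))
  n2 <- rowSums(!is.na(d2))
  p1 <- rowSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- rowMeans(d1 == 1L, na.rm = TRUE)
  h2 <- rowMeans(d2 == 1L, na.rm = TRUE)

  keep <- n1 >= 2 & n2 >= 2
  poly <- rep(FALSE, length(keep))
  poly[keep] <- (p1[keep] * n1[keep] + p2[keep] * n2[keep]) /
    (n1[keep] + n2[keep]) > 0 &
    (p1[keep] * n1[keep] + p2[keep] * n2[keep]) / (n1[keep] + n2[keep]) < 1
  keep <- keep & poly

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  out <- data.frame(seqname = vt$sites$seqname, pos = vt$sites$pos,
                    id = vt$sites$id, a = a, b = b, c = cc,
                    theta = a / (a + b + cc), stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Fst components for every cluster pair
#'
#' @param vt a biallelic `variant_table`.
#' @param clusters named character/factor vector mapping sample name to
#'   cluster label (or a data.frame with columns `sample`, `cluster`).
#' @return named list of [wc_fst_sites()] data.frames, one per unordered
#'   cluster pair, named `"A_vs_B"` style.
#' @export
pairwise_fst_sites <- function(vt, clusters) {
  if (is.data.frame(clusters))
    clusters <- stats::setNames(as.character(clusters$cluster), clusters$sample)
  labs <- sort(unique(as.character(clusters)))
  if (length(labs) < 2)
    stop("at least two clusters are required for pairwise Fst")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr)
    wc_fst_sites(vt, names(clusters)[clusters == pr[1]],
                 names(clusters)[clusters == pr[2]]))
  names(out) <- vapply(pairs, function(pr) paste0(pr[1], "_vs_", pr[2]), "")
  out
}

#' Sliding-window weighted Fst
#'
#' Tiles each sequence with windows of `window` bp advancing by `step` bp,
#' anchored at position 1, and reports the ratio-of-sums estimator
#' `sum(a) / sum(a + b + c)` over the sites falling in each window. Windows
#' containing no retained site are omitted. A sequence shorter than the
#' window yields a single truncated window flagged in the `truncated`
#' column.
#'
#' @param components per-site components from [wc_fst_sites()].
#' @param chrom_lengths named numeric vector of sequence lengths.
#' @param window,step window size and step in bp (defaults 50000 and 10000).
#' @param pair optional label stored in the `pair` column.
#' @return data.frame with columns `seqname`, `start`, `end`, `n_variants`,
#'   `weighted_fst`, `truncated`, `pair`.
#' @export
windowed_fst <- function(components, chrom_lengths, window = 50000,
                         step = 10000, pair = NA_character_) {
  res <- list()
  for (sq in names(chrom_lengths)) {
    L <- chrom_lengths[[sq]]
    truncated <- window > L
    starts <- if (truncated) 1 else seq(1, L - window + 1, by = step)
    ends <- pmin(starts + window - 1, L)
    cs <- components[components$seqname == sq, , drop = FALSE]
    if (!nrow(cs)) next
    o <- order(cs$pos)
    pos <- cs$pos[o]
    ca <- cumsum(cs$a[o])
    cabc <- cumsum((cs$a + cs$b + cs$c)[o])
    cn <- seq_along(pos)
    lo <- findInterval(starts - 1, pos)   # sites strictly before window
    hi <- findInterval(ends, pos)         # sites up to window end
    nvar <- hi - lo
    sum_at <- function(v, i) ifelse(i == 0, 0, v[pmax(i, 1)])
    wa <- sum_at(ca, hi) - sum_at(ca, lo)
    wabc <- sum_at(cabc, hi) - sum_at(cabc, lo)
    keep <- nvar >= 1
    if (!any(keep)) next
    res[[sq]] <- data.frame(
      seqname = sq, start = as.integer(starts[keep]),
      end = as.integer(ends[keep]), n_variants = as.integer(nvar[keep]),
      weighted_fst = wa[keep] / wabc[keep], truncated = truncated,
      pair = pair, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), n_variants = integer(0),
                      weighted_fst = numeric(0), truncated = logical(0),
                      pair = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
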