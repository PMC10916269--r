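#' Variant quality-control filter
#'
#' Applies the depth, site-quality and call-rate gates used before any
#' population analysis. Per-call depths outside `[min_dp, max_dp]` set the
#' call to missing *first*; sites with `QUAL < min_qual` are then removed;
#' finally sites whose post-masking call rate falls below `min_call_rate`
#' are removed (boundary inclusive: a call rate exactly at the threshold is
#' retained). Site order is preserved and the filter is idempotent.
#'
#' Defaults mirror the conventional VCFtools invocation
#' `--minDP 10 --maxDP 200 --minQ 30 --max-missing 0.5`.
#'
#' @param vt a `variant_table`.
#' @param min_qual minimum site QUAL (strict: sites below are dropped).
#' @param min_dp,max_dp inclusive per-call depth bounds; calls outside are
#'   set to missing.
#' @param min_call_rate minimum fraction of non-missing calls (inclusive).
#' @return the filtered `variant_table`.
#' @export
filter_variants <- function(vt, min_qual = 30, min_dp = 10, max_dp = 200,
                            min_call_rate = 0.5) {
  if (n_sites(vt) == 0) return(vt)
  mask <- !is.na(vt$gt) & (vt$dp < min_dp | vt$dp > max_dp)
  vt$gt[mask] <- NA_character_
  keep <- vt$sites$qual >= min_qual & site_call_rate(vt) >= min_call_rate
  subset_sites(vt, which(keep))
}

#' Greedy linkage-disequilibrium pruning
#'
#' Optional extra thinning step, disabled by default in the pipeline: scans
#' sites left to right and drops the later site of any pair within a
#' `window`-site span whose genotype-dosage correlation satisfies
#' `r^2 > max_r2`. Squared correlation is computed on non-missing dosage
#' pairs; pairs with fewer than 4 complete observations, or with a
#' monomorphic member, are never pruned.
#'
#' @param vt a biallelic `variant_table`.
#' @param window number of kept sites looked back at (default 50).
#' @param max_r2 pruning threshold (default 0.1, strict `>`).
#' @return the pruned `variant_table`.
#' @export
ld_prune <- function(vt, window = 50, max_r2 = 0.1) {
  if (n_sites(vt) < 2) return(vt)
  d <- gt_dosage(vt)
  keep <- logical(n_sites(vt))
  kept_idx <- list()
  for (i in seq_len(n_sites(vt))) {
    sq <- vt$sites$seqname[i]
    prev <- kept_idx[[sq]]
    if (!is.null(prev) && length(prev) > window)
      prev <- prev[(length(prev) - window + 1):length(prev)]
    drop <- FALSE
    for (j in rev(prev)) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (sum(ok) < 4) next
      if (stats::var(d[i, ok]) == 0 || stats::var(d[j, ok]) == 0) next
      if (stats::cor(d[i, ok], d[j, ok])^2 > max_r2) {
        drop <- TRUE
        break
      }
    }
    if (!drop) {
      keep[i] <- TRUE
      kept_idx[[sq]] <- c(kept_idx[[sq]], i)
    }
  }
  subset_sites(vt, which(keep))
}

#' Population-genetics site filter
#'
#' Applied after [filter_variants()]: keeps biallelic SNPs (single-base ref
#' and alt) with minor allele frequency at or above `maf` (computed over
#' non-missing alleles) and call rate at or above `min_call_rate`, then
#' thins greedily left-to-right so consecutive kept sites on the same
#' seqname are at least `thin_bp` apart. Mirrors
#' `--maf 0.01 --max-alleles 2 --min-alleles 2 --remove-indels
#' --max-missing 0.5 --thin 10`.
#'
#' @param vt a `variant_table`.
#' @param maf minimum minor allele frequency (inclusive).
#' @param thin_bp minimum distance in bp between kept sites; 0 disables.
#' @param min_call_rate minimum call rate (inclusive).
#' @return the filtered `variant_table`.
#' @export
popgen_site_filter <- function(vt, maf = 0.01, thin_bp = 10,
                               min_call_rate = 0.5) {
  if (n_sites(vt) == 0) return(vt)
  keep <- is_biallelic(vt) &
    nchar(vt$sites$ref) == 1 & nchar(vt$sites$alt) == 1 &
    site_call_rate(vt) >= min_call_rate
  keep[keep] <- site_maf(subset_sites(vt, which(keep))) >= maf
  vt <- subset_sites(vt, which(keep))
  if (thin_bp > 0 && n_sites(vt) > 1) {
    keep <- logical(n_sites(vt))
    last <- numeric(0)
    for (i in seq_len(n_sites(vt))) {
      sq <- vt$sites$seqname[i]
      lp <- if (sq %in% names(last)) last[[sq]] else NA_real_
      if (is.na(lp) || vt$sites$pos[i] - lp >= thin_bp) {
        keep[i] <- TRUE
        last[sq] <- vt$sites$pos[i]
      }
    }
    vt <- subset_sites(vt, which(keep))
  }
  vt
}
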