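#' Fit candidate distributions to windowed Fst values
#'
#' Fits Weibull, normal, lognormal and gamma distributions by maximum
#' likelihood (via [fitdistrplus::fitdist()]) and ranks them by
#' `AIC = 2k - 2 logL` with `k = 2` parameters per family. The three
#' positive-support families are fitted to the strictly positive values
#' only; the normal family uses all values.
#'
#' @param values numeric vector of windowed Fst values.
#' @param families subset of `c("weibull", "norm", "lnorm", "gamma")`.
#' @param min_n minimum number of strictly positive values required
#'   (default 30); below this an error advises the empirical-quantile
#'   fallback.
#' @return object of class `fst_distribution_fit`: list with `fits` (one
#'   entry per family: `family`, `estimate`, `loglik`, `aic`, `n_obs`),
#'   `best` (family name with the smallest AIC) and `values_positive`.
#' @export
fit_fst_distribution <- function(values,
                                 families = c("weibull", "norm", "lnorm",
                                              "gamma"),
                                 min_n = 30) {
  families <- match.arg(families, several.ok = TRUE)
  values <- values[is.finite(values)]
  pos <- values[values > 0]
  if (length(pos) < min_n)
    stop("only ", length(pos), " positive values; need >= ", min_n,
         " for a parametric fit - use an empirical quantile instead")
  fits <- lapply(families, function(fam) {
    x <- if (fam == "norm") values else pos
    f <- tryCatch(fitdistrplus::fitdist(x, fam, method = "mle"),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$loglik))
      return(list(family = fam, estimate = NULL, loglik = NA_real_,
                  aic = NA_real_, n_obs = length(x)))
    list(family = fam, estimate = f$estimate,
         loglik = as.numeric(f$loglik),
         aic = 2 * 2 - 2 * as.numeric(f$loglik), n_obs = length(x))
  })
  names(fits) <- families
  aics <- vapply(fits, function(f) f$aic, 0)
  if (all(is.na(aics))) stop("no family could be fitted")
  structure(list(fits = fits, best = families[which.min(aics)],
                 values_positive = pos),
            class = "fst_distribution_fit")
}

#' @export
print.fst_distribution_fit <- function(x, ...) {
  for (f in x$fits)
    cat(sprintf("%-8s logL = %10.3f  AIC = %10.3f  (n = %d)%s\n", f$family,
                f$loglik, f$aic, f$n_obs,
                if (f$family == x$best) "  <- best" else ""))
  invisible(x)
}

#' Quantile cutoff from the best-fitting Fst distribution
#'
#' Evaluates the inverse CDF of the AIC-selected family at probability `q`
#' (default 0.95, i.e. the top 5% of the theoretical distribution).
#'
#' @param fit an `fst_distribution_fit`.
#' @param q probability in (0, 1).
#' @param family override the AIC-selected family.
#' @return numeric cutoff value.
#' @export
outlier_cutoff <- function(fit, q = 0.95, family = fit$best) {
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  est <- fit$fits[[family]]$estimate
  if (is.null(est)) stop("family ", family, " was not successfully fitted")
  switch(family,
         weibull = stats::qweibull(q, est[["shape"]], est[["scale"]]),
         norm = stats::qnorm(q, est[["mean"]], est[["sd"]]),
         lnorm = stats::qlnorm(q, est[["meanlog"]], est[["sdlog"]]),
         gamma = stats::qgamma(q, est[["shape"]], est[["rate"]]),
         stop("unknown family ", family))
}

#' Select outlier windows above a fitted quantile cutoff
#'
#' @param windows data.frame from [windowed_fst()].
#' @param q outlier probability (default top 5%).
#' @param fit optional pre-computed `fst_distribution_fit`; fitted from
#'   `windows$weighted_fst` when omitted.
#' @return object of class `outlier_set`: list with `pair`, `cutoff`,
#'   `q`, `family`, `windows` (rows with `weighted_fst >= cutoff`,
#'   inclusive) and the `fit`.
#' @export
outlier_windows <- function(windows, q = 0.95, fit = NULL) {
  if (is.null(fit)) fit <- fit_fst_distribution(windows$weighted_fst)
  cutoff <- outlier_cutoff(fit, q)
  sel <- windows[windows$weighted_fst >= cutoff, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(pair = if (nrow(windows)) windows$pair[1] else NA_character_,
                 cutoff = cutoff, q = q, family = fit$best, windows = sel,
                 fit = fit),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat("outlier_set [", x$pair, "]: ", nrow(x$windows), " windows >= ",
      signif(x$cutoff, 4), " (", x$family, " q = ", x$q, ")\n", sep = "")
  invisible(x)
}

windows_granges <- function(windows) {
  GenomicRanges::GRanges(windows$seqname,
                         IRanges::IRanges(windows$start, windows$end))
}

#' Genes overlapping outlier windows
#'
#' A gene is reported when it overlaps any outlier window by at least 1 bp
#' (closed-interval semantics on both sides).
#'
#' @param outliers an `outlier_set` (or a windows data.frame).
#' @param models a [gene_model_set()].
#' @return character vector of unique gene IDs, in genomic order.
#' @export
intersect_outliers_with_genes <- function(outliers, models) {
  windows <- if (inherits(outliers, "outlier_set")) outliers$windows else outliers
  if (!nrow(windows)) return(character(0))
  bad <- setdiff(unique(windows$seqname), unique(models$genes$seqname))
  if (length(bad))
    stop("window seqnames absent from gene models: ", paste(bad, collapse = ", "))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gene_granges(models),
                                windows_granges(windows)))
  unique(models$genes$gene_id[sort(unique(S4Vectors::queryHits(hits)))])
}

#' Regions outlying in every pairwise comparison
#'
#' Computes the maximal intervals covered by at least one outlier window
#' from *every* supplied pairwise set; overlapping common intervals are
#' merged and counted as one region.
#'
#' @param outlier_sets list of `outlier_set` objects (or windows
#'   data.frames), one per cluster pair.
#' @return data.frame with columns `seqname`, `start`, `end`.
#' @export
common_regions <- function(outlier_sets) {
  grs <- lapply(outlier_sets, function(o) {
    w <- if (inherits(o, "outlier_set")) o$windows else o
    if (!nrow(w)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(windows_granges(w))
  })
  common <- Reduce(GenomicRanges::intersect, grs)
  common <- GenomicRanges::reduce(common)
  if (!length(common))
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0)))
  data.frame(seqname = as.character(GenomicRanges::seqnames(common)),
             start = GenomicRanges::start(common),
             end = GenomicRanges::end(common), stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' One-sided hypergeometric tail test (`P(X >= k)`) for over-representation
#' of each annotation term in a gene selection against a background, with
#' Benjamini-Hochberg adjustment across terms. Terms with no annotated gene
#' in the background are skipped with a warning.
#'
#' @param genes character vector of selected gene IDs (subset of
#'   `background`).
#' @param background character vector of background gene IDs.
#' @param annotation data.frame with columns `gene_id`, `term`.
#' @return data.frame with columns `term`, `n_selected`, `n_background`,
#'   `p_value`, `p_adjust`, sorted by p-value.
#' @export
enrichment_test <- function(genes, background, annotation) {
  if (!all(genes %in% background))
    stop("selection must be a subset of the background")
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  terms <- unique(annotation$term)
  N <- length(unique(background))
  n <- length(unique(genes))
  rows <- lapply(terms, function(tm) {
    tg <- unique(annotation$gene_id[annotation$term == tm])
    K <- length(tg)
    if (K == 0) {
      warning("term ", tm, " has no annotated background gene; skipped")
      return(NULL)
    }
    k <- length(intersect(genes, tg))
    data.frame(term = tm, n_selected = k, n_background = K,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), n_selected = integer(0),
                      n_background = integer(0), p_value = numeric(0),
                      p_adjust = numeric(0)))
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
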