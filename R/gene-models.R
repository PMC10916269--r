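#' Stranded gene models with exon/CDS structure and optional EC annotations
#'
#' @param genes data.frame with columns `gene_id`, `seqname`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based closed).
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @param cds data.frame with columns `gene_id`, `start`, `end`; CDS
#'   intervals must lie within exons of the same gene.
#' @param ec named list mapping gene IDs to character vectors of EC numbers
#'   (genes without enzymatic annotation may be absent).
#'
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons, cds, ec = list()) {
  stopifnot(all(c("gene_id", "seqname", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)),
            all(c("gene_id", "start", "end") %in% names(cds)),
            all(genes$strand %in% c("+", "-")))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene IDs")
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$start), ]
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds, ec = ec),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,",
      sum(names(x$ec) %in% x$genes$gene_id & lengths(x$ec) > 0),
      "with EC annotation\n")
  invisible(x)
}

#' EC annotations of a gene model set as a long data.frame
#' @param models a `gene_model_set`.
#' @return data.frame with columns `gene_id`, `ec`.
#' @export
gene_ec_table <- function(models) {
  ec <- models$ec[lengths(models$ec) > 0]
  if (!length(ec)) return(data.frame(gene_id = character(0), ec = character(0)))
  data.frame(gene_id = rep(names(ec), lengths(ec)),
             ec = unlist(ec, use.names = FALSE), stringsAsFactors = FALSE)
}

gene_granges <- function(models, flank = 0) {
  GenomicRanges::GRanges(
    seqnames = models$genes$seqname,
    ranges = IRanges::IRanges(start = pmax(1L, models$genes$start - flank),
                              end = models$genes$end + flank),
    gene_id = models$genes$gene_id)
}
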