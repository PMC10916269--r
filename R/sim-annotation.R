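#' Simulate an annotated toy genome, orthogroups and pathway catalog
#'
#' Builds a random genome over `config$chrom_lengths`, places multi-exon
#' protein-coding genes (valid ATG start, stop codon, GT..AG introns, 100 bp
#' UTRs) without overlap, and produces three metabolic-pathway gene sets in
#' the style of the tuber-quality pathways (pentose and glucuronate
#' interconversions `map00040`, starch and sucrose metabolism `map00500`,
#' flavonoid biosynthesis `map00941`). `n_pathway_genes_annotated` genes
#' carry `ec_number` attributes listed in the pathway catalog;
#' `n_pathway_genes_orthology_only` genes carry no EC attribute but share an
#' orthogroup with an annotated gene, so they are recoverable only through
#' orthogroup expansion. Orthogroups also contain members from two other
#' species plus background orthogroups, giving presence/absence tallies
#' something to count.
#'
#' @param config a [sim_config()].
#' @return list with `models` (a [gene_model_set()]), `genome` (named
#'   [Biostrings::DNAStringSet]), `og_table` (long data.frame `og_id`,
#'   `species`, `gene_id`), `pathway_table` (data.frame `pathway_id`, `ec`),
#'   `gene_pathways` (data.frame `gene_id`, `pathway`, `annotated`),
#'   `orthology_only_gene_ids`, `focal_species` (`"dalata"`).
#' @export
simulate_annotation_and_orthogroups <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 11L)
  pathways <- c("map00040", "map00500", "map00941")
  ec_prefix <- c(map00040 = "4.2.2", map00500 = "2.4.1", map00941 = "1.14.11")

  n_ann <- config$n_pathway_genes_annotated
  n_orth <- config$n_pathway_genes_orthology_only
  ann_share <- diff(round(seq(0, n_ann, length.out = 4)))
  orth_share <- diff(round(seq(0, n_orth, length.out = 4)))

  genes <- data.frame(gene_id = sprintf("dal_%03d", seq_len(n_ann + n_orth)),
                      pathway = c(rep(pathways, ann_share),
                                  rep(pathways, orth_share)),
                      annotated = rep(c(TRUE, FALSE), c(n_ann, n_orth)),
                      stringsAsFactors = FALSE)
  genes <- genes[sample.int(nrow(genes)), , drop = FALSE]  # placement order
  rownames(genes) <- NULL

  # random genome as one mutable string per chromosome
  bases <- c("A", "C", "G", "T")
  genome_str <- lapply(config$chrom_lengths, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""))

  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], character(0))
  utr_len <- 100L

  gene_rows <- exon_rows <- cds_rows <- list()
  struct <- list()  # per-gene structure kept for QTN planting
  cursors <- stats::setNames(rep(5001L, length(config$chrom_lengths)),
                             names(config$chrom_lengths))
  chrom_cycle <- rep(names(config$chrom_lengths), length.out = nrow(genes))

  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    n_cds_exons <- sample(2:3, 1)
    n_codons <- sample(100:240, 1)
    cds_len <- 3L * n_codons
    intron_lens <- sample(100:200, n_cds_exons - 1, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    total <- 2L * utr_len + cds_len + sum(intron_lens)

    # find a chromosome with room
    placed <- FALSE
    for (try_sq in unique(c(chrom_cycle[i], names(config$chrom_lengths)))) {
      if (cursors[[try_sq]] + total - 1L <=
          config$chrom_lengths[[try_sq]] - 5000L) {
        sq <- try_sq
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place ", nrow(genes), " genes on the configured ",
           "chromosome lengths")
    s <- cursors[[sq]]
    cursors[[sq]] <- s + total + 1500L

    # transcript-order segments
    part_bounds <- round(seq(0, cds_len, length.out = n_cds_exons + 1) / 3) * 3
    part_lens <- diff(part_bounds)
    seg_type <- c("utr5",
                  as.vector(rbind(rep("cds", n_cds_exons),
                                  c(rep("intron", n_cds_exons - 1), NA)))[
                    seq_len(2 * n_cds_exons - 1)],
                  "utr3")
    seg_len <- c(utr_len,
                 as.vector(rbind(part_lens,
                                 c(intron_lens, NA)))[
                   seq_len(2 * n_cds_exons - 1)],
                 utr_len)
    cds_seq <- paste0("ATG",
                      paste(sample(setdiff(sense_codons, "ATG"),
                                   n_codons - 2, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TGA", "TAG"), 1))
    # assemble the pre-mRNA on the coding strand
    seg_seq <- character(length(seg_type))
    cds_used <- 0L
    for (k in seq_along(seg_type)) {
      if (seg_type[k] == "cds") {
        seg_seq[k] <- substr(cds_seq, cds_used + 1L, cds_used + seg_len[k])
        cds_used <- cds_used + seg_len[k]
      } else if (seg_type[k] == "intron") {
        seg_seq[k] <- paste0("GT", paste(sample(bases, seg_len[k] - 4L,
                                                replace = TRUE),
                                         collapse = ""), "AG")
      } else {
        seg_seq[k] <- paste(sample(bases, seg_len[k], replace = TRUE),
                            collapse = "")
      }
    }
    pre_mrna <- paste(seg_seq, collapse = "")
    genomic_seq <- if (strand == "+") pre_mrna else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pre_mrna)))
    substr(genome_str[[sq]], s, s + total - 1L) <- genomic_seq

    # transcript -> genomic interval mapping
    t2 <- cumsum(seg_len)
    t1 <- t2 - seg_len + 1L
    e <- s + total - 1L
    g1 <- if (strand == "+") s + t1 - 1L else e - t2 + 1L
    g2 <- if (strand == "+") s + t2 - 1L else e - t1 + 1L
    segs <- data.frame(type = seg_type, start = pmin(g1, g2),
                       end = pmax(g1, g2), stringsAsFactors = FALSE)
    segs <- segs[order(segs$start), , drop = FALSE]
    # exons = maximal runs of non-intron segments
    is_ex <- segs$type != "intron"
    ex_list <- split(segs[is_ex, , drop = FALSE],
                     cumsum(!is_ex)[is_ex])
    exons <- do.call(rbind, lapply(ex_list, function(d)
      data.frame(start = min(d$start), end = max(d$end))))

    gene_rows[[i]] <- data.frame(gene_id = gid, seqname = sq, strand = strand,
                                 start = s, end = e, stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(gene_id = gid, start = exons$start,
                                 end = exons$end, stringsAsFactors = FALSE)
    cdss <- segs[segs$type == "cds", , drop = FALSE]
    cds_rows[[i]] <- data.frame(gene_id = gid, start = cdss$start,
                                end = cdss$end, stringsAsFactors = FALSE)
    struct[[gid]] <- list(seqname = sq, strand = strand,
                          cds = cdss[, c("start", "end")],
                          n_codons = n_codons)
  }

  # EC assignment and orthogroups: one OG per annotated gene; each
  # orthology-only gene joins the OG of an annotated gene of its pathway
  ec <- list()
  og_rows <- list()
  focal <- "dalata"
  other_species <- c("drotundata", "dzingiberensis")
  ann_genes <- genes$gene_id[genes$annotated]
  og_of <- stats::setNames(sprintf("OG%07d", seq_along(ann_genes)), ann_genes)
  pathway_table <- list()
  for (pw in pathways) {
    pw_ann <- genes$gene_id[genes$annotated & genes$pathway == pw]
    ecs <- paste0(ec_prefix[[pw]], ".", seq_along(pw_ann))
    for (j in seq_along(pw_ann)) ec[[pw_ann[j]]] <- ecs[j]
    pathway_table[[pw]] <- data.frame(pathway_id = pw, ec = ecs,
                                      stringsAsFactors = FALSE)
    pw_orth <- genes$gene_id[!genes$annotated & genes$pathway == pw]
    host <- rep(pw_ann, length.out = length(pw_orth))
    for (j in seq_along(pw_orth)) {
      og_rows[[length(og_rows) + 1L]] <-
        data.frame(og_id = og_of[[host[j]]], species = focal,
                   gene_id = pw_orth[j], stringsAsFactors = FALSE)
    }
  }
  for (g in ann_genes) {
    og_rows[[length(og_rows) + 1L]] <-
      data.frame(og_id = og_of[[g]], species = focal, gene_id = g,
                 stringsAsFactors = FALSE)
    for (sp in other_species)
      og_rows[[length(og_rows) + 1L]] <-
        data.frame(og_id = og_of[[g]], species = sp,
                   gene_id = paste0(substr(sp, 1, 4), "_", og_of[[g]]),
                   stringsAsFactors = FALSE)
  }
  # background orthogroups with varied species membership
  for (k in seq_len(30)) {
    ogid <- sprintf("OGbg%05d", k)
    members <- sample(c(focal, other_species),
                      sample(1:3, 1))
    for (sp in members)
      og_rows[[length(og_rows) + 1L]] <-
        data.frame(og_id = ogid, species = sp,
                   gene_id = paste0(substr(sp, 1, 4), "_bg", k),
                   stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(unlist(genome_str))
  names(genome) <- names(config$chrom_lengths)
  models <- gene_model_set(do.call(rbind, gene_rows),
                           do.call(rbind, exon_rows),
                           do.call(rbind, cds_rows), ec)
  list(models = models, genome = genome,
       og_table = do.call(rbind, og_rows),
       pathway_table = do.call(rbind, pathway_table),
       gene_pathways = genes[order(genes$gene_id), , drop = FALSE],
       orthology_only_gene_ids = sort(genes$gene_id[!genes$annotated]),
       focal_species = focal, gene_struct = struct)
}

# genomic position of coding-strand CDS position p (inverse of cds_position)
cds_to_genomic <- function(cds, strand, p) {
  cds <- cds[order(cds$start), , drop = FALSE]
  lens <- cds$end - cds$start + 1L
  if (strand == "+") {
    cum <- cumsum(lens)
    j <- which(p <= cum)[1]
    off <- p - c(0L, cum)[j]
    cds$start[j] + off - 1L
  } else {
    k <- nrow(cds)
    cum <- cumsum(rev(lens))
    jr <- which(p <= cum)[1]
    j <- k - jr + 1L
    off <- p - c(0L, cum)[jr]
    cds$end[j] - off + 1L
  }
}

# Rewrite one codon of a gene to TGG (Trp) and return the stop-gain SNP spec
# at its third base (G>A on the coding strand turns TGG into the TGA stop).
plant_stop_gain_site <- function(annotation, gene_id, codon_index = NULL) {
  st <- annotation$gene_struct[[gene_id]]
  if (is.null(st)) stop("unknown gene ", gene_id)
  if (is.null(codon_index)) codon_index <- max(2L, st$n_codons %/% 2L)
  if (codon_index <= 1L || codon_index >= st$n_codons)
    stop("codon_index must be internal to the CDS")
  cds_pos <- (codon_index - 1L) * 3L + 1:3
  gpos <- vapply(cds_pos, function(p)
    as.integer(cds_to_genomic(st$cds, st$strand, p)), 0L)
  codon_coding <- c("T", "G", "G")
  write_base <- if (st$strand == "+") codon_coding else
    rev(comp_base(codon_coding))
  wpos <- if (st$strand == "+") gpos else rev(gpos)
  genome <- annotation$genome
  genome[[st$seqname]] <- Biostrings::replaceLetterAt(
    genome[[st$seqname]], wpos, paste(write_base, collapse = ""))
  annotation$genome <- genome
  site <- list(seqname = st$seqname, pos = gpos[3],
               ref = if (st$strand == "+") "G" else "C",
               alt = if (st$strand == "+") "A" else "T",
               gene_id = gene_id, codon_index = codon_index)
  list(annotation = annotation, site = site)
}
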