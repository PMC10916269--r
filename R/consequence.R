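#' @title SNP consequence classification within gene models
#' @description Re-implements the standard consequence classes for biallelic
#'   SNPs against a set of gene models and the reference genome: coding
#'   effects (stop gained/lost, start lost, missense, synonymous) are
#'   computed on the coding strand with the standard nuclear genetic code;
#'   splice donor/acceptor sites are the two intronic bases adjacent to each
#'   exon boundary (strand-aware); exonic non-CDS positions are UTRs;
#'   positions within `flank` bp of the gene span are upstream/downstream;
#'   everything else is intergenic.
#' @name consequence
NULL

CONSEQUENCE_IMPACT <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_acceptor_variant = "HIGH", splice_donor_variant = "HIGH",
  missense = "MODERATE", synonymous = "LOW",
  intron = "MODIFIER", `5_prime_UTR` = "MODIFIER", `3_prime_UTR` = "MODIFIER",
  upstream = "MODIFIER", downstream = "MODIFIER", intergenic = "MODIFIER")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

comp_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# Per-gene lookup used repeatedly during classification: transcript-ordered
# CDS intervals, coding-strand CDS sequence and cumulative offsets.
gene_cache <- function(models, genome, gene) {
  strand <- models$genes$strand[models$genes$gene_id == gene]
  seqn <- models$genes$seqname[models$genes$gene_id == gene]
  cds <- models$cds[models$cds$gene_id == gene, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  exons <- models$exons[models$exons$gene_id == gene, , drop = FALSE]
  exons <- exons[order(exons$start), , drop = FALSE]
  seq <- genome[[seqn]]
  cds_seq <- ""
  if (nrow(cds)) {
    parts <- vapply(seq_len(nrow(cds)), function(j)
      as.character(Biostrings::subseq(seq, cds$start[j], cds$end[j])), "")
    cds_seq <- paste(parts, collapse = "")
    if (strand == "-")
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
  }
  list(strand = strand, seqname = seqn, cds = cds, exons = exons,
       cds_seq = cds_seq, cds_len = nchar(cds_seq))
}

# 1-based position within the coding sequence (transcript orientation);
# NA if pos is not inside a CDS interval.
cds_position <- function(cache, pos) {
  cds <- cache$cds
  if (!nrow(cds)) return(NA_integer_)
  j <- which(pos >= cds$start & pos <= cds$end)
  if (!length(j)) return(NA_integer_)
  lens <- cds$end - cds$start + 1L
  if (cache$strand == "+") {
    sum(lens[seq_len(j - 1)]) + (pos - cds$start[j] + 1L)
  } else {
    k <- nrow(cds)
    before <- if (j < k) sum(lens[(j + 1):k]) else 0L
    before + (cds$end[j] - pos + 1L)
  }
}

classify_one <- function(cache, pos, ref, alt, gene) {
  strand <- cache$strand
  exons <- cache$exons
  gene_start <- min(exons$start)
  gene_end <- max(exons$end)
  cpos <- cds_position(cache, pos)

  if (!is.na(cpos)) {
    if (cache$cds_len %% 3 != 0)
      warning("CDS length of ", gene, " not divisible by 3; ",
              "classifying by local codon", call. = FALSE)
    ref_c <- if (strand == "+") toupper(ref) else comp_base(toupper(ref))
    alt_c <- if (strand == "+") toupper(alt) else comp_base(toupper(alt))
    ci <- (cpos - 1L) %/% 3L + 1L
    off <- (cpos - 1L) %% 3L + 1L
    codon <- substr(cache$cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
    if (nchar(codon) < 3)  # trailing partial codon of an incomplete model
      return(list(category = "synonymous", notation = NA_character_))
    if (substr(codon, off, off) != ref_c)
      stop("reference base mismatch inside CDS of ", gene)
    alt_codon <- codon
    substr(alt_codon, off, off) <- alt_c
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(alt_codon)
    if (ci == 1L && codon == "ATG" && alt_codon != "ATG")
      return(list(category = "start_lost", notation = "p.Met1?"))
    if (aa_ref != "*" && aa_alt == "*")
      return(list(category = "stop_gained",
                  notation = paste0("p.", AA3[aa_ref], ci, ">STOP")))
    if (aa_ref == "*" && aa_alt != "*")
      return(list(category = "stop_lost",
                  notation = paste0("p.Ter", ci, AA3[aa_alt], "ext*?")))
    if (aa_ref == aa_alt)
      return(list(category = "synonymous",
                  notation = paste0("p.", AA3[aa_ref], ci, "=")))
    list(category = "missense",
         notation = paste0("p.", AA3[aa_ref], ci, AA3[aa_alt]))
  } else if (any(pos >= exons$start & pos <= exons$end)) {
    cds <- cache$cds
    if (!nrow(cds)) return(list(category = "intron", notation = NA_character_))
    five <- if (strand == "+") pos < min(cds$start) else pos > max(cds$end)
    list(category = if (five) "5_prime_UTR" else "3_prime_UTR",
         notation = NA_character_)
  } else if (pos >= gene_start && pos <= gene_end) {
    k <- nrow(exons)
    ref_c <- if (strand == "+") toupper(ref) else comp_base(toupper(ref))
    alt_c <- if (strand == "+") toupper(alt) else comp_base(toupper(alt))
    for (j in seq_len(k - 1)) {
      istart <- exons$end[j] + 1L
      iend <- exons$start[j + 1] - 1L
      if (pos < istart || pos > iend) next
      donor <- if (strand == "+") c(istart, istart + 1L) else c(iend - 1L, iend)
      accept <- if (strand == "+") c(iend - 1L, iend) else c(istart, istart + 1L)
      if (pos %in% donor) {
        dist <- if (strand == "+") pos - istart + 1L else iend - pos + 1L
        return(list(category = "splice_donor_variant",
                    notation = paste0("c.", splice_anchor(cache, j, "donor"),
                                      "+", dist, ref_c, ">", alt_c)))
      }
      if (pos %in% accept) {
        dist <- if (strand == "+") iend - pos + 1L else pos - istart + 1L
        return(list(category = "splice_acceptor_variant",
                    notation = paste0("c.", splice_anchor(cache, j, "acceptor"),
                                      "-", dist, ref_c, ">", alt_c)))
      }
      return(list(category = "intron", notation = NA_character_))
    }
    list(category = "intron", notation = NA_character_)
  } else {
    # flanking region; orientation decides upstream vs downstream
    before <- pos < gene_start
    up <- (before && strand == "+") || (!before && strand == "-")
    list(category = if (up) "upstream" else "downstream",
         notation = NA_character_)
  }
}

# CDS coordinate anchoring a splice-site description: the last coding base of
# the transcriptionally upstream exon (donor) or the first coding base of the
# downstream exon (acceptor); UTR-side introns get a signed offset from the
# start codon, echoing notations such as "c.-109+1G>A".
splice_anchor <- function(cache, intron_j, side) {
  exons <- cache$exons
  if (cache$strand == "+") {
    bpos <- if (side == "donor") exons$end[intron_j] else exons$start[intron_j + 1]
  } else {
    bpos <- if (side == "donor") exons$start[intron_j + 1] else exons$end[intron_j]
  }
  cp <- cds_position(cache, bpos)
  if (!is.na(cp)) return(cp)
  cds <- cache$cds
  if (!nrow(cds)) return(0L)
  if (cache$strand == "+") {
    if (bpos < min(cds$start)) -(min(cds$start) - bpos) else
      cache$cds_len + (bpos - max(cds$end))
  } else {
    if (bpos > max(cds$end)) -(bpos - max(cds$end)) else
      cache$cds_len + (min(cds$start) - bpos)
  }
}

#' Classify SNP consequences against gene models
#'
#' @param snps a `variant_table` or a data.frame with columns `seqname`,
#'   `pos`, `ref`, `alt` (biallelic single-base alleles).
#' @param models a [gene_model_set()].
#' @param genome a named [Biostrings::DNAStringSet] covering the SNP
#'   seqnames; reference bases are checked against `ref`.
#' @param flank upstream/downstream window in bp (default 5000).
#' @return data.frame with one row per SNP x overlapping gene (plus an
#'   `intergenic` row for SNPs overlapping no gene): columns `snp_id`,
#'   `seqname`, `pos`, `ref`, `alt`, `gene_id`, `category`, `impact`,
#'   `notation`.
#' @export
classify_consequence <- function(snps, models, genome, flank = 5000) {
  if (inherits(snps, "variant_table")) snps <- snps$sites
  stopifnot(all(c("seqname", "pos", "ref", "alt") %in% names(snps)))
  bad <- setdiff(unique(snps$seqname), names(genome))
  if (length(bad)) stop("seqnames absent from genome: ",
                        paste(bad, collapse = ", "))
  # reference check against the FASTA
  for (sq in unique(snps$seqname)) {
    i <- which(snps$seqname == sq & nchar(snps$ref) == 1)
    if (!length(i)) next
    obs <- strsplit(as.character(Biostrings::extractAt(
      genome[[sq]], IRanges::IRanges(snps$pos[i], snps$pos[i]))), "")
    obs <- toupper(vapply(obs, `[`, "", 1))
    mm <- which(obs != toupper(snps$ref[i]))
    if (length(mm)) stop("reference allele mismatch vs genome at ", sq, ":",
                         snps$pos[i][mm[1]])
  }
  snp_gr <- GenomicRanges::GRanges(snps$seqname,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_granges(models, flank)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  caches <- new.env(parent = emptyenv())
  rows <- vector("list", length(qh) + nrow(snps))
  k <- 0L
  for (h in seq_along(qh)) {
    i <- qh[h]
    gene <- models$genes$gene_id[sh[h]]
    if (is.null(caches[[gene]]))
      caches[[gene]] <- gene_cache(models, genome, gene)
    cl <- classify_one(caches[[gene]], snps$pos[i], snps$ref[i], snps$alt[i],
                       gene)
    k <- k + 1L
    rows[[k]] <- data.frame(
      snp_id = snp_id(snps$seqname[i], snps$pos[i]), seqname = snps$seqname[i],
      pos = snps$pos[i], ref = snps$ref[i], alt = snps$alt[i], gene_id = gene,
      category = cl$category, impact = unname(CONSEQUENCE_IMPACT[cl$category]),
      notation = cl$notation, stringsAsFactors = FALSE)
  }
  nohit <- setdiff(seq_len(nrow(snps)), unique(qh))
  for (i in nohit) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      snp_id = snp_id(snps$seqname[i], snps$pos[i]), seqname = snps$seqname[i],
      pos = snps$pos[i], ref = snps$ref[i], alt = snps$alt[i],
      gene_id = NA_character_, category = "intergenic", impact = "MODIFIER",
      notation = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out <- out[order(match(out$seqname, unique(snps$seqname)), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Default high-impact consequence categories
#'
#' The conventional HIGH tier: premature stop, lost stop/start and broken
#' splice sites. Set `include_missense = TRUE` to also treat non-synonymous
#' substitutions as high impact (some annotation summaries group them with
#' protein-disrupting changes).
#'
#' @param include_missense logical.
#' @return character vector of category names.
#' @export
high_impact_categories <- function(include_missense = FALSE) {
  cats <- c("stop_gained", "stop_lost", "start_lost",
            "splice_acceptor_variant", "splice_donor_variant")
  if (include_missense) cats <- c(cats, "missense")
  cats
}

#' Keep only consequences in a chosen impact set
#'
#' @param consequences output of [classify_consequence()].
#' @param impact_set character vector of categories to retain; must be
#'   non-empty.
#' @return the filtered consequence data.frame.
#' @export
select_high_impact <- function(consequences,
                               impact_set = high_impact_categories()) {
  if (!length(impact_set)) stop("impact_set must not be empty")
  out <- consequences[consequences$category %in% impact_set, , drop = FALSE]
  rownames(out) <- NULL
  out
}
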