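#' @title Readers and writers for the pipeline's file formats
#' @description VCF v4.2 (GT:DP), GFF3 gene models with `ec_number`
#'   attributes, FASTA, and the TSV/JSON side tables (orthogroups, pathway
#'   EC lists, phenotypes, expression, cluster assignments, truth sets,
#'   windowed Fst, outlier BED). Writers produce deterministic plain text;
#'   VCF reading goes through vcfR, FASTA through Biostrings.
#' @name tuberscan-io
NULL

#' Write a variant table as VCF v4.2
#'
#' @param vt a `variant_table`.
#' @param path output file.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tuberscan",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                      "Description=\"Read depth\">")), con)
  for (sq in unique(vt$sites$seqname))
    writeLines(paste0("##contig=<ID=", sq, ">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(vt$gt)), collapse = "\t"), con)
  gt <- vt$gt
  gt[is.na(gt)] <- "./."
  dp <- vt$dp
  dp[is.na(dp)] <- 0L
  calls <- matrix(paste(gt, dp, sep = ":"), nrow(gt), ncol(gt))
  lines <- paste(vt$sites$seqname, vt$sites$pos, vt$sites$id, vt$sites$ref,
                 vt$sites$alt, sprintf("%.1f", vt$sites$qual), "PASS", ".",
                 "GT:DP", apply(calls, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses fixed fields plus per-call GT and DP via vcfR.
#'
#' @param path VCF file.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  mode(dp) <- "integer"
  variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
                fix[, "ALT"], as.numeric(fix[, "QUAL"]), gt, dp)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features; EC annotations go on the gene line as
#' an `ec_number` attribute (comma-joined).
#'
#' @param models a [gene_model_set()].
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    ec <- models$ec[[g$gene_id]]
    attr_g <- paste0("ID=", g$gene_id,
                     if (length(ec)) paste0(";ec_number=",
                                            paste(ec, collapse = ",")) else "")
    mrna <- paste0(g$gene_id, ".1")
    writeLines(paste(g$seqname, "tuberscan", "gene", g$start, g$end, ".",
                     g$strand, ".", attr_g, sep = "\t"), con)
    writeLines(paste(g$seqname, "tuberscan", "mRNA", g$start, g$end, ".",
                     g$strand, ".",
                     paste0("ID=", mrna, ";Parent=", g$gene_id), sep = "\t"),
               con)
    ex <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(paste(g$seqname, "tuberscan", "exon", ex$start[j], ex$end[j],
                       ".", g$strand, ".", paste0("Parent=", mrna),
                       sep = "\t"), con)
    cd <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(cd)) {
      lens <- cd$end - cd$start + 1L
      ord <- if (g$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
      frame <- integer(nrow(cd))
      acc <- 0L
      for (j in ord) {
        frame[j] <- (3L - acc %% 3L) %% 3L
        acc <- acc + lens[j]
      }
      for (j in seq_len(nrow(cd)))
        writeLines(paste(g$seqname, "tuberscan", "CDS", cd$start[j], cd$end[j],
                         ".", g$strand, frame[j], paste0("Parent=", mrna),
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read GFF3 gene models
#'
#' Minimal GFF3 parser for the gene/mRNA/exon/CDS feature set written by
#' [write_gff3()] (one transcript per gene), retaining `ec_number`
#' attributes.
#'
#' @param path GFF3 file.
#' @return a [gene_model_set()].
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) == 9))
  m <- do.call(rbind, f)
  get_attr <- function(a, key) {
    r <- regexpr(paste0("(^|;)", key, "=([^;]*)"), a)
    out <- rep(NA_character_, length(a))
    out[r > 0] <- sub(paste0("^;?", key, "="), "", regmatches(a, r))
    out
  }
  type <- m[, 3]
  ga <- m[, 9]
  genes_i <- type == "gene"
  genes <- data.frame(gene_id = get_attr(ga[genes_i], "ID"),
                      seqname = m[genes_i, 1], strand = m[genes_i, 7],
                      start = as.integer(m[genes_i, 4]),
                      end = as.integer(m[genes_i, 5]),
                      stringsAsFactors = FALSE)
  ec_raw <- get_attr(ga[genes_i], "ec_number")
  ec <- list()
  for (i in which(!is.na(ec_raw)))
    ec[[genes$gene_id[i]]] <- strsplit(ec_raw[i], ",", fixed = TRUE)[[1]]
  mrna_i <- type == "mRNA"
  mrna_parent <- stats::setNames(get_attr(ga[mrna_i], "Parent"),
                                 get_attr(ga[mrna_i], "ID"))
  feat <- function(what) {
    i <- type == what
    parent <- get_attr(ga[i], "Parent")
    data.frame(gene_id = unname(mrna_parent[parent]),
               start = as.integer(m[i, 4]), end = as.integer(m[i, 5]),
               stringsAsFactors = FALSE)
  }
  gene_model_set(genes, feat("exon"), feat("CDS"), ec)
}

#' Write / read a genome FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path FASTA file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write / read an orthogroup table
#'
#' One row per (orthogroup, species): `OG_ID<tab>species<tab>gene1,gene2`.
#'
#' @param og_table long-format data.frame (`og_id`, `species`, `gene_id`).
#' @param path TSV file.
#' @export
write_orthogroups <- function(og_table, path) {
  key <- paste(og_table$og_id, og_table$species, sep = "\r")
  sp <- split(og_table$gene_id, key)
  parts <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  df <- data.frame(og_id = parts[, 1], species = parts[, 2],
                   genes = vapply(sp, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  df <- df[order(df$og_id, df$species), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orthogroups
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes <- strsplit(df$genes, ",", fixed = TRUE)
  data.frame(og_id = rep(df$og_id, lengths(genes)),
             species = rep(df$species, lengths(genes)),
             gene_id = unlist(genes), stringsAsFactors = FALSE)
}

#' Write / read simple TSV side tables
#'
#' Plain `write.table`/`read.delim` wrappers used for the pathway catalog,
#' phenotype, expression, cluster-assignment and result tables.
#'
#' @param df data.frame.
#' @param path TSV file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write / read a truth set as JSON (round-trip stable)
#'
#' @param truth truth list from [simulate_population()] /
#'   [simulate_study()].
#' @param path JSON file.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  if (!is.null(tr$qtn_dosage))
    tr$qtn_dosage <- list(snp_id = rownames(tr$qtn_dosage),
                          sample = colnames(tr$qtn_dosage),
                          dosage = unname(tr$qtn_dosage))
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tr$qtn_dosage)) {
    d <- tr$qtn_dosage$dosage
    dimnames(d) <- list(tr$qtn_dosage$snp_id, tr$qtn_dosage$sample)
    tr$qtn_dosage <- d
  }
  if (!is.null(tr$qtn)) tr$qtn <- as.data.frame(tr$qtn)
  tr
}

#' Write outlier windows as BED (0-based half-open)
#'
#' @param outliers an `outlier_set`.
#' @param path BED file.
#' @export
write_outlier_bed <- function(outliers, path) {
  w <- outliers$windows
  df <- data.frame(w$seqname, w$start - 1L, w$end,
                   paste0(outliers$pair, "_fst_outlier"),
                   signif(w$weighted_fst, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write all inputs of a simulated study to a directory
#'
#' Materialises the study as the file set a real analysis would start from:
#' `variants.vcf`, `genes.gff3`, `genome.fa`, `orthogroups.tsv`,
#' `pathways.tsv`, `phenotypes.tsv`, `expression.tsv`, `clusters.tsv`,
#' `truth.json`.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(study$variants, file.path(dir, "variants.vcf"))
  write_gff3(study$models, file.path(dir, "genes.gff3"))
  write_fasta(study$genome, file.path(dir, "genome.fa"))
  write_orthogroups(study$og_table, file.path(dir, "orthogroups.tsv"))
  write_tsv(study$pathway_table, file.path(dir, "pathways.tsv"))
  write_tsv(study$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (!is.null(study$expression))
    write_tsv(study$expression, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample = names(study$clusters),
                       cluster = unname(study$clusters)),
            file.path(dir, "clusters.tsv"))
  write_truth(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
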