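#' Retrieve pathway genes by EC-number keyword search
#'
#' Returns the genes of the annotation whose EC attribute intersects the EC
#' list of one pathway. Full EC strings match exactly; partial catalog codes
#' terminated by `-` (e.g. `"2.4.1.-"`) match by prefix.
#'
#' @param models a [gene_model_set()] whose `ec` slot carries EC numbers.
#' @param catalog data.frame with columns `pathway_id`, `ec`.
#' @param pathway a pathway ID present in `catalog` (e.g. `"map00500"`).
#' @return data.frame with columns `gene_id`, `ec` (comma-joined matching
#'   ECs) and `provenance = "keyword"`.
#' @export
keyword_retrieval <- function(models, catalog, pathway) {
  if (!pathway %in% catalog$pathway_id)
    stop("unknown pathway '", pathway, "'; available: ",
         paste(sort(unique(catalog$pathway_id)), collapse = ", "))
  ecs <- unique(catalog$ec[catalog$pathway_id == pathway])
  tab <- gene_ec_table(models)
  if (!nrow(tab))
    return(data.frame(gene_id = character(0), ec = character(0),
                      provenance = character(0)))
  m <- vapply(tab$ec, function(e) any(ec_matches(ecs, e)), TRUE)
  tab <- tab[m, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(gene_id = character(0), ec = character(0),
                      provenance = character(0)))
  agg <- stats::aggregate(ec ~ gene_id, data = tab,
                          FUN = function(x) paste(sort(unique(x)),
                                                  collapse = ","))
  data.frame(gene_id = agg$gene_id, ec = agg$ec, provenance = "keyword",
             stringsAsFactors = FALSE)
}

# does gene EC `e` match any catalog entry (exact, or prefix for "x.y.z.-")?
ec_matches <- function(catalog_ecs, e) {
  partial <- grepl("-$", catalog_ecs)
  hit <- catalog_ecs == e
  if (any(partial))
    hit[partial] <- startsWith(e, sub("-$", "", catalog_ecs[partial]))
  hit
}

#' Expand a pathway gene set through orthogroups
#'
#' Adds every focal-species gene sharing an orthogroup with at least one
#' seed gene. Added genes inherit the union of the EC labels carried by the
#' seed genes of their orthogroup and are labelled `provenance =
#' "orthology"`; genes already in the seed set keep their `"keyword"`
#' provenance. Seed genes absent from the orthogroup table are kept as
#' singletons (with a message). The operation is monotone and idempotent.
#'
#' @param seeds data.frame from [keyword_retrieval()] (columns `gene_id`,
#'   `ec`, `provenance`).
#' @param og_table long-format orthogroup table: data.frame with columns
#'   `og_id`, `species`, `gene_id`.
#' @param focal_species species whose genes are expanded (e.g. `"dalata"`).
#' @return data.frame with columns `gene_id`, `ec`, `provenance`, `og_id`.
#' @export
orthogroup_expansion <- function(seeds, og_table, focal_species) {
  focal <- og_table[og_table$species == focal_species, , drop = FALSE]
  seed_og <- focal$og_id[match(seeds$gene_id, focal$gene_id)]
  orphan <- seeds$gene_id[is.na(seed_og)]
  if (length(orphan))
    message(length(orphan), " seed gene(s) absent from the orthogroup ",
            "table kept as singletons: ", paste(orphan, collapse = ", "))
  rows <- data.frame(gene_id = seeds$gene_id, ec = seeds$ec,
                     provenance = "keyword",
                     og_id = seed_og, stringsAsFactors = FALSE)
  for (og in unique(stats::na.omit(seed_og))) {
    members <- focal$gene_id[focal$og_id == og]
    added <- setdiff(members, seeds$gene_id)
    if (!length(added)) next
    inherited <- paste(sort(unique(unlist(strsplit(
      seeds$ec[!is.na(seed_og) & seed_og == og], ",", fixed = TRUE)))),
      collapse = ",")
    rows <- rbind(rows, data.frame(gene_id = added, ec = inherited,
                                   provenance = "orthology", og_id = og,
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[!duplicated(rows$gene_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Orthogroup presence/absence matrix and UpSet-style tallies
#'
#' Builds the OG x species binary matrix restricted to a species subset and
#' counts, for every combination of species, the orthogroups present in
#' exactly that combination, plus the count shared by all species.
#'
#' @param og_table long-format orthogroup table (`og_id`, `species`,
#'   `gene_id`).
#' @param species character vector of species to include (>= 1).
#' @return list with `matrix` (binary, rownames = OG IDs), `tallies`
#'   (data.frame `combination` (species joined by `&`), `degree`, `n_og`)
#'   and `shared_all` count.
#' @export
presence_absence <- function(og_table, species) {
  missing_sp <- setdiff(species, unique(og_table$species))
  if (length(missing_sp))
    stop("species absent from orthogroup table: ",
         paste(missing_sp, collapse = ", "))
  sub <- og_table[og_table$species %in% species, , drop = FALSE]
  ogs <- sort(unique(sub$og_id))
  mat <- matrix(0L, length(ogs), length(species),
                dimnames = list(ogs, species))
  key <- paste(sub$og_id, sub$species)
  for (sp in species)
    mat[, sp] <- as.integer(paste(ogs, sp) %in% key)
  pattern <- apply(mat, 1, function(r) paste(species[r == 1], collapse = "&"))
  tal <- table(pattern[pattern != ""])
  tallies <- data.frame(combination = names(tal),
                        degree = lengths(strsplit(names(tal), "&", fixed = TRUE)),
                        n_og = as.integer(tal), stringsAsFactors = FALSE)
  tallies <- tallies[order(-tallies$n_og, tallies$combination), , drop = FALSE]
  rownames(tallies) <- NULL
  all_comb <- paste(species, collapse = "&")
  list(matrix = mat, tallies = tallies,
       shared_all = sum(tallies$n_og[tallies$combination == all_comb]))
}

#' Candidate SNPs of each pathway's gene set
#'
#' Restricts a consequence table to SNPs lying within the transcribed unit
#' (CDS, intron including splice sites, 5'/3' UTR) of pathway genes and
#' passing the high-impact gate. Provenance (keyword vs orthology) of the
#' host gene is carried through.
#'
#' @param consequences data.frame from [classify_consequence()].
#' @param pathway_genes named list mapping pathway ID to the expanded gene
#'   data.frame from [orthogroup_expansion()].
#' @param impact_set categories to retain (default
#'   [high_impact_categories()]).
#' @return data.frame with the consequence columns plus `pathway` and
#'   `provenance`; attribute `"counts"` holds the per-pathway SNP counts.
#' @export
candidate_snp_extraction <- function(consequences, pathway_genes,
                                     impact_set = high_impact_categories()) {
  transcribed <- c("stop_gained", "stop_lost", "start_lost", "missense",
                   "synonymous", "splice_acceptor_variant",
                   "splice_donor_variant", "intron",
                   "5_prime_UTR", "3_prime_UTR")
  out <- list()
  for (pw in names(pathway_genes)) {
    gs <- pathway_genes[[pw]]
    rows <- consequences[!is.na(consequences$gene_id) &
                           consequences$gene_id %in% gs$gene_id &
                           consequences$category %in% transcribed &
                           consequences$category %in% impact_set, ,
                         drop = FALSE]
    if (!nrow(rows)) next
    rows$pathway <- pw
    rows$provenance <- gs$provenance[match(rows$gene_id, gs$gene_id)]
    out[[pw]] <- rows
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(consequences[0, , drop = FALSE],
          data.frame(pathway = character(0), provenance = character(0)))
  rownames(res) <- NULL
  counts <- vapply(names(pathway_genes), function(pw)
    sum(res$pathway == pw), 0L)
  attr(res, "counts") <- counts
  res
}
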