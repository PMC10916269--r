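#' Simulate a structured diploid SNP panel with planted selected loci
#'
#' Draws cluster-specific allele frequencies under the Balding-Nichols
#' model: the ancestral frequency of each site is Uniform(0.05, 0.95) and
#' each cluster's frequency is Beta-distributed with that mean and
#' dispersion set by the divergence parameter F
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)`), using `background_F` for ordinary
#' sites and `selected_F` for planted selected loci. Diploid genotypes are
#' binomial draws from the cluster frequency; per-call depths are negative
#' binomial around the configured mean coverage, site QUALs normal (floored
#' at 1), and a configurable fraction of calls is set missing, so the QC
#' filters downstream have material to act on. Planted QTN sites draw their
#' ancestral frequency from Uniform(0.25, 0.75), keep their cluster
#' frequencies away from joint fixation, and carry site QUAL of at least
#' 40: a planted trait signal is ground truth and must survive the QC gates
#' rather than be lost to simulated drift or call noise.
#'
#' All randomness is governed by `config$seed`; a fixed seed reproduces the
#' output bit for bit.
#'
#' @param config a [sim_config()].
#' @param sites optional pre-built site table (data.frame with columns
#'   `seqname`, `pos`, `ref`, `alt`, `selected`, `qtn_index`), as produced
#'   by [simulate_study()] when sites must align with the annotated genome;
#'   by default sites are placed independently of any annotation.
#' @return list with `variants` (a [variant_table()]), `clusters` (named
#'   character vector sample -> cluster label) and `truth` (list with
#'   `selected_site_ids`, `qtn` (data.frame `snp_id`, `trait`, `effect`),
#'   `qtn_dosage` (true dosage matrix for QTN sites, before missingness),
#'   `sweep_regions`).
#' @export
simulate_population <- function(config, sites = NULL) {
  validate_sim_config(config)
  if (is.null(sites)) sites <- sim_sites_standalone(config)
  set.seed(config$seed)
  n <- nrow(sites)
  ids <- snp_id(sites$seqname, sites$pos)

  p0 <- stats::runif(n, 0.05, 0.95)
  is_qtn <- !is.na(sites$qtn_index)
  p0[is_qtn] <- stats::runif(sum(is_qtn), 0.25, 0.75)
  Fv <- ifelse(sites$selected, config$selected_F, config$background_F)

  samples <- sim_sample_names(config)
  clusters <- stats::setNames(rep(cluster_labels(config),
                                  each = config$n_samples_per_cluster),
                              samples)
  P <- vapply(cluster_labels(config), function(cl)
    stats::rbeta(n, p0 * (1 - Fv) / Fv, (1 - p0) * (1 - Fv) / Fv),
    numeric(n))
  # planted QTN sites must stay clearly polymorphic in the panel, or the
  # planted trait signal would be lost to drift rather than to the method
  for (i in which(is_qtn)) {
    tries <- 0
    while ((mean(P[i, ]) < 0.1 || mean(P[i, ]) > 0.9) && tries < 100) {
      P[i, ] <- stats::rbeta(config$n_clusters, p0[i] * (1 - Fv[i]) / Fv[i],
                             (1 - p0[i]) * (1 - Fv[i]) / Fv[i])
      tries <- tries + 1
    }
  }
  dosage <- matrix(NA_integer_, n, length(samples),
                   dimnames = list(NULL, samples))
  for (cl in cluster_labels(config)) {
    members <- which(clusters == cl)
    dosage[, members] <- stats::rbinom(n * length(members), 2, P[, cl])
  }

  dp <- matrix(stats::rnbinom(n * length(samples), mu = config$mean_depth,
                              size = config$depth_dispersion),
               n, length(samples), dimnames = list(NULL, samples))
  qual <- round(pmax(stats::rnorm(n, config$qual_mean, config$qual_sd), 1), 1)
  # QTN sites carry confident site calls so the planted ground truth is
  # recoverable downstream of the QUAL gate
  qual[is_qtn] <- pmax(qual[is_qtn], 40)

  qtn_dosage <- dosage[is_qtn, , drop = FALSE]
  rownames(qtn_dosage) <- ids[is_qtn]

  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], n, length(samples),
               dimnames = list(NULL, samples))
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(gt)) < config$missing_rate
    gt[miss] <- NA_character_
  }

  vt <- variant_table(sites$seqname, sites$pos, sites$ref, sites$alt,
                      qual, gt, dp)
  qtn_df <- data.frame(snp_id = ids[is_qtn], stringsAsFactors = FALSE)
  if (nrow(qtn_df)) {
    spec <- config$qtn_spec[sites$qtn_index[is_qtn]]
    qtn_df$trait <- vapply(spec, function(q) q$trait, "")
    qtn_df$effect <- vapply(spec, function(q) q$effect, 0)
  } else {
    qtn_df$trait <- character(0)
    qtn_df$effect <- numeric(0)
  }
  truth <- list(selected_site_ids = ids[sites$selected],
                qtn = qtn_df, qtn_dosage = qtn_dosage,
                sweep_regions = attr(sites, "sweep_regions"))
  list(variants = vt, clusters = clusters, truth = truth)
}

# Standalone site placement: background sites uniform over the genome,
# selected loci uniform within randomly anchored sweep regions, QTN sites
# at their configured (or evenly spaced) sorted indices.
sim_sites_standalone <- function(config) {
  set.seed(config$seed + 1L)
  lens <- config$chrom_lengths
  n_bg <- config$n_sites - config$n_selected_loci
  share <- round(n_bg * lens / sum(lens))
  share[length(share)] <- n_bg - sum(share[-length(share)])
  seqname <- rep(names(lens), share)
  pos <- unlist(lapply(names(lens), function(sq)
    sample.int(lens[[sq]], share[[sq]])))
  sweep_regions <- NULL
  if (config$n_selected_loci > 0) {
    per <- diff(round(seq(0, config$n_selected_loci,
                          length.out = config$n_sweeps + 1)))
    anchor_chr <- rep(names(lens), length.out = config$n_sweeps)
    anchor <- vapply(anchor_chr, function(sq)
      sample.int(max(1, lens[[sq]] - config$sweep_width), 1), 0L)
    sweep_regions <- data.frame(seqname = anchor_chr, start = anchor,
                                end = anchor + config$sweep_width - 1L,
                                stringsAsFactors = FALSE)
    for (j in seq_len(config$n_sweeps)) {
      p <- anchor[j] + sample.int(config$sweep_width, per[j]) - 1L
      seqname <- c(seqname, rep(anchor_chr[j], per[j]))
      pos <- c(pos, p)
    }
  }
  selected <- c(rep(FALSE, n_bg), rep(TRUE, config$n_selected_loci))
  # de-duplicate collisions by nudging (positions must be unique per seqname)
  key <- paste(seqname, pos)
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    pos[d] <- pos[d] + 1L
    key <- paste(seqname, pos)
  }
  o <- order(match(seqname, names(lens)), pos)
  sites <- data.frame(seqname = seqname[o], pos = pos[o],
                      selected = selected[o], qtn_index = NA_integer_,
                      stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(bases, r), 1), "")
  if (length(config$qtn_spec)) {
    for (i in seq_along(config$qtn_spec)) {
      s <- config$qtn_spec[[i]]$site
      if (is.null(s))
        s <- round(i * config$n_sites / (length(config$qtn_spec) + 1))
      sites$qtn_index[s] <- i
    }
  }
  attr(sites, "sweep_regions") <- sweep_regions
  sites
}
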