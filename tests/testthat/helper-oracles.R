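# Independent oracles, each a direct scalar evaluation written separately
# from the package's vectorised implementations.

# Weir & Cockerham (1984) two-population components for one site, straight
# from the printed formulas, on diploid dosage vectors (NA = missing).
wc_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# O(n^2) pairwise-mismatch nucleotide diversity for one site's dosages.
pi_oracle <- function(g) {
  g <- g[!is.na(g)]
  alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# Whole-CDS re-translation oracle for coding SNPs: mutate the genome,
# extract and translate the complete CDS, and diff the two proteins.
coding_oracle <- function(models, genome, gene, pos, ref, alt) {
  st <- models$genes[models$genes$gene_id == gene, ]
  cds <- models$cds[models$cds$gene_id == gene, ]
  cds <- cds[order(cds$start), ]
  get_cds <- function(gn) {
    parts <- vapply(seq_len(nrow(cds)), function(j)
      as.character(Biostrings::subseq(gn[[st$seqname]], cds$start[j],
                                      cds$end[j])), "")
    s <- paste(parts, collapse = "")
    if (st$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  ref_cds <- get_cds(genome)
  mut <- genome
  mut[[st$seqname]] <- Biostrings::replaceLetterAt(mut[[st$seqname]],
                                                   pos, alt)
  alt_cds <- get_cds(mut)
  trans <- function(s) {
    n <- nchar(s) %/% 3
    vapply(seq_len(n), function(i)
      unname(Biostrings::GENETIC_CODE[substr(s, 3 * i - 2, 3 * i)]), "")
  }
  p_ref <- trans(ref_cds)
  p_alt <- trans(alt_cds)
  if (substr(ref_cds, 1, 3) == "ATG" && substr(alt_cds, 1, 3) != "ATG")
    return("start_lost")
  d <- which(p_ref != p_alt)
  if (!length(d)) return("synonymous")
  i <- d[1]
  if (p_ref[i] != "*" && p_alt[i] == "*") return("stop_gained")
  if (p_ref[i] == "*" && p_alt[i] != "*") return("stop_lost")
  "missense"
}

# Welch two-sample t statistic and p-value from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, p = 2 * pt(-abs(t), df))
}

# Exact hypergeometric upper tail P(X >= k) by pmf enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Brute-force UpSet tallies: test every species subset against every OG.
upset_oracle <- function(og_table, species) {
  sub <- og_table[og_table$species %in% species, ]
  ogs <- unique(sub$og_id)
  combos <- unlist(lapply(seq_along(species), function(k)
    utils::combn(species, k, paste, collapse = "&", simplify = FALSE)))
  counts <- sapply(combos, function(cmb) {
    members <- strsplit(cmb, "&", fixed = TRUE)[[1]]
    sum(vapply(ogs, function(og) {
      present <- unique(sub$species[sub$og_id == og])
      setequal(present, members)
    }, TRUE))
  })
  counts[counts > 0]
}

# Brute-force closed-interval overlap between two interval sets.
overlap_oracle <- function(a, b) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a$seqname[i] == b$seqname[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i])
        hits[i] <- TRUE
  hits
}

# Reference CIELAB transform coded directly from the published formulas
# (sRGB gamma expansion, D65 XYZ matrix, f(t) with the 6/29 cut-off).
lab_oracle <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wh <- c(0.95047, 1, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wh)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]),
    b = 200 * (fx[2] - fx[3]))
}
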