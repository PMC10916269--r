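---
title: "tuberscan: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tuberscan: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quality traits of boiled tubers — texture (hardness, gumminess,
springiness, cohesiveness, total penetration area), starch content and
flesh colour — drive varietal adoption in root and tuber crops such as
greater yam (*Dioscorea alata*). tuberscan implements a complete
candidate-gene analysis chain for linking genomic variation to such
traits in a structured clonal panel:

1. variant quality control and consequence annotation;
2. a selection scan: per-site Weir–Cockerham Fst between genetic
   clusters, 50 kb / 10 kb sliding windows, a parametric fit to the
   window distribution and a top-5% quantile cutoff, then genes in the
   outlier windows;
3. metabolic-pathway gene retrieval by EC-number keyword search,
   expanded through orthogroups to genes that lack an EC annotation;
4. a per-pathway candidate-gene GLM association with allele-effect and
   expression-by-allele follow-up;
5. CIELAB colour indices for tuber-flesh phenotyping.

Because real panels of this kind (hundreds of resequenced genotypes)
cannot be shipped with a package, tuberscan includes a first-class
synthetic-data generator that plants known selected loci, quantitative
trait nucleotides (QTNs) and an allele-linked expression signal, so
every stage of the chain is testable against ground truth.

# Population divergence: the Weir–Cockerham estimator

For two populations with, at one biallelic site, sample sizes $n_1, n_2$
(diploids), alternate-allele frequencies $p_1, p_2$ and observed
heterozygote proportions $h_1, h_2$, the Weir & Cockerham (1984)
variance components are

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p)
  - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right],$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2
  - \frac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \frac{\bar h}{2},$$

with $r = 2$ populations, $\bar n$ the mean sample size, $n_c$ the
sample-size correction, $\bar p, \bar h$ the weighted means and $s^2$
the weighted among-population variance of allele frequencies. The
per-site estimate is $\hat\theta = a/(a+b+c)$; a window's weighted Fst
is the ratio of sums $\sum a / \sum(a+b+c)$ over the sites it contains,
which is far more stable than averaging per-site ratios. Missing calls
are excluded per site; a site is skipped for a pair when either cluster
has fewer than two non-missing genotypes, or when it is monomorphic
across both. The estimator is fixed to Weir–Cockerham (1984) because it
is the estimator implemented by the standard VCF tooling this pipeline
mirrors; the tests verify the implementation against an independently
hand-coded evaluation of the printed formulas and against a label
permutation null.

Windows are anchored at position 1 of each chromosome and advance by the
step (defaults 50,000 bp and 10,000 bp); emitted windows must contain at
least one variant. A chromosome shorter than the window yields a single
truncated, flagged window. A minimum variant count per window beyond 1
is configurable but not imposed: with the toy genome's site density, a
higher floor would silently drop informative windows.

# The outlier scan

Windowed Fst values are not normal, so the cutoff is taken from a
parametric fit: Weibull, normal, lognormal and gamma distributions are
fitted by maximum likelihood (`fitdistrplus::fitdist`, the same engine a
practitioner would use) and ranked by $\mathrm{AIC} = 2k - 2\log L$ with
$k = 2$ for every family — no location parameters are fitted, so the
comparison is on equal footing. The outlier cutoff is the inverse CDF of
the AIC-best family at $q = 0.95$ ("top 5% of the theoretical
distribution"); the comparison against windows is inclusive
($\ge$ cutoff). Fitting is done per cluster pair, since each pairwise
comparison has its own scale of divergence.

Numerical choices:

* the three positive-support families are fitted to strictly positive
  values only (slightly negative weighted Fst is a routine finite-sample
  artefact of the estimator); the normal family uses all values. Fewer
  than 30 positive values is an error that advises the empirical
  quantile instead of a parametric fit;
* a family whose optimiser fails is recorded with `NA` AIC and excluded
  from the argmin rather than aborting the scan.

Genes are intersected with outlier windows under closed-interval
semantics with a 1 bp minimum overlap (BED output converts to 0-based
half-open coordinates). "Common regions" are the maximal intervals
covered by at least one outlier window from *every* pairwise set;
overlapping common intervals are merged and counted once. Enrichment of
gene sets is a one-sided hypergeometric tail with Benjamini–Hochberg
adjustment across terms.

# Variant QC and consequence classes

The QC gates mirror the conventional VCFtools invocation: per-call
depths outside [10, 200] are masked to missing *before* the call-rate
computation (depth is a per-genotype quantity, so it must act per call);
sites with QUAL < 30 are removed; sites with call rate below 0.5 are
removed, boundary inclusive ("`--max-missing 0.5`" retains a site at
exactly half missing). The filter is idempotent. The population-genetics
filter then keeps biallelic single-base SNPs with MAF ≥ 0.01 over
non-missing alleles and thins greedily left-to-right at 10 bp. An
optional greedy LD pruner (look-back window of 50 kept sites, drop the
later site of any pair with $r^2 > 0.1$) is provided but disabled by
default: genuine r²-based pruning is not part of the core chain and the
thinning step already removes tightly packed sites.

Consequence classification re-implements the standard classes rather
than wrapping an annotation tool, because the class definitions are load
bearing for the candidate-SNP logic. For each SNP × overlapping gene
model: positions inside the CDS are translated on the coding strand with
the standard nuclear code (stop_gained, stop_lost, start_lost,
missense, synonymous, with protein notation such as `p.Trp287>STOP`,
`p.Met1?`); the two intronic bases adjacent to each exon boundary are
splice sites, donor at the transcription-upstream end and acceptor at
the downstream end, strand-aware, with `c.{pos}+1G>A`-style notation;
other intronic positions are introns; exonic non-CDS positions are
5'/3' UTR by strand; positions within 5 kb of the gene span (the
conventional annotation-tool default, the size being otherwise
unstated) are upstream/downstream; SNPs touching no gene are intergenic.
Impacts follow the conventional tiering — protein-truncating and
splice-disrupting classes are HIGH, missense MODERATE, synonymous LOW,
everything else MODIFIER. Because some annotation summaries group
non-synonymous changes with the protein-disrupting ones, the
high-impact gate is a configurable set
(`high_impact_categories(include_missense = TRUE)`), with the
conventional HIGH tier as the default; neither convention is asserted
as the only valid one. A SNP in a CDS whose length is not divisible
by 3 is classified by its local codon with a warning. Classification is
verified against a whole-CDS re-translation oracle on hundreds of
random SNPs and is exactly symmetric under reverse-complementing the
genome and flipping strands.

SNP identifiers use the `S{chromosome-number}_{position}` convention
(e.g. `S4_20715506`) common in marker–trait association tables.

# Pathway retrieval and orthogroup expansion

A pathway catalog maps pathway IDs (e.g. `map00040` pentose and
glucuronate interconversions, `map00500` starch and sucrose metabolism,
`map00941` flavonoid biosynthesis) to EC numbers. Keyword retrieval
returns genes whose `ec_number` annotation intersects the pathway's EC
set; dash-terminated catalog codes (`2.4.1.-`) match by prefix, since
enzyme catalogs routinely contain partially specified codes.

Orthogroup expansion adds every focal-species gene that shares an
orthogroup with at least one seed gene. Three choices were genuinely
open and are resolved as follows: (i) expanded genes inherit the union
of the EC labels of their orthogroup's seed genes — inheritance must be
defined somehow, and the union is the least presumptive choice;
(ii) a gene reached by both routes is labelled `keyword` (direct
annotation is stronger evidence than homology), and the provenance
label travels with the gene into every downstream table so
orthology-only discoveries remain identifiable end to end;
(iii) expansion is anchored on focal-species seeds only — orthogroups
whose EC evidence exists solely in other species are not pulled in,
because the retrieval is defined by the focal annotation. Expansion is
monotone and idempotent. Presence/absence tallies over a species subset
follow UpSet semantics: for every species combination, the count of
orthogroups present in exactly that combination.

Candidate SNPs of a pathway are the high-impact SNPs within the
transcribed unit (CDS, introns including splice sites, 5'/3' UTR) of
the pathway's genes; upstream/downstream SNPs are excluded by the
region rule.

# Association, allele effects and expression

Candidate SNPs are gated at MAF ≥ 0.05 (inclusive, over non-missing
alleles among phenotyped samples) and missing rate < 20% (strict).
Phenotype replicates are averaged per (sample, location) and each
location is analysed independently — locations differ in environment,
and the per-location analysis avoids modelling location effects. The
association model is an ordinary least-squares fit of the trait on the
genotype as a class factor (the default of the standard GLM tooling;
an additive dosage encoding is available via `encoding = "dosage"`),
with no structure covariates, and the overall F-test p-value gated at
P ≤ 0.001. No multiple-testing correction is applied beyond that fixed
gate by default; `adjust = "BH"` is available. Retained hits are named
`q<TraitAbbrev><chrom>.<rank>` (e.g. `qSC10.1`) in genomic order.

The allele effect compares minor-allele carriers against major-allele
homozygotes with a two-tailed t-test (Welch by default) and reports
$100 \times (\bar y_\text{minor} - \bar y_\text{major}) /
|\bar y_\text{major}|$, sign preserved. The "% of group mean" definition
is one of several plausible effect definitions and is therefore explicit
and configurable at the call site rather than hidden.

A power note for panels of ~45 genotypes: a QTN explaining exactly 30%
of the trait variance has theoretical F-test power 0.795 at
$\alpha = 0.001$ under the additive encoding (0.674 under the 2-df
factor encoding), so near-certain retention is only expected of stronger
QTNs; the package's power demonstrations use a QTN explaining 40% of
variance (theoretical power 0.92–0.97), which is representative of the
large-effect QTNs such panels are designed to find.

Expression is summarised per sample as the mean TPM over replicates and
transformed as $\log_2(\text{mean} + 1)$. The transform is a *positive*
log: a negated log would invert the ordering of expression values, which
contradicts the way allele-linked expression differences are reported
(a more highly expressed allele class should score higher). Allele
classes are compared by the ratio of group mean TPMs; genes reaching a
two-fold change in either direction are flagged by default. Note that
with a handful of expression samples the "minor" allele within that
subset may differ from the panel-wide minor allele, so the fold change
is interpreted two-sidedly.

# Colour indices

From CIELAB coordinates (D65 white point; sRGB conversion via the
standard linearisation and XYZ matrix):

* whiteness index $WI = 100 - \sqrt{(100-L)^2 + a^2 + b^2}$ (Judd
  style);
* yellowness index $YI = 142.86\, b / L$ (ASTM E313 style);
* colour index of red grapes $CIRG = (180 - h)/(L + C)$ with chroma
  $C = \sqrt{a^2+b^2}$ and $h$ the unsigned hue;
* hue index $HI$ = the hue angle $\mathrm{atan2}(b, a)$ in degrees. The
  signed convention $(-180, 180]$ is the default because purple-fleshed
  tubers then take negative values, matching how hue ranges with
  negative lower bounds are reported for purple-flesh panels; the
  unsigned convention $[0, 360)$ is available, and the two differ by a
  deterministic modulo-360 mapping;
* browning index $BI = 100\,(x - 0.31)/0.172$ with
  $x = (a + 1.75L)/(5.645L + a - 3.012b)$ (Buera/Petriella style).

$L = 0$ leaves YI and BI undefined (returned as `NA` with a warning).
Image segmentation is out of scope: the module consumes per-region mean
Lab (or sRGB) values.

# The synthetic study generator

The generator's defaults *are* the study conditions; they are not test
dials. They emulate a diploid greater-yam resequencing panel:

* **Population.** 3 genetic clusters (the K = 3 admixture solution
  typical of such panels) × 36 diploids = 108 samples, close to the
  ~107 diploid genotypes a real panel of this kind retains. Cluster
  allele frequencies follow the Balding–Nichols model: ancestral
  frequency $p_0 \sim U(0.05, 0.95)$, cluster frequency
  $\sim \mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$, with
  $F = 0.05$ background divergence and $F = 0.40$ at selected loci.
* **Genome and sites.** Two 1 Mb chromosomes carrying 1,600 SNPs; 24
  selected loci placed in three 40 kb sweep regions (plus background
  sites that happen to fall inside a sweep, which are also simulated as
  selected — hitchhiking makes divergence a property of the region, not
  of isolated sites). Each sweep is centred on an annotated pathway
  gene.
* **Calls.** Per-call depth ~ NegBin(mean 37, dispersion 8), echoing a
  37× panel with realistic overdispersion; site QUAL ~ N(60, 25)
  floored at 1; 5% of calls missing. These choices deliberately leave
  ~10–12% of sites below the QUAL gate and a tail of low-depth calls,
  so the QC filters act on real material.
* **Genes.** 148 multi-exon protein-coding genes (valid ATG, stop
  codon, GT..AG introns, 100 bp UTRs): 100 carry `ec_number`
  attributes across the three pathways and 48 are orthology-only — a
  planted 48% annotation gain through orthogroup expansion, the
  magnitude a comparative-genomics complement to keyword annotation
  can realistically deliver. Orthogroups also contain members of two
  other *Dioscorea*-like species plus background orthogroups, so
  presence/absence tallies have structure.
* **QTNs.** Three by default (starch content, hardness, hue index),
  planted as stop-gain SNPs inside pathway-gene CDS: the generator
  rewrites an internal codon to TGG and the SNP converts it to TGA, so
  the planted variant is genuinely high impact by construction. The
  first QTN lands in the first sweep's anchor gene, giving one gene
  with *both* divergence and trait evidence — the dual-evidence case
  the cross-reference stage must recover. Planted QTN sites draw
  ancestral frequencies from $U(0.25, 0.75)$, keep cluster frequencies
  away from joint fixation, and carry site QUAL ≥ 40: a planted QTN is
  ground truth for the association stage, and losing it to simulated
  drift or a random low site QUAL would test nothing about the method.
* **Phenotypes.** Trait = baseline + additive QTN effects × dosage +
  i.i.d. normal noise per (sample, location, replicate), scaled so the
  genetic fraction of the per-observation variance equals $h^2 = 0.4$;
  3 locations × 3 replicates. Baselines put traits on realistic scales
  (starch content ~78, hardness ~30, ...) so percentage effects are
  interpretable. Traits without QTNs are pure noise. With $h^2 = 1$
  the trait is an exact affine function of dosage.
* **Expression.** TPM for every pathway gene in 6 samples chosen to
  cover both allele groups at the planted expression SNP (the last
  QTN's host gene, echoing an allele-linked pigment-pathway gene),
  3 replicates each, log-normal baselines around 20 TPM, multiplicative
  replicate noise, and a fixed 4× fold change between allele groups at
  the planted gene.
* **Determinism.** Every stage derives its RNG stream from
  `config$seed` with fixed offsets; a fixed seed reproduces the VCF
  byte for byte.

What the generator does **not** emulate: linkage disequilibrium decay
(sites are exchangeable given cluster frequencies), polyploid
genotypes, read-level errors, multi-transcript isoforms, genuine
phenotypic correlations between traits, or the real trait architecture
of yam. Passing tests therefore demonstrate the *correctness of the
computational chain* under a faithful structured-population model — not
that the pipeline would rediscover specific yam genes from real data.

# Problem sizes

The test suite and the acceptance script run the chain at deliberately
modest sizes chosen as representative while keeping a full run in a few
minutes: 300–1,600 sites, 36–108 samples, 192 windows per pair, 20
replicate studies for the sweep-recovery rate, 100 seeded datasets of
n = 5,000 per family for the AIC model-selection study, 10,000 null
markers for GLM calibration, and 500 random SNPs for the re-translation
oracle.

# Known limitations

* Per-site Fst components are two-population; multi-way comparisons are
  handled pairwise (as in the windowed scans this mirrors), not via the
  general r-population estimator.
* The GLM has no kinship or structure correction; in a structured panel
  the null retention rate is nominal only when phenotypes are
  independent of structure, which the planted-QTN design satisfies but
  real panels may not.
* HGVS notation is approximate (sufficient for the `p.Trp287>STOP` /
  `c.63-2A>G` reporting style, not a full implementation).
* One transcript per gene; UTR assignment assumes the CDS lies inside
  the exon span.
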