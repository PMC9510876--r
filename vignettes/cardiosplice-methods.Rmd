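---
title: "Methods: screening for cardiac splicing factors with cardiosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for cardiac splicing factors with cardiosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosplice)
library(dplyr)
```

# The screening problem

Dilated cardiomyopathy (DCM) is accompanied by widespread changes in
alternative mRNA splicing, and mutations in splicing regulators such as
RBM20 cause severe familial forms of the disease. cardiosplice implements
a computational screen for nominating *new* cardiac splicing factors from
bulk transcriptomic data, together with the downstream analyses that
characterize a nominated factor: exon-level splicing quantification,
RNA-immunoprecipitation (RIP) enrichment, per-exon correlation profiling
and binding-motif scanning.

The screen rests on two orthogonal axes:

1. **Tissue enrichment.** A factor that matters specifically to the heart
   should be expressed in heart muscle and comparatively little elsewhere.
2. **Disease regulation.** A factor driving disease-associated splicing
   changes should itself be differentially expressed between diseased and
   control myocardium.

Genes scoring high on both axes — unlike constitutively heart-restricted
factors, which score high on the first axis only — are the screen's
candidates.

# The heart-specificity score

For gene $g$ with expression $x_{g,t}$ (RPKM-like units, non-negative)
across a panel of tissues containing one heart reference $h$ (left
ventricle by default) and non-heart tissues $T$,

$$\mathrm{HSS}_g \;=\; \frac{1}{|T|}\sum_{t\in T}
  \frac{x_{g,h}+\epsilon}{x_{g,t}+\epsilon}.$$

A uniformly expressed gene scores 1; a gene expressed in heart at $k$
times a uniform background scores $k$; the score is invariant to global
rescaling of the matrix and monotone in the heart entry. Genes with
$\mathrm{HSS}\ge 3$ (the default threshold) are called heart-enriched.

Two aggregation orders are defensible: the mean of per-tissue ratios
(implemented as the default, `mode = "ratio_mean"`) and the heart value
over the mean background (`mode = "mean_ratio"`). We default to the mean
of per-tissue ratios because it weights every tissue equally — a gene
must be low *everywhere else* to score high, rather than merely low on
average — and we expose the other variant behind the mode switch. The
orientation is heart-over-non-heart throughout: a high score means high
heart specificity.

The pseudocount $\epsilon$ (default 0.01, expression units) keeps the
score finite for genes undetected in some tissue. At typical RPKM scales
(medians of a few units) it is negligible for expressed genes; it only
matters for genes near zero everywhere, which are not credible
candidates anyway. An alternative heart reference (atrial appendage)
supports a validation mode, `hss_validate()`, which reports the Spearman
correlation between the two rankings.

# Differential expression

Counts are normalized with median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_{g} \left( k_{gj} / (\prod_j k_{gj})^{1/m} \right)$
over genes positive in all $m$ samples. This is the standard RNA-seq
normalization; it assumes most genes are unchanged between conditions,
which holds by construction in the synthetic data and approximately in
screening cohorts.

Per gene, a **pooled-variance two-sample t-test** (Student's t; Welch's
correction behind a flag) compares normalized counts between disease and
control. We screen at raw $P<0.05$ without multiple-testing correction —
the screen is a hypothesis generator whose output is validated
downstream, not an inference endpoint — and expose Benjamini–Hochberg
adjustment behind `adjust = TRUE` for users who want controlled false
discovery. Fold change is the ratio of group means; when one group mean
is zero, a pseudocount of 0.5 is added to both so the ratio stays finite.
Genes constant within both groups but unequal between them have no valid
t-statistic; they are flagged (`zero_variance`) and excluded from
candidate calls rather than assigned an arbitrary P value.

A candidate is a gene with $\mathrm{HSS}\ge 3$ **and** $P<0.05$
(`nominate_candidates()`); candidates are ranked by P value, then by
absolute log2 fold change.

# Exonic parts and PSI

Exon-level analysis needs a counting unit that is stable across
overlapping isoforms. `flatten_annotation()` segments each gene's exons
at every exon boundary of every transcript and merges maximal runs of
identical supporting-transcript sets, yielding disjoint **exonic parts**
whose union is exactly the gene's exonic sequence. A part supported by a
proper subset of the gene's isoforms is *alternative*. Internally all
coordinates are 0-based half-open (BED convention); GTF input/output
converts at the boundary. Parts are named `gene:NNN` with a zero-padded
index ascending along the genome irrespective of strand.

Per part and sample, evidence is split by interval arithmetic:

- **exclusion**: junction reads whose intron covers the whole part — a
  splice that removes it. This covers both cassette exons (the skipping
  junction strictly contains the part) and retained introns (the spliced
  junction coincides exactly with the intronic part);
- **inclusion**: reads assigned to the part plus junction reads splicing
  into or out of its boundaries (introns abutting the part from outside).

$$\mathrm{PSI} = \frac{\mathrm{inclusion}}
  {\mathrm{inclusion}+\mathrm{exclusion}}$$

after optional length normalization, which divides inclusion evidence by
the number of read placements overlapping the part
($L_\mathrm{part}+L_\mathrm{read}-1$) and exclusion evidence by the
junction-spanning placements ($L_\mathrm{read}-1$). The raw mode is the
right choice when inputs are event-level informative-read counts (as the
synthetic generator emits); normalized mode is for positional coverage.
A part with no evidence in a sample has *undefined* PSI — never 0 or 1.

$\Delta$PSI between conditions is tested per part with the same pooled
t-test on per-sample PSI values; undefined values are dropped pairwise
and parts with fewer defined values than `min_defined` (default: all
samples) are skipped with an explicit reason. Splice-product ratios from
three-band assays and the retention index (largest product over total)
are provided by `retention_index()`.

# RIP enrichment and the bound-and-spliced set

`rip_enrich()` contrasts immunoprecipitated libraries of two conditions
(disease IP vs control IP by default; passing input libraries as the
control side gives an IP-vs-input contrast). Counts are size-factor
normalized across all libraries, fold change is the ratio of normalized
means and a feature is **bound** when enriched at $P<0.05$ with fold
change above 1. `bound_and_spliced()` collapses evidence to gene level —
a gene is bound if any feature is bound, spliced if any exonic part
changes significantly — and intersects the two sets, with an optional
per-chromosome tally of the result.

# Correlation profiles and motif scanning

`exon_factor_correlation()` correlates a factor's expression with each
exonic part's expression across samples (Pearson on log2(x+1) by
default; Spearman and identity transforms behind flags). Zero-variance
parts are reported as missing. Profiles of two factors over the same
gene are compared region-wise with `compare_factor_profiles()` — the
design that localizes a factor's action to, e.g., the exons encoding
titin's elastic PEVK region, where a true regulator shows elevated
coefficients and an unrelated factor does not.

`scan_uwaa()` finds all, including overlapping, occurrences of the
STAR-family binding motif UWAA (U, A-or-U, A, A) with T read as U and N
never matching; overlap counting is deliberate since the motif occurs as
tandem repeats. `mutate_motifs()` designs ablating mutations for
minigene experiments by replacing the two invariant adenosines with C
and G — bases that cannot occur in any match, so the edit provably
cannot create a new site; the mutated sequence is rescanned and verified
nonetheless.

# The synthetic-data generator

Every pipeline input can be simulated with planted ground truth, making
the whole screen testable by parameter recovery:

- **Tissue matrices**: log-normal background expression (log-mean
  $\log 5$, log-sd 1 — an RPKM-like spread), multiplicative log-normal
  noise (sd 0.2) across 53 tissues including left ventricle and atrial
  appendage, and planted heart-enrichment factors.
- **Splice counts**: three-exon, two-isoform gene models (cassette exon
  or retained intron). Informative reads per part and sample are
  Poisson (`depth_per_event`), split binomially into inclusion and
  exclusion by the sample's PSI; an optional beta-distributed PSI adds
  extra-binomial dispersion. Junctions are emitted
  coordinate-consistently with the annotation.
- **RIP counts**: Poisson counts around log-normal feature abundances,
  with case-IP means multiplied by planted enrichment factors.
- **Motif sequences**: uniform-background RNA with motifs planted at
  exact positions and accidental matches removed by rejection (a
  background base inside any stray match is set to C/G), so scans have
  an exact expected answer.

The generative models (Poisson/binomial for counts, log-normal for
abundances) are the standard RNA-seq noise models; effect sizes are
configurable and the defaults — enrichment factor 8, disease fold change
2, $\Delta$PSI 0.3 with a 0.5 intron-retention shift, RIP factor 8,
cohort sizes 4 + 4 (RIP 3 + 4) — are chosen as realistic mid-sized
effects at desk-scale cohort sizes. `simulate_screen_data()` bundles one
complete fixture: one enriched *and* up-regulated factor among 500
genes, ten enriched-but-unregulated decoys, 25 bound-and-differentially-
spliced genes (one of them the intron-retention event) among 40 assayed,
and RIP libraries covering the full gene universe so that the unchanged
majority keeps median-of-ratios normalization well-posed.

What the simulations do **not** emulate: read-level sequencing artefacts
(mapping bias, positional coverage non-uniformity), correlated
biological replicates, isoform complexity beyond two transcripts per
gene, overdispersion of gene-level counts beyond Poisson, and real
tissue-to-tissue correlation structure. Passing recovery tests therefore
demonstrates correctness of the statistics and plumbing under the stated
models, not robustness to every artefact of real data.

# Numerical and design choices

- Coordinates: 0-based half-open everywhere internally; GTF (1-based
  inclusive) and SJ-tab junction files are converted at the I/O
  boundary; BED passes through unchanged.
- Zero-length parts arising from shared boundaries are dropped; abutting
  same-support exons merge into one part (the per-base segmentation
  semantics).
- Exclusion requires the intron to cover the *whole* part, endpoints
  included, so that a retained intron's spliced junction — which shares
  both boundaries with the part — counts as exclusion; junctions abutting
  a part from outside count as inclusion.
- Medians over even counts are the average of the two central values;
  size factors are not rescaled to unit geometric mean.
- Ties and degenerate inputs fail loudly: empty joins, missing columns,
  single-tissue matrices, all-zero retention assays and malformed
  annotation lines raise errors or explicit flags rather than silent
  defaults.
- All generators draw from one integer seed recorded in their truth
  object; equal configuration and seed reproduce outputs exactly.

# Problem sizes used in validation

The packaged validation exercises run at deliberately desk-sized scales:
1000-gene tissue matrices over 20 seeds for enrichment recovery;
200 random gene models against a per-base flattening oracle; 1000-gene
null count matrices (4 vs 4) for t-test calibration; PSI recovery at
depth $10^4$ and power at depth $10^3$ over 20 seeds; 500 null
alternative parts for $\Delta$PSI calibration; 20 end-to-end screen
replicates of the 500-gene fixture; and motif scans up to length
$10^4$ against an exhaustive 4-mer oracle. These sizes give
Monte-Carlo error well inside the asserted bands while keeping a full
validation run in the low minutes.

# Known limitations

- The HSS is a ratio statistic; with very small $\epsilon$ it is
  sensitive to near-zero background tissues. The mean-of-ratios default
  makes a single silent tissue inflate the score; users scoring noisy
  panels may prefer `mode = "mean_ratio"`.
- Raw-P screening at 0.05 deliberately trades false positives for
  sensitivity; downstream stages (RIP, PSI) are the filter.
- PSI evidence assignment handles cassette exons, retained introns and
  alternative splice sites that remove a whole part; events that remove
  only part of a part (boundary shifts within one counting bin) are not
  classified.
- The t-test on PSI values treats per-sample PSI as approximately
  normal; at very low depth a count-based test would be preferable.
- No multiple-testing correction is applied by default anywhere;
  Benjamini–Hochberg is available behind `adjust = TRUE` flags.
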