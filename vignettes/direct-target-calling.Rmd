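---
title: "Calling direct transcription-factor targets from ChIP-seq and expression data"
author: "tfdirect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct transcription-factor targets from ChIP-seq and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdirect)
```

# The analysis

A transcription factor (TF) that drives a differentiation program — the
motivating system is a posterior Hox protein induced in neuroblastoma cells —
leaves two genome-wide footprints: binding sites mapped by ChIP-seq, and
expression changes measured across induced versus control replicates.
Neither footprint alone identifies *direct* regulation: many bound genes do
not change expression, and many responsive genes respond indirectly.
`tfdirect` implements the standard integration:

1. **Responsive genes.** For each gene, a one-way ANOVA across the two
   conditions and a signed fold change of condition means.  A gene is
   responsive when $|FC| \ge 1.5$ and $P < 0.01$.
2. **Bound genes.** A gene is bound when at least one ChIP peak (FDR < 1%)
   overlaps its locus extended by 5 kb on each side.
3. **Direct targets.** The intersection: bound *and* responsive, carrying
   the expression direction.

Around this core, the package reproduces the supporting genome-wide
characterizations: classification of peaks into functional categories with
size-normalized densities, summit distance to the nearest transcription
start site (TSS), inter-replicate reproducibility as windowed tag-density
correlation, consensus-motif enrichment under peak summits, and
hypergeometric over-representation analysis (ORA) of the resulting gene
lists.

# Models, definitions and numerical choices

## Coordinates

All coordinates are 0-based, half-open (BED native), on disk and in memory;
the single convention removes off-by-one ambiguity at every boundary.  The
TSS of a gene is `start` on the `+` strand and `end - 1` on the `-` strand.
Peaks are strandless (ChIP enrichment is double-stranded); when a peak file
lacks a summit column the summit defaults to the floor of the interval
midpoint.

## Differential expression

The ANOVA is computed on log2-transformed intensities; with two groups it is
exactly the pooled two-sample t-test ($F = t^2$).  The fold change is
computed on *linear-scale* condition means and reported in the signed
convention with magnitude $\ge 1$: $+\,induced/control$ when induction
raises the mean, $-\,control/induced$ otherwise, so the thresholds read
"$\ge +1.5$ and $\le -1.5$".  These two scale choices (log for testing,
linear for effect size) are standard microarray practice; the upstream
normalization that produced the intensities is instrument-specific and is
assumed already applied — the package does not quantile-normalize.

No multiple-testing correction is applied at this stage: the responsive
call deliberately uses the raw $P < 0.01$, matching the screening character
of the analysis.  ORA p-values downstream *are* BH-adjusted.

Zero-variance groups (which arise by construction in noiseless synthetic
data) are resolved deterministically: $p = 1$ when the group means are
equal, $p = 0$ when they differ.

## Peak classification

Each peak is assigned exactly one of seven categories — promoter, 5'UTR,
3'UTR, exon, intron, downstream, intergenic — by the position of its
**summit**, with the precedence

> promoter > utr5 > utr3 > exon > intron > downstream > intergenic.

Classification by the summit (rather than whole-peak overlap) guarantees a
partition whose fractions sum to 100%.  The precedence puts the regulatory
categories the analysis highlights (promoters, UTRs) above the gene-body
categories that would otherwise absorb them; the same precedence is applied
per base pair when computing category *sizes*, so category sizes always sum
exactly to the genome length and the size-normalized density
(peaks per 100 kb of category) is well defined.  The promoter is the 5 kb
window immediately upstream of the TSS in gene orientation; downstream is
the 5 kb past the gene end; UTRs are each gene's exonic sequence between
its transcript and CDS bounds; both extents are parameters.

Nearest-TSS distances are signed in the orientation of the nearest TSS's
gene (upstream negative) and binned at 100 bp.  Equidistant TSSs are broken
toward the smaller coordinate, then the `+` strand, so the histogram is
deterministic.

## Binding and direct targets

"Within −5 ~ +5 kb of a gene" is read as the gene **locus** (transcript
span) extended by 5 kb on each side — not TSS ± 5 kb.  This reading follows
the phrase "within 5 kb upstream or downstream of their genomic loci" and
changes the counts materially, so it is stated prominently here.  Binding
requires at least one shared base pair between the peak interval and the
extended locus under half-open semantics; a summit-containment mode is
available as a sensitivity analysis (`binding_genes(mode = "summit")`).
One peak may bind several genes.  Gene identifiers are matched as exact
strings.  Reported percentages are rounded half-away-from-zero to one
decimal.

## Replicate reproducibility

Tag densities are counts of read 5' ends in 200 bp non-overlapping windows;
the last, shorter window of each chromosome is kept so that every tag is
counted.  The Pearson correlation is computed over **all** genome windows by
default, including windows empty in both replicates, because that makes R a
function of the data alone rather than of a coverage support threshold; a
`nonzero_only` mode restricted to covered windows is also provided and both
are reported by the workflow.  R > 0.9 is flagged "highly correlated".
Zero variance in either vector is an error, not a number.

## Motif analysis

"100 bp flanking sequences from peak summits" is ambiguous between 100 bp
per side and 100 bp total; the package takes 100 bp **per side** (200 bp
records), preserving symmetric context, with the flank configurable.  The
records are written as FASTA for external discovery tools; the package
itself implements only consensus scanning for the AT-rich Abd-B-type site,
default `WTTTAT` (i.e. T/ATTTAT), as degenerate IUPAC matching on both
strands.  `N` in a subject sequence never matches.  Enrichment compares the
fraction of foreground sequences with at least one hit against a
**mononucleotide** shuffle of the same sequences (seeded Fisher–Yates per
sequence, composition- and length-preserving) with a one-sided binomial
p-value at the background rate.  A dinucleotide shuffle would preserve more
local structure and is a stated limitation.  Position-weight-matrix scoring
and E-values belong to the discovery tools and are out of scope.

## Over-representation

ORA uses the standard hypergeometric upper tail
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, with fold
enrichment $(k/n)/(K/N)$ and BH-adjusted FDR, filtered at fold > 2.0
(strict) and FDR < 1% (strict).  The widely used DAVID tool scores with an
EASE-penalized variant (one overlapping gene removed); the plain
hypergeometric is the default here because it is exactly testable by
enumeration, and `ease = TRUE` provides the penalized score for comparison.
The default universe is all genes on the expression platform, matching the
context in which the study lists were formed.

# The synthetic study

The generator produces the complete statistical structure the analysis
assumes, so every stage is testable without any download.  Defaults
describe the study conditions the pipeline is meant for:

* **Genome**: 3 chromosomes × 500 kb, 20 genes each, random strands and
  exon structures, inter-gene gaps ≥ 12 kb so that neighbouring ±5 kb
  extended loci never overlap.  Packing feasibility is checked from the
  configuration alone, so infeasible configurations fail for every seed
  rather than sporadically.
* **ChIP**: 40% of genes bound, one true site per bound gene (60% in the
  promoter, the rest in the gene body), six additional intergenic sites,
  ~200 tags per site over a 0.2 tags/window background, and three noise
  peaks per replicate carrying FDR > 1% so the standard filter removes
  them.  The consensus `WTTTAT` is written into the genome under each
  flagged summit.
* **Expression**: 3 control vs 3 induced samples; 30% of genes carry
  planted signed fold changes of magnitude $1.5 + \mathrm{Exp}(2)$
  (40% up), applied to log-normal baselines under multiplicative noise of
  CV 0.1.  Responsiveness is drawn at the same rate inside and outside the
  bound set, which makes the expected share of responsive genes that are
  direct targets equal the bound fraction (~40%), mirroring the proportions
  such experiments report.
* **Gene sets**: one planted set containing the responsive genes plus a few
  others, and five random sets — the planted set should rank first in any
  correct ORA.

**Replicate correlation calibration.**  Window counts for the two
replicates are Poisson draws from mixed intensities
$\lambda_r = w\mu + (1-w)\nu_r$, where $\mu$ is the shared per-window
intensity profile and $\nu_r$ is an independent permutation of $\mu$.
Writing $m = \overline\mu$ and $v = \mathrm{Var}(\mu)$,

$$\rho(w) = \frac{w^2 v}{m + v\,(w^2 + (1-w)^2)},$$

which is solved for $w$ in closed form given the target $\rho$ (0.93 by
default).  The achievable maximum is $v/(m+v)$ (about 0.97–0.98 under the
default intensity profile); targets above it fall back to the fully shared
mixture with a warning.  At $\rho = 1$ with zero summit jitter the second
replicate is an exact copy.  The test suite verifies the realized
correlation across 20 seeds against the 0.93 target within ±0.05.

Each generator draws from its own RNG stream seeded at a fixed offset from
the master seed, so adding or re-running one generator never perturbs
another's output.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: read-level sequencing (FASTQ, mapping,
duplicates), fragment-size geometry, GC and mappability bias, peak-caller
behaviour (peaks are generated, not called), probe-level microarray
artefacts and normalization, correlated co-regulation between genes, and
realistic gene-set topology.  The synthetic study validates the *logic and
arithmetic* of every stage, including exact ground-truth recovery in the
noiseless limit, not the upstream measurement process.

# Problem sizes

The bundled analyses and tests run on the desk-scale defaults above: a
1.5 Mb genome (7,500 correlation windows), 60 genes, ~30 peaks per
replicate and a 3-vs-3 expression design.  These sizes were chosen so the
complete synthetic study exercises every code path — multi-chromosome
bookkeeping, strand mirroring, edge truncation, FDR filtering — while a
full pipeline run stays in the seconds range; all algorithms are written
against interval and string machinery (GenomicRanges, Biostrings) that
scales to genome-sized inputs unchanged.

# Degenerate inputs and tie-breaks, in one place

* zero-variance expression groups: $p \in \{0, 1\}$ by mean equality;
* empty peak set: all-zero annotation summary, flagged, fractions reported
  as 0;
* peak on a chromosome unknown to the feature index: intergenic, with a
  warning;
* summit flank running off a chromosome end: truncated record, with a
  warning;
* no responsive genes: target percentage flagged undefined rather than NaN;
* motif absent from foreground and background: fold flagged undefined,
  $p = 1$; background rate 0 with foreground hits: fold flagged infinite;
* equidistant TSSs: smaller coordinate, then `+` strand;
* non-coding genes: no UTR intervals, their exons remain exons.

# Known limitations

Pre-collapsed gene models are required (one record per locus): when several
transcripts share a locus the caller must choose the representative, and
bound/target counts depend on that choice.  The DE stage assumes the
expression matrix is already normalized.  Consensus scanning deliberately
stops short of PWM scoring.  The ORA gene-universe choice materially
affects p-values; the default (all expression-platform genes) is one
defensible choice among several.
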