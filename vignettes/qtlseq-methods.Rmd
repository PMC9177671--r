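---
title: "Methods: bulked-segregant QTL mapping with simulated null bands"
author: "bulkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL mapping with simulated null bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The method

Bulked-segregant analysis by sequencing (QTL-seq) detects trait-linked loci
from two pooled DNA samples: the most extreme individuals at each end of a
segregating population's phenotype distribution. In an F2, an unlinked
marker segregates 1:2:1, so both bulks carry each parental allele at
frequency 1/2 and sequencing reads split evenly. Near a causal locus,
selection on phenotype skews the bulks in opposite directions.

The per-site statistic is the **SNP-index**, the fraction of aligned reads
carrying the alternate allele (the allele of the parent the reads were
*not* scored against):

$$\mathrm{SNPindex} = \frac{\text{alternate-allele read count}}{\text{total read count}}$$

and the contrast between bulks is the **ΔSNP-index**,

$$\Delta = \mathrm{SNPindex}_{\text{high bulk}} - \mathrm{SNPindex}_{\text{low bulk}},$$

which is near 0 at unlinked sites and approaches ±1 at a locus where the
two bulks are fixed for opposite parental alleles. Because reads are
scored against a *pseudo-reference* — the public reference with the
sequenced parent's homozygous SNP alleles substituted in
(`apply_snp_substitutions()`) — a site where the high bulk matches that
parent and the low bulk carries the other parent's allele has indices
(0, 1) and Δ = −1.

## Site filters

`apply_site_filters()` implements three removal rules, each recorded as a
flag so filter accounting is auditable:

* **depth**: sites need ≥ 7 reads. The source protocol's phrasing ("read
  depth < 7 in both the bulks ... filtered out") literally removes only
  sites thin in *both* bulks; the default here requires depth ≥ 7 in
  *each* bulk, the stricter convention standard in QTL-seq practice, with
  the literal reading available as `depth_rule = "require_either"`.
* **spurious index**: sites with SNP-index < 0.3 in *both* bulks are
  removed. The literal "in either of the bulks" reading would delete every
  Δ = −1 site (one bulk always has index 0), i.e. every causal candidate
  the method is designed to find, so the both-bulks rule — whose purpose
  is to drop false SNPs supported by a minority of reads in both pools —
  is the default; the literal rule remains available.
* **homozygosity**: a bulk call is homozygous when its index is ≤ 0.1 or
  ≥ 0.9 (threshold configurable; caller genotypes are used when present).
  Both bulks must be homozygous for a site to feed the causal-SNP rule.

For the default rules the three tests commute, so the filter order is
immaterial; the order-invariance is asserted by test.

Sliding windows are computed over sites passing the depth and
spurious-index rules only. The homozygosity rule gates the *causal-SNP*
flag (`flag_causal()`: Δ exactly −1), not the window track: under the null
a homozygous-only subset retains just the |Δ| ≈ 1 sampling extremes and
would destroy the calibration of the confidence bands.

## Null confidence bands

The no-QTL null is simulated, not approximated (`simulate_null_delta()`):
each bulk of $B$ plants draws its allele frequency as
$\mathrm{Bin}(2B, 1/2)/2B$ (the 1:2:1 dosage law pooled with equal DNA
contribution per plant), then observed counts as
$\mathrm{Bin}(d, f)$ at read depth $d$. Empirical α/2 and 1−α/2 quantiles
(inverse-ECDF, so bounds are attained values of the discrete small-depth
distribution) give two-sided bands at P < 0.05 and P < 0.01.

A 1 Mb window averages its member SNPs, and markers within a window are in
near-complete linkage (≈ 1–3 cM), so the genetic draw is common to the
window while read noise is per-site and averages out. The band for a
window is therefore simulated for the null *window mean*: one frequency
draw per bulk per replicate, read noise over the window's $n$ member SNPs
at its median depths. Distributionally the mean of $n$ same-frequency
binomial indices at common depth $d$ equals $\mathrm{Bin}(nd, f)/(nd)$,
which is what is drawn — one binomial per replicate, making thousands of
per-window bands cheap. A per-site band (`n_snps = 1`) is the special
case. Bands are cached by (depth pair, bulk size, n, replicates, seed);
10,000 replicates per band by default.

The optional redraw of null replicates failing the observed-data filters
is off by default: at fixed depth the depth rule is vacuous, the
both-bulks index rule removes well under 1% of null mass at the depths
modeled here, and conditioning on homozygosity would leave only |Δ| ≈ 1
draws. The exact-enumeration oracle used in the tests (full multinomial ×
binomial probability mass at bulk size 2, depth 2) is likewise
unconditioned.

## Region calling

Windows whose mean Δ leaves the band at the calling level (default
P < 0.05, the level at which the mapped regions in the motivating study
were reported) are merged when overlapping or within one step
(`call_regions()`), and boundaries are reported in Mb to two decimals, the
span being the difference of the rounded boundaries (19.22–20.80 Mb spans
1.58 Mb; 6.69–8.88 Mb spans 2.19 Mb).

A per-window band controls the *per-window* error rate; with several
effectively independent genetic blocks per chromosome, some window
somewhere strays outside a 95% band in a sizeable fraction of null
genomes. The retained control is the causal-SNP rule: a merged region is
kept only if it contains at least one Δ = −1 SNP that passed all filters.
A fully fixed, opposite-allele site at filter-passing depth essentially
never arises without a linked locus (per-site probability ~10⁻⁸ at depth
14), while a real QTL region contains several, so the rule suppresses
genome-wise false positives without touching band calibration. Both are
testable separately: band coverage on distant null windows is ~5% at the
95% band, and null genomes yield zero regions in well over 90% of runs.

## The simulator and its defaults

`sim_config()`/`simulate_f2()` generate the study design the analysis
assumes. Gametes follow a Markov chain along each chromosome with
inter-marker recombination by the Haldane map function
$r = \tfrac12(1 - e^{-2d})$ (no crossover interference — the minimal
standard choice absent map-function information); two independent gametes
form each F2 plant, so dosages segregate 1:2:1.

Defaults and the reasoning behind them:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 179 | the modeled F2 population size |
| `bulk_size` | 15 | 15 plants per extreme bulk |
| `mean_depth` | 14 reads | bulk sequencing depth of ~13.4–15.1× |
| `seq_error_rate` | 0.001 | typical short-read substitution error |
| marker density | 80 /Mb (2400 per 30 Mb chromosome) | ~47k usable SNPs genome-wide in the motivating data |
| genetic map | 3 cM/Mb | legume-scale recombination |
| DF additive effect | 19 days | parental means 105 and 67 ⇒ homozygote gap 38 days |
| DF dominance | −6 days | slight dominance toward earliness (late-bulk maxima fall short of the late parent) |
| `trait_noise_sd` | 14 days | yields PVE ≈ 0.49 for the major locus, matching its interval-mapping estimate (~48%); the polygenic background is folded into this Gaussian term |
| leaf-shape locus | Mendelian recessive | obcordate only as reference-parent homozygote; 3:1 classes |
| `misclass_prob` | 0 | the recorded Mendelian phenotype is treated as truth; contamination is an explicit option |
| depth model | Poisson | fixed-depth mode exists for exact oracles |

Sequencing error is a symmetric two-allele flip: the observed alternate
read probability is $f(1-e) + (1-f)e$; no third allele is emitted. Bulk
pooling is equimolar (equal weight per plant), matching the stated
protocol; pooling noise (e.g. a Dirichlet contribution model) is out of
scope. Genotype dosage counts the *reference-parent* allele, so the
sequenced ALT frequency is $1 - \text{dosage}/2B$; this orientation
reproduces the published sign convention (high bulk index 0, Δ = −1 at
causal sites).

One consequence worth knowing for recessive Mendelian traits: the
recessive-class bulk is genotypically pure (index 0 at the locus), but the
dominant-class bulk is a 1:2 mixture of homozygotes and heterozygotes, so
its true index is 2/3, not 1. Window means of ≈ −2/3 still leave any
band, and Δ = −1 *sites* arise through finite-depth sampling of the 2/3
frequency — a handful per region at depth 14, which is what the causal
rule needs. Quantitative-trait bulks selected from distribution tails can
be genuinely fixed and show many Δ = −1 sites.

What the simulator does not emulate: alignment and mapping-bias artifacts,
indels and structural variants, library or GC biases, contaminated or
swapped samples, multi-QTL genetic architecture (one locus per trait plus
Gaussian background), and linkage disequilibrium with unmodeled pedigree
structure. Passing tests therefore demonstrate the statistical machinery
under the stated sampling model, not robustness to real-data artifacts.

## Pseudo-reference and effect annotation

Parent variants qualify for substitution when biallelic SNPs at depth ≥ 7
called homozygous-alternate (alt fraction ≥ 0.9 absent a genotype call) —
declared defaults mirroring the bulk-side depth filter, since the source
protocol does not define "confidence variants". Substitution validates the
stated reference base at every position and rejects mismatches and indels
with reasons, preserving sequence lengths; output FASTA is uppercase at 60
columns.

Effect classification uses the canonical (first) transcript per gene, the
standard nuclear genetic code, and transcript-orientation codon extraction
(minus-strand genes reverse-complemented, the alternate base complemented
before substitution). Exonic positions outside the CDS (UTR) count as
"exon" with effect "non-coding", matching the exon/intron dichotomy of
published genic-SNP tables; sites in incomplete terminal codons defer to
"non-coding" with a warning. Overlapping genes report the
lexicographically first gene id as primary. Published tables print
amino-acid names that sometimes disagree with their own codon strings
(e.g. aCg→aTg labelled Cys→Thr; ACG encodes Thr and ATG Met); the
implementation follows the codon strings and the standard code — the
synonymous/non-synonymous call is unaffected.

## Numerical and reproducibility choices

* Quantiles are inverse-ECDF (type 1) everywhere, so band bounds are
  attainable values of discrete nulls.
* Bulk-selection ties are broken by a stable sort on (value, id);
  over-sized categorical classes are down-sampled under a derived seed.
* One run seed fans out to stage seeds by stable string hashing
  (`derive_seed()`), keeping every stage's stream independent of the
  others and all outputs byte-reproducible.
* Sliding windows are half-open 0-based internally and reported 1-based
  inclusive; BED output is 0-based half-open; all TSVs declare their
  convention in a header comment.
* Multi-allelic VCF records are dropped with a message (only biallelic
  SNPs enter the statistics).

## Scale of the validation suite

The test and acceptance runs use desk-scale problem sizes chosen to keep
Monte-Carlo error far below the tolerances they assert: single
10–30 Mb chromosomes with 400–2400 markers, 100 seeded recovery scans,
20 null genomes for coverage, 10⁵ replicates against the exact
small-depth enumeration, and 10⁴-replicate bands elsewhere. The full
published experiment (11 chromosomes, ~600 Mb, tens of millions of reads)
differs only in size, not in any statistic computed.

## Known limitations

Band lookup uses each window's median member depth; long-tailed depth
variation within a window slightly understates read noise (the harmonic
mean would be exact for the average of per-site indices). Region
boundaries inherit window granularity (one step). The causal-SNP rule
assumes the causal locus region retains at least one fully contrasted
site after filtering; extremely low depth or heavy contamination could
starve it, in which case regions can be called at `min_causal_snps = 0`
and judged by band excursion alone.
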