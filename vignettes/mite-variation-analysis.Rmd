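---
title: "Profiling MITE methylation dynamics and insertion polymorphisms"
author: "mitescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling MITE methylation dynamics and insertion polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

## The biological problem

Miniature inverted-repeat transposable elements (MITEs) are short
(< 600 bp) non-autonomous DNA transposons bounded by terminal inverted
repeats (TIRs). They accumulate preferentially near genes, which puts them
in a position to act as mobile regulatory modules in two distinct ways:

* **epigenetically** — MITEs are heavily cytosine-methylated, and a change
  in the methylation level of an element sitting in a gene's regulatory
  region can alter the expression of that gene without any sequence change;
* **genetically** — when a MITE mobilises it reinserts elsewhere, creating a
  transposon insertion polymorphism (TIP) between genomes that differ only
  by that insertion.

`mitescan` implements both readouts for a multi-generation stress-exposure
design: a set of mutagenised lines (for instance plants regenerated after
an environmental exposure such as spaceflight) tracked over generations
(F3–F5), each generation carrying treated ("space") and ground-control
replicates. The package answers four questions: how much does per-element
methylation shift relative to controls and how stable is that shift across
generations; which elements' methylation tracks a phenotype; which
insertions were induced by the treatment; and where in the genome those
induced insertions land.

## Per-element methylation

The unit of measurement is the element, not the cytosine. From a
cytosine-resolution report (a Bismark-style CX table: chromosome, 1-based
position, strand, methylated count, unmethylated count, context), the level
of element $m$ in sample $s$ is, in the default *weighted* mode,

$$\hat{L}_{ms} \;=\; \frac{\sum_{c \in m} k_c}{\sum_{c \in m} n_c},$$

the ratio of methylated read counts to total informative read counts over
all cytosines inside the element interval, both strands, all three contexts
(CpG/CHG/CHH) pooled. This is the depth-weighted mean of per-position
methylated fractions. The phrase "methylated cytosines over total
cytosines" that defines such levels is ambiguous between counting *reads*
and counting *positions*, so a *positional* mode is also provided: the
fraction of covered positions whose methylated fraction reaches a calling
threshold (default 0.5). The mode in use is a recorded argument, and the
two agree in expectation when depth is uniform. Elements with no
informative cytosine are `NA`, never 0 — absence of evidence is not
evidence of hypomethylation — and the exclusion count is reported when
proportions are formed.

Decisions that were genuinely open and how they were fixed:

* **Context pooling.** All three contexts are pooled by default because the
  element-level statistic is a summary of total methylation; a `contexts`
  argument restricts to any subset.
* **Strands.** Both strands count: the element is a genomic interval, not a
  stranded feature.
* **Depth floor.** Any covered cytosine (`minDepthPerC = 1`) is
  informative by default; raising the floor trades coverage for variance.

Differential methylation of a treated sample is its level minus the *mean
level of its matched controls* (same line and generation; n = 3 controls in
the default design). Each treated sample's elements are then dichotomised
into hypermethylated ($\delta > \varepsilon$), hypomethylated
($\delta < -\varepsilon$) and unchanged, with $\varepsilon = 0$ by default
(any shift counts; a dead zone is available for noise-robust runs). The
transgenerational *stability* statistic is the sample standard deviation
(denominator $n-1$) of these proportions across the treated replicates of
one generation: a line whose replicates disagree wildly in a generation has
a high SD, i.e. unstable methylation behaviour.

## TIP calling from soft-clipped reads

A non-reference MITE insertion leaves a precise signature in a reference
alignment. The insertion duplicates a short stretch of host sequence — the
target site duplication (TSD) — so the donor chromosome reads
`…A–TSD–element–TSD–B…` while the reference reads `…A–TSD–B…`. Reads
crossing the element's 5′ junction align up to the *end* of the TSD and
carry the element's 5′ start as a terminal soft clip (CIGAR `S`) at their
3′ end; reads crossing the 3′ junction align from the *start* of the TSD
and carry the element's 3′ end as a clip at their 5′ end. Consequently the
left-clip cluster sits a few bases *upstream* of the right-clip cluster,
and the interval between them is exactly the TSD.

`callTips()` operationalises this as: extract terminal clips of at least
10 bp from primary alignments (mapping quality ≥ 20); single-linkage
cluster breakpoints per side with a 3 bp tolerance, taking the modal
position as consensus; pair left/right clusters whose offset lies in the
TSD length range (2–10 bp by default, the short direct repeats typical of
the Tourist and Stowaway superfamilies); require total read depth over the
TSD interval of at least 5 (all primary alignments overlapping the
interval, clipped or not); and require the two clusters' clipped sequences
to match *opposite termini of the same library element in a consistent
orientation*. Terminus matching is ungapped with one tolerated mismatch
per started 10 bp of clip; each clip votes, and the plurality call wins.
One subtlety is intrinsic to MITEs: because of the TIR, an element's 5′
start equals the reverse complement of its 3′ end, so clips shorter than
the TIR vote for both orientations and only clips longer than the TIR
decide the orientation — with 100 bp reads and ~15 bp TIRs there are always
such clips at real junctions.

Thresholds that the data model fixes (10 bp clip floor, 5× depth, TSD
"aligned") are defaults; quantities the model leaves open are explicit
arguments with documented defaults: the clustering tolerance (3 bp), the
TSD range (2–10 bp), the cross-sample locus-identity tolerance (±5 bp),
and the mismatch allowance. The 10 bp floor is interpreted as the minimum
*clipped-segment* length — it is the clipped fragment that must be aligned
to the element library, and 10 bp is far below any plausible floor for the
genome-side mapped segment.

Cross-sample logic: `diffTips()` is a tolerance-aware two-way set
difference between a sample's calls and a reference sample's calls;
`reconfirmLoci()` genotypes a merged locus list in every sample
(`present` / `absent` / `no_data`, where `no_data` means zero coverage and
deliberately blocks any absence claim); and `spaceInduced()` returns loci
present in at least one treated sample and affirmatively absent in *all*
controls. Rather than differencing against one randomly chosen control, the
pipeline differences every treated sample against every matched control and
reconfirms the union — a deterministic superset of the single-reference
procedure that cannot miss a locus by an unlucky choice of reference.

## Methylation–phenotype association

For every regulatory-region element (any overlap with the window 2 kb
either side of a gene body; strand-aware upstream/downstream labels), the
element's level across samples is Pearson-correlated with a trait, with the
two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom. A hit is *strong* when $p < 0.05$ and $|r| > 0.65$; the magnitude
criterion is applied to $|r|$ because a strong negative coefficient is as
informative as a positive one (a signed mode exists). Both treated and
control samples across all generations of a line enter the correlation
(n = 18 in the default design), since the control samples anchor the
unshifted end of the methylation range. No multiple-testing correction is
applied in the screening rule itself — it is a raw-threshold screen — but
the output optionally carries a Benjamini–Hochberg q column, clearly an
extension. Elements with undefined levels in more than half the samples,
fewer than 6 complete pairs, or zero variance are excluded and counted.

Genomic context of induced insertions uses two utilities: the euchromatic
fraction (each locus assigned by its left breakpoint to a user-supplied
euchromatin/heterochromatin interval map; unannotated gaps are tallied
separately, not guessed) and 1-Mb bin counts along each chromosome
(half-open bins, all bins emitted, so counts always sum to the locus
count). Neighbour-gene context takes the gene overlapping the insertion
point plus the two nearest genes on each genomic side — genomic left/right,
not gene-strand-aware, because an insertion point has no strand.

Two further utilities round out the statistics used in such studies:
`ddctFoldChange()` (relative expression, $2^{-\Delta\Delta C_t}$, replicate
Cts averaged before differencing) and `groupDifferenceTest()` (two-sample
pooled-variance or single-sample t tests).

## What the simulator emulates — and what it does not

`simulationConfig()` + `simulateDataset()` generate every input the
analysis consumes, with a recorded truth table, so the whole pipeline can
be validated by implant-and-recover. The `cohort` preset mirrors the full
study design — 3 mutagenised lines × generations F3–F5 × (3 treated + 3
control) replicates = 54 samples — while the `mini` preset (1 line, 1
generation, 6 samples; 1 chromosome × 200 kb, 10 genes, 20 MITEs, 30×
depth, 100 bp reads, TSDs 2–5 bp) runs every stage in seconds and is the
workhorse of the test suite. Genome sizes are scaled down from a real plant
genome so that a full multi-sample cohort remains a desk-scale object; all
rates and thresholds are kept at their realistic values.

The generator:

* builds each element as `TIR + core + reverse-complement(TIR)` and embeds
  it in the reference flanked by its own TSD;
* places 60% of elements in gene regulatory windows (50–1500 bp from a
  gene) and the rest intergenically, on a deterministic slot layout that
  guarantees non-overlap;
* draws per-cytosine counts Binomial(Poisson(20), level), with per-element
  base levels Uniform(0.2, 0.8), line-specific hyper/hypo shift sets (25%
  of elements each, shifts 0.05–0.3) applied to treated samples, and small
  replicate jitter (sd 0.02);
* emits alignments as already-aligned SAM rather than FASTQ: background
  reads fully mapped at 30×, junction reads soft-clipped with clip content
  taken verbatim from the (oriented) element, reads that would span the
  whole TSD removed (they cannot exist in the donor genome), and a few
  element-internal reads emitted unmapped. At least five clipped reads per
  junction are guaranteed, which is the generator's stated contract that
  every implanted locus is callable at the default thresholds;
* couples one designated regulatory element's level to a trait following
  `trait = baseline + slope · level + noise`, with the noise
  orthogonalised against the levels and mixed so that the *realised*
  sample correlation equals the configured `rTrue` (0.8 by default)
  exactly — the empirical construction familiar from
  `MASS::mvrnorm(empirical = TRUE)`. This makes "a true correlation of
  0.8 built into the cohort" a property of every generated dataset rather
  than a population parameter subject to sampling noise; with `rTrue = 0`
  the trait is instead drawn fully independently, preserving the sampling
  variation a null-calibration study needs;
* implants, per line, 4 treatment-only loci and 2 loci shared with
  controls (10 insertion events per line), ~90% of them in euchromatin.

One master seed fixes every byte of output; per-sample and per-stage seeds
are derived arithmetically from it.

What the simulator deliberately does **not** model: sequencing error and
base-quality structure (an optional per-base error rate exists but is off
by default), PCR duplicates, bisulfite conversion failure, discordant
read-pair signals, nested or truncated insertions, and polymorphism among
element copies. Passing implant-and-recover therefore demonstrates that the
caller's geometry, clustering, TSD pairing and terminus matching are
correct — not that the caller is robust to every artefact of real
sequencing data. Similarly the binomial methylation model validates the
estimator's calibration, not robustness to conversion-efficiency bias.

## Numerical choices

* Intervals are held in Bioconductor containers (`GRanges`,
  `DNAStringSet`, `SummarizedExperiment`), i.e. 1-based closed coordinates
  internally; GFF3/BED/SAM conventions are handled entirely by
  rtracklayer/Rsamtools at the file boundary.
* Breakpoint cluster consensus is the modal member position, smallest on
  ties; neighbour-gene distance ties break by (start, gene id); competing
  TSD pairings of one junction cluster resolve by higher support, then
  shorter TSD.
* The three differential proportions are computed from integer counts over
  one denominator, with the unchanged class as the complement, so they sum
  to 1 exactly.
* Undefined levels (`NA`) propagate and are excluded with logged counts,
  never silently imputed.
* `hyperHypoProportions(epsilon = 0)` means replicate noise makes the
  unchanged class empty in simulated data; that is the intended reading of
  a strict increase/decrease dichotomy.

## Validation summary

The test suite validates each stage against independent oracles:
brute-force all-pairs interval scans for regulatory-context assignment,
hand-computed ratios for the estimators, closed-form t/Pearson formulas,
`stats::cor.test` as a cross-check of the package's own Pearson machinery,
and the Rsamtools BAM route as a cross-check of the SAM text reader. The
acceptance harness re-simulates 50 mini cohorts and demands exact
implant-and-recover (precision = recall = 1, exact breakpoints, TSDs,
element identities and orientations), checks the estimator's 3-standard-
error calibration over 4000 element-seed pairs, and calibrates the
correlation screen under the null (rate of p < α within binomial error of
α = 0.05; the joint significant-and-strong rate is necessarily far rarer,
about 0.4% at n = 18, and is checked against its upper bound) and under a
true correlation of 0.8 (target element top-ranked and strong in ≥ 90% of
seeds). Pipeline determinism is asserted byte-for-byte on all tabular
outputs. Problem sizes (200 kb mini genomes, 50/200 seed batches, 200 × 20
estimator grid) were chosen as the smallest designs at which these
properties are sharp.

## Worked example

```{r example, eval = FALSE}
library(mitescan)

cfg <- simulationConfig("mini", seed = 7)
runSimulate(cfg, "dataset")
runPipeline("dataset", "results")

# per-element methylation levels across the 6 samples
lev <- read.delim("results/methylation_levels.tsv", comment.char = "#",
                  check.names = FALSE)

# treatment-induced insertions with TSDs and matched elements
read.delim("results/space_induced.bed", header = FALSE,
           col.names = c("chrom", "start0", "end", "locus_id", "support",
                         "strand", "tsd_seq", "mite_id"))

# the methylation-phenotype screen, strongest correlations first
head(read.delim("results/correlation_hits.tsv", comment.char = "#"))
```

## Known limitations

* The caller uses soft-clip evidence only: no discordant-pair support, no
  excision (absence-from-reference) calling, no genotype likelihoods.
* Terminus matching is ungapped; a clipped fragment containing an indel
  relative to the library element will not match. For ~10–80 bp fragments
  and a curated element library this is rarely limiting, but a
  local-alignment fallback is out of scope.
* The correlation screen reports raw p-values by design; with thousands of
  elements the strong-hit list is a screening set, not a
  multiplicity-controlled discovery set.
* `reconfirmLoci()` re-reads each alignment file once per sample; for
  cohorts far beyond the simulated scale an indexed-BAM region-query
  strategy would be preferable.
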