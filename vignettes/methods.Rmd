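---
title: "Methods: 3' read-through detection, remnant quantification and DMR calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3' read-through detection, remnant quantification and DMR calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthrough)
```

## The biological question and the measurement model

When 5'→3' exoribonucleolytic RNA surveillance is impaired — directly, by
loss of a nuclear XRN exoribonuclease, or indirectly, through accumulation
of the XRN-inhibiting metabolite PAP in *fry1* mutants — RNA polymerase II
read-through products downstream of mRNA 3' ends escape degradation and
accumulate. Under the torpedo model of termination these uncapped 3'
"extensions" are normally destroyed almost as fast as they are made, so
their steady-state abundance in a wild-type strand-specific RNA-seq
library is close to zero, and their appearance in a mutant is a sensitive
readout of the surveillance defect.

The package measures this with a deliberately simple window statistic.
For every annotated transcript unit, a fixed-length window (default 500
nt) is laid immediately downstream of the annotated 3' terminus on the
gene's strand: bases `end+1 … end+500` for a `+` gene, `start−500 …
start−1` for a `−` gene, truncated at chromosome boundaries. Reads of
each replicate library that overlap the window by at least 1 bp on the
same strand are counted, and abundance is expressed as RPKM,

$$\mathrm{RPKM} = \frac{c}{(L/10^3)\,(N/10^6)},$$

with `c` the window count, `L` the window length and `N` the library's
total number of uniquely mapped reads. The 500-nt length reflects the
observation that most read-through products are shorter than ~800 nt;
sensitivity to the choice is a matter of rerunning with a different
`length` argument, not of the code.

## The four-parameter extension filter

A gene is called a 3'-extension candidate in a mutant/wild-type
comparison when all of the following hold (all comparisons strict):

1. **Fold change** mutant/WT of replicate-mean downstream RPKM > 5. When
   the WT mean is exactly 0 and the mutant mean positive the fold is
   `+Inf` and passes any finite cut — these are exactly the "new
   transcript" cases; when both means are 0 the fold is undefined and the
   gene fails. No pseudocount is used.
2. **Abundance**: mutant mean downstream RPKM > 1.
3. **Reproducibility**: two-sided pooled-variance (Student) two-sample
   t-test on per-replicate RPKM, p < 0.1. We read "Student t-test"
   literally as the equal-variance form (`df = nA + nB − 2`) rather than
   Welch. Zero-variance degeneracies are mapped to definite p-values
   (1 for equal constants, 0 for different constants) so the filter stays
   total; with fewer than two replicates in a genotype the p filter is
   skipped with a warning.
4. **Non-pri-miRNA**: the gene is not a MIR locus and its downstream
   window does not overlap one on either strand. Without this, pri-miRNA
   3' remnants (a distinct decay substrate, see below) would flood the
   extension list.

The *relaxed* preset lowers the fold cut to 2 and drops the p filter.
Because every relaxed criterion is implied by the default one, the
default call set is provably a subset of the relaxed set; this is tested
as a property on randomized quantification tables. The "raw" count — the
number of genes with any positive mutant downstream RPKM — is reported
alongside; an alternative reading (positive in mutant *and* zero in WT)
is implemented as `mode = "new_only"`.

The t-test was applied to per-replicate RPKM rather than raw counts; the
two are proportional within a library, so the choice only matters when
library depths differ, and RPKM is what the filter thresholds are
denominated in.

## pri-miRNA remnants and miRNA-target fragments

Most pri-miRNA gene models cover the hairpin but not the region 3' of it,
yet the decay intermediate of interest — the 3' remnant left after
microprocessor (DCL1) cleavage — lives exactly there. pri-miRNA loci are
therefore quantified on the span-plus-500-nt-pad window
(`primirna_windows()`), and a locus is "expressed" when its mean RPKM is
positive in at least one genotype. The positive-RPKM threshold is the
weakest defensible reading of "expressed"; it is exposed as
`expressed_min_rpkm` for stricter choices.

miRNA targets are profiled with two 200-nt windows clipped to the gene
span: the first 200 nt in transcription order (head; reports the 5'
cleavage fragment and overall transcription) and the last 200 nt (tail;
the 3' cleavage fragment that XRN4/FRY1-dependent decay removes).
Fragment stabilisation appears as a tail fold change far above the head
fold change, with the within-genotype tail/head ratio controlling for
expression level. The ratio is undefined (NA) at zero head coverage.

## The DMR caller

Per-cytosine methylation calls (allc-style: chrom, 1-based position,
strand, context CG/CHG/CHH, methylated count, coverage) from two or more
samples are processed per context:

1. **Scan**: each chromosome is tiled with non-overlapping 100-bp
   windows anchored at coordinate 1. A site is a *difference site* when
   it is covered by ≥ `min_cov` (default 3) reads in every sample and
   its between-sample methylation-level range is ≥ `site_diff_min`
   (default 0.1). Tiles with ≥ 10 difference sites become candidates.
   The underlying per-site "mC difference" rule of the original
   methylPipe procedure is not publicly specified, so our coverage and
   level-difference thresholds are declared, exposed parameters rather
   than hidden constants.
2. **Test**: per-site levels (sites covered ≥ `min_cov` in the given
   sample) are compared across samples with the Kruskal-Wallis test
   (chi-square approximation with midrank tie correction; an exact
   permutation mode exists for verification at small site counts).
   A sample with fewer than two usable sites drops the window.
3. **Join**: neighbouring candidate windows of the same context within
   100 bp are merged transitively; member p-values are combined with
   Fisher's method, −2Σln p ~ χ²(2k). For a singleton the combination is
   an exact identity, so joining never distorts lone windows.
4. **Retain**: joined regions from all three contexts are pooled into a
   single Benjamini-Hochberg adjustment (one genome-wide FDR rather than
   three context-wise ones), and a region is kept when adjusted p < 0.01
   *and* the methylation-density fold between the most- and
   least-methylated sample is ≥ 8. Density is coverage-weighted,
   Σmc/Σcov over every covered cytosine of *all three contexts* in the
   region span; a least-methylated density of exactly 0 with a positive
   maximum gives fold `+Inf`.

Fixed tiling (rather than a sliding window) was chosen because the
100-bp joining step recovers signal that straddles a tile boundary;
any ≥ 200-bp differentially methylated stretch necessarily contains a
complete tile. Strands are pooled and symmetric CG pairs are *not*
merged — each covered cytosine contributes independently.

## The synthetic-data generator

The generator emulates the study's data shapes at desk scale so every
stage can be tested against a known truth:

* **Annotation**: 200 protein-coding genes (800–3000 nt), 10 MIR loci
  (200–400 nt), 15 miRNA targets, half on each strand, placed with
  1–3-kb intergenic gaps on two 600-kb chromosomes. Four convergent
  gene pairs with 3' ends < 500 bp apart are included so that mutual
  extension overlaps exist by construction; their members are always
  planted.
* **Libraries**: genotypes WT, *fry1* and *xrn3* with three replicates
  each. Per-gene expression is log-normal (median 10 RPKM); replicate
  counts are negative-binomial with dispersion 0.1, the standard
  overdispersion model for RNA-seq replicates. Reads are single-end
  fixed-length 42-nt intervals (the study's GAIIx cycle count), placed
  uniformly; there is no splicing or sequencing error because
  quantification consumes intervals, not bases. The nominal library
  depth is 11 million uniquely mapped reads (the study reported ~33–35
  million per genotype over three replicates); emitted reads are the
  subset at simulated loci and `total_mapped` carries the nominal depth.
* **Planted signals**: 40 genes receive mutant-only downstream signal
  with RPKM drawn uniformly from 5–50 (the low end sits deliberately
  near the detection threshold); every gene, in every genotype, also
  receives downstream "leakage" at RPKM 0.05, so the null is not
  artificially clean. All MIR loci get mutant-only remnant signal (2–20
  RPKM) downstream of the hairpin; targets get a 5-fold tail-window
  boost in mutants.
* **Methylomes**: two samples; background cytosines at ~1/15 (CG), 1/20
  (CHG) and 1/10 (CHH) bp with Arabidopsis-like background levels
  (0.25/0.10/0.05) identical across samples; coverage Poisson(20);
  methylated counts binomial. Twenty planted 200-bp regions each carry
  24 evenly spaced CG sites at levels 0.9 versus 0.05 (direction
  alternating), placed away from genes (±500 nt) so that DMR calls
  cannot trivially intersect extension windows — matching the designed
  biological expectation that read-through does not induce methylation.

Everything is deterministic under the config seed; the pipeline report
is byte-identical across reruns, which is itself a test.

What the generator does **not** emulate: spliced and multi-mapping
reads, 3'-UTR annotation error, coverage decay along a real extension
(planted signal is uniform over the 500-nt window), nested/overlapping
gene models beyond the convergent pairs, bisulfite non-conversion error,
and chromosome-scale methylation heterogeneity. A pass on synthetic data
therefore demonstrates the correctness of the window geometry, counting,
statistics and filter logic — not the field performance of the
thresholds on real libraries.

## Numerical and scale choices

* Internally all intervals are `GRanges` (1-based, closed), the
  Bioconductor convention; GFF (1-based) and BED (0-based half-open)
  conversions happen only in `rtracklayer` at the I/O boundary, and the
  BED-like DMR TSV writes 0-based `begin` explicitly. This removes the
  class of off-by-one bugs that motivates 0-based internal coordinates,
  without fighting the container library.
* A read counts for a window on ≥ 1 bp overlap (not 5'-end-in-window,
  not full containment). The rule is deterministic, strand-aware and
  matches `countOverlaps(minoverlap = 1)`; tests pin it against a
  brute-force per-read scan.
* Zero p-values entering Fisher's method are clamped to the smallest
  positive double with a warning; BH adjustment is `p.adjust(method =
  "BH")`.
* Zero-length downstream windows (gene flush against a chromosome end)
  are excluded with a warning rather than carried as untestable rows.
* Test problem sizes — 200-gene genomes, 100-kb methylomes, a 30-kb
  genome for the 200-run DMR null batch — were chosen as the smallest
  scales at which the planted effects and null rates are comfortably
  resolvable; the methylome null uses a small genome because the null
  property is per-run binary (any false call) and needs many runs, not
  long chromosomes.

## Known limitations

* One window per gene: isoform-level 3' ends are not resolved, and
  annotation 3'-UTR error translates directly into window misplacement.
* The caller quantifies presence, not extension length; estimating decay
  endpoints from coverage profiles is out of scope.
* The DMR caller's two-sample default has no biological replication;
  the Kruskal-Wallis "groups" are samples, as in the original two-
  methylome design, and the test's power at 10–30 sites per window is
  modest — the 8-fold density filter does most of the specificity work.
* Because candidate windows are whole 100-bp tiles, a joined DMR span
  can extend past the truly differential stretch into flanking
  background when sampling noise tips a flank tile over the site
  threshold; the flank then dilutes the coverage-weighted density and
  can pull the fold below 8. On the default synthetic conditions this
  costs about one planted region in twenty — visible directly in the
  recovery numbers the tests compute.
* `fold = +Inf` conventions are convenient for strict-threshold
  filtering but mean fold values are not safe to average; downstream
  summaries use counts and fractions instead.
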