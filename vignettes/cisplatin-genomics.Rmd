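---
title: "Mutational spectra and consensus copy-number calling in drug-selected cell lines"
author: "mutsigcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational spectra and consensus copy-number calling in drug-selected cell lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsigcnv)
```

## Motivation

When a cancer cell line is kept for months under a drug concentration that
would kill its parental line, the surviving population carries two kinds of
genomic record of that selection: point mutations with a characteristic
sequence context, and segmental copy-number changes. `mutsigcnv` implements
the computational side of such a study as a reusable, testable pipeline:

1. **Novel-variant extraction** — treated-minus-parental catalog
   subtraction, a read-fraction filter, and classification of events into
   single-, double- and multi-base substitutions, insertions and deletions;
2. **Mutational-spectrum construction** — the 96-category trinucleotide
   profile under the pyrimidine convention, with cosine comparison between
   profiles, stranded 12-class tallies and deletion-flank context;
3. **Consensus copy-number calling** — a three-detector array-CGH pipeline
   (circular binary segmentation, Haar-wavelet breakpoints, penalized
   optimal partitioning) with a 2-of-3 consensus rule and cross-sample
   penetrance;
4. **A seeded simulator** that generates every input with planted truth, so
   each stage can be validated without external data.

## Variant catalogs

A `VariantCatalog` is a normalized table of sequence variants keyed by
`(chrom, pos, ref, alt)`. Normalization uppercases alleles, trims shared
prefix/suffix bases, represents pure indels with a `-` allele, and
left-aligns indels through repeat tracts when a reference genome is
available; catalogs without a genome are compared on raw trimmed keys (a
documented limitation for indel-heavy comparisons). Coordinates are 1-based
inclusive internally; BED output converts to 0-based half-open.

`subtract_parental()` keeps exactly the treated variants whose key is
absent from the parental catalog — the operation that isolates
treatment-acquired mutations. It induces a partition of the treated
catalog, which the test suite asserts on random catalogs.

Two tunable rules matter downstream:

* **Minimum VAF** (`filter_min_vaf`, default 0.10): variants below 10% of
  reads are discarded; the boundary is inclusive (a variant at exactly 10%
  is kept, reading "below 10%" strictly).
* **Adjacent-SNV merging** (`merge_adjacent_snvs`, VAF tolerance 0.05):
  maximal runs of single-base substitutions at strictly consecutive
  positions whose VAFs agree pairwise within the tolerance are merged into
  one event — double-base substitutions for runs of two, multi-base events
  for longer runs. Adjacent substitutions with discordant VAFs are almost
  certainly independent events and are left alone. The merged VAF is the
  member mean.

`summarize_catalog()` reports the tallies an exome study prints (overall,
genes hit, per-type and per-functional-class counts) and maintains
`SBS + DBS + MBS + INS + DEL = overall`. `intersect_gene_sets()` computes
exact Venn-region counts for up to six gene sets by brute-force membership
(gene-level, matching how "genes mutated in all lines" is counted), and
`vaf_matrix()` bins allele frequencies and reports the fraction of
near-homozygous clonal variants at `VAF >= 0.95` — a descriptive cutoff
for the population a selected clone fixes at frequency close to 1.

## The 96-category spectrum

Every single-base substitution is referred to the pyrimidine of the mutated
base pair: six classes (C>A, C>G, C>T, T>A, T>C, T>G), each split by the
5' and 3' flanking bases into 16 contexts. The category order is the
conventional signature layout (classes as listed, contexts by 5' then 3'
base, A < C < G < T). Double- and multi-base substitutions and indels are
excluded from the profile; they are tallied separately by the catalog
summary.

One convention is worth stating precisely: a variant whose reference allele
equals the *complement* of the genome base is interpreted as a minus-strand
representation of the same event and flipped before classification. This
makes the profile exactly invariant to the strand on which a variant was
reported — a property the tests assert — while a genuine reference mismatch
(wrong genome build) still aborts by default (`on_mismatch = "skip"`
downgrades it to a tallied skip). Sites at contig edges or with an `N`
flank are skipped and counted.

`cosine_similarity()` is the usual dot-product similarity on category
vectors: symmetric, scale-invariant, in `[0, 1]` for nonnegative profiles.
Profiles are compared on fractions, so catalogs of very different sizes are
comparable; with fewer than a few hundred substitutions the profile itself
is noisy and similarities should be interpreted cautiously.

For strand-bias tallies (`stranded_class_counts`), "transcribed strand"
means the *template* strand of the covering gene: a substitution counts as
transcribed when the pyrimidine of the mutated pair lies on the template
strand. The convention is isolated in one function so it can be flipped if
a different definition is preferred. Positions outside any gene, or covered
by genes on conflicting strands, are excluded (and reported, so totals
always reconcile). Deletion flank pairs (`deletion_flank_counts`) are
unordered — "between G and C" does not fix an orientation — giving ten
possible base pairs.

## The array-CGH consensus caller

The CNV workflow follows a five-step structure:

1. **Conversion**: feature-extraction software reports reference/tumor
   log10 ratios; these become tumor/reference log2 ratios via
   `log2(t/r) = -log10(r/t) / log10(2)`.
2. **Probe QC**: probes flagged as non-uniform or saturated
   (`gIsFeatNonUnifOL`, `rIsFeatNonUnifOL`, `gIsSaturated`,
   `rIsSaturated`), or with a raw log-ratio of exactly zero (the upstream
   sentinel for unusable spots), are removed.
3. **Breakpoint detection** by three independent methods (below).
4. **Consensus calling**: a region is gain/loss only if it spans at least
   5 oligos, its mean log2 ratio exceeds 0.25 in magnitude (strictly), and
   at least 2 of the 3 methods support it in the same direction.
5. **Reporting**: positions, sizes, probe counts, mean log ratios,
   supporting methods and overlapping genes; multi-sample runs add a
   penetrance table.

### Noise calibration: DLRS and UNDO.SD

The derivative log ratio spread is the robust noise scale of an array:
`IQR(diff(x)) / (1.349 * sqrt(2))`, computed per chromosome and combined as
the probe-count-weighted median. First differences cancel the piecewise-
constant signal, and the IQR ignores the few differences that straddle real
breakpoints, so DLRS estimates probe noise rather than biology. The CBS
undo parameter is tied to the calling cutoff as `UNDO.SD = 0.25 / DLRS`:
adjacent segments whose means differ by less than the 0.25 log2 cutoff are
not worth keeping apart.

### The three detectors

**CBS** (`segment_cbs`): recursive circular binary segmentation. On each
interval the maximal arc statistic
`|S_j - S_i - m/n * S_n| / sqrt(m (1 - m/n))` is located (compiled scan);
the split is accepted if its permutation p-value is below `alpha = 0.01`
(1000 permutations, early-stopped once significance is impossible).
Accepted splits then pass the UNDO.SD re-merging step. Singleton outliers
are clamped toward a running median *before* break detection — the
customary smoothing companion of CBS; without it one heavy-tailed probe
dominates the permutation reference on every interval and masks real
breakpoints. Segment means are always computed from raw values.

**Haar** (`segment_haar`): undecimated Haar-wavelet coefficients across
dyadic scales contrast the next `2^(s-1)` probes against the previous
`2^(s-1)`. Local maxima are tested against a Gaussian null with SD
`mad(diff(x)) / sqrt(2)` and thresholded per scale by Benjamini-Hochberg
FDR at `q = 0.001`; significant peaks are unified across scales strongest-
first, suppressing neighbours within a peak's own half-window. On noiseless
input the robust noise estimate is zero and any nonzero coefficient is a
breakpoint, so exact steps are recovered exactly.

**Penalized partitioning** (`segment_dp`): exact dynamic-programming
minimization of within-segment squared error plus a per-segment penalty,
default `2 * sigma^2 * log(n)` per chromosome with `sigma` the
chromosome's DLRS floored at `1e-6` (the floor keeps noiseless input from
degenerating into singleton segments; any positive penalty then favours
the most parsimonious exact fit). This stands in as the third independent
change-point detector: the consensus rule needs three independent methods,
and an exact least-squares partitioner is a transparent, well-understood
choice.

### Consensus construction

The union of the three methods' breakpoints partitions each chromosome
into atomic regions. Each atomic region takes the mean log2 ratio of its
member probes; a method *supports* it in a direction when the method's
covering segment mean crosses the same ±0.25 threshold in that direction
(directional agreement — support for a gain cannot come from a segment
that looks like a loss). Aberrant status additionally requires at least 5
probes and the atomic region's own mean beyond the threshold (strict
inequality). Adjacent same-status regions are merged for output; the
supporting-method set of a merged region is the union over its parts, each
of which satisfied the 2-of-3 rule on its own. Reported region bounds run
from the first member probe's start to the last member probe's end.

Raising `min_support` from 2 to 3 can only remove calls — a monotonicity
the tests assert — and no aberrant call can ever have fewer than
`min_probes` probes or `|mean| <= threshold`.

### Penetrance

For recurrence across samples, the genome is partitioned at the union of
all samples' aberrant-region boundaries; each atomic interval and direction
receives the fraction of samples calling that direction there (exact
interval-partition overlap, no reciprocal-overlap fuzziness). Fractions are
always multiples of `1/n`; 100% marks a change shared by every sample.

## The simulator

`make_genome()` draws seeded random sequence at a requested GC content
(default 0.41, human-like) and places non-overlapping strand-labelled gene
intervals. `sample_mutation_catalog()` draws substitutions from a
96-category spectrum by indexing every genome position by its
pyrimidine-normalized trinucleotide context and sampling eligible sites
without replacement, so the planted category of every variant is exact by
construction. The shipped `cisplatin_like_spectrum()` concentrates weight
on C>A at ACC/GCC, C>T at CCC/CCT and C>G at GCC over a uniform
background — an illustrative fixture mimicking the qualitative shape of
platinum mutagenesis, not a measured signature.

VAFs follow a two-component mixture: with weight 0.6 a clonal value
(Normal(0.98, 0.02) truncated to (0.95, 1]) and otherwise a subclonal value
uniform on (0.1, 0.6). The clonal truncation bound deliberately coincides
with the 0.95 clonality cutoff used in reporting, so the planted clonal
weight is directly recoverable from generated data; all parameters are
configurable. `make_parental_pair()` plants background variants shared by
both catalogs plus treatment-specific novel variants at disjoint sites, so
subtraction recovery can be scored exactly.

`make_acgh()` tiles probes at 13-kb spacing (the median spacing of a 60mer
oligo design), assigns each probe its truth segment's level plus Gaussian
noise (default sd 0.15 log2 units), replaces a small fraction (default 1%)
by heavy-tailed t(3) outliers, and QC-flags a further fraction (default
2%) to exercise the loading filter. Truth — per-probe levels and a segment
table with status at the 0.25 cutoff — is always emitted alongside the
data.

What the simulator does *not* emulate: read-level errors and mapping
artifacts, dye bias and wave artifacts on arrays, aneuploid baselines
(levels are relative, centred at zero), linkage between mutations, or
selection. Passing tests therefore demonstrate correctness of the
computations under the stated noise models, not robustness to every
artifact of real arrays or sequencing.

## Validation operating points

The test suite and `scripts/acceptance.R` validate the pipeline at fixed
problem sizes chosen to exercise each property well inside a desk-scale
run: spectrum recovery from 10,000 substitutions on a 5-Mb genome
(cosine to source ≥ 0.995); exact strand-flip invariance; exact recovery
of 40 planted novel keys over 100 background variants; DLRS on 10^5 iid
Gaussian probes (within 2%, hence UNDO.SD = 1.25 at sd 0.2); breakpoint
localization within ±2 probes in ≥95% of 100 noisy replicates per method
(step of 0.5, sd 0.15, 40-probe segments); end-to-end consensus precision
and recall ≥ 0.95 pooled over 20 seeded arrays of 500 probes with planted
segments of 5-30 probes at |level| 0.6-1.0 under Gaussian noise sd 0.15;
and zero aberrant calls on noise-only arrays. The end-to-end operating
point uses Gaussian noise only: a 5-probe true segment that loses a probe
to QC-flag removal is uncallable under the 5-oligo rule by design, which
is a property of the corruption process rather than of the caller.

## Known limitations

* Catalogs compared without a reference genome rely on trimmed raw keys;
  equivalent indel representations in repeat tracts may then fail to match.
* The DBS/MBS merging rule (adjacency + VAF tolerance) is a heuristic;
  phased read evidence, when available, is the better arbiter.
* The third breakpoint detector is a penalized least-squares partitioner,
  not an adaptive-weights smoother; it was chosen for exactness and
  independence from the other two methods.
* Whether consensus support should require directional agreement is a
  modelling choice (adopted here); flipping it would only loosen calls.
* No ploidy or absolute copy-number inference is attempted: calls are
  relative to the hybridization partner.
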