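---
title: "Quantifying species abundance in mixed samples with msgbs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying species abundance in mixed samples with msgbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Root samples from species-rich grasslands are mixtures of DNA from many
plant species that cannot be told apart morphologically. Multispecies
genotyping-by-sequencing (msGBS) quantifies the relative abundance of each
species in such a mixture from reduced-representation sequencing reads:
genomic DNA is digested with two restriction enzymes (PacI and NsiI),
adapters carrying a sample index and three random UMI nucleotides per mate
are ligated, and the fragment pool is paired-end sequenced. Because no
reference genomes exist for most of the species involved, the method
builds its own mapping target — a *meta-reference* of de novo read
clusters from single-species ("monoculture") samples, each cluster
labelled with the species it came from — and interprets the per-species
share of mapped reads as an abundance signal.

Two obstacles stand between read counts and biomass estimates, and the
package's two central components address them:

1. **Shared sequence.** Closely related species share homologous loci, and
   monoculture reference material is never perfectly pure, so some
   clusters attract reads from more than one species. The
   *monoculture-based cluster filter* removes them using only the
   monoculture samples' counts.
2. **Species-specific read yield.** The number of reads per unit biomass
   varies severalfold between species (genome size, gDNA extractability,
   restriction-site density). The *calibration key*, estimated from
   samples containing equal biomass of every species, converts the
   within-species read share into an across-species biomass proxy.

## Pipeline stages

`run_msgbs()` composes the stages; each is exported separately.

**Preprocessing** (`preprocess_reads()`): read pairs are demultiplexed on
their dual index tags (exact match by default, `max_mismatch`
configurable; a pair must match exactly one sample on both mates), the
3-nt UMIs from both mates are concatenated into a 6-nt molecule tag,
adapter read-through and low-quality 3' tails (below Q10) are trimmed, and
mates are merged into a consensus when they overlap by at least 20 bp at
90% identity, or else joined with a fixed run of 10 `N` characters. The
`N` junction cannot match any reference base, so a joined read scores as
its two informative arms. Quality trimming is a single maximal
low-quality-suffix scan — simple, idempotent, and adequate for the
constant-quality regime the simulator produces; windowed trimming would
add a parameter without changing any downstream contract. At merge
mismatches the higher-quality base wins and mate 1 wins ties, making the
consensus deterministic.

**Meta-reference construction** (`dereplicate()`, `cluster_sequences()`,
`build_meta_reference()`): per monoculture, identical reads are collapsed
and uniques seen fewer than `min_unique_size` times (default 2; 3 suits
very deep monocultures) are discarded — at typical error rates most
singletons are sequencing-error variants. The remaining uniques, ordered
by abundance then lexicographically, are clustered greedily: a sequence
joins the first-founded centroid reaching 95% identity in either
orientation, else founds a new cluster. Identity is `1 - d / max(length)`
with `d` the unit-cost global alignment (Levenshtein) distance, so end
gaps are penalized; this formulation is deterministic, symmetric in the
sequence pair, and directly checkable against `utils::adist()`, which the
test suite exploits. Per-species clusters are renamed `species_ordinal`
and combined; an optional annotation table (`taxonomic_filter()`) removes
clusters identified as non-Eukaryota or Fungi, standing in for an external
homology search whose live queries would not be reproducible.

**Mapping and counting** (`map_reads()`, `mark_duplicates()`,
`build_count_matrix()`): every assembled read is mapped against all
centroids via exact k-mer seeding (k = 20) followed by ungapped diagonal
scoring, both orientations; identity is matching bases over scored read
bases, with `N` positions excluded and reference overhangs penalized. On
the substitution-dominated reads GBS produces, this equals the semi-global
alignment score; a full DP kernel is included and the tests verify the
agreement. Reads below 95% identity are unmapped. Best-hit ties across
clusters of one species resolve to the first cluster in reference order;
ties across *different* species are discarded as ambiguous. This is
deliberately conservative: a multi-species tie is direct evidence of
shared sequence, and counting such reads anywhere would manufacture
cross-species signal. The cost is read efficiency — in simulations with
impure monocultures a substantial fraction of reads sitting on shared
high-coverage loci is discarded — but proportions, which are all the
method reports, are preserved. PCR duplicates are then flagged within each
(sample, cluster) group as reads sharing the 6-nt UMI (first by identity,
then read id, is kept), and the cluster-by-sample matrix of retained reads
is extracted, dropping clusters with fewer than 10 reads in total.

**Cluster filtering** (`monoculture_filter()`, parameters `f1 = 8`,
`f2 = 15`, `f3 = 1000`): per cluster, reads from the monoculture of its
own species are the *target count*; reads from every other monoculture are
*non-target counts*. A cluster is kept only if (a) the target count is the
strict maximum — a tie means the top count is not uniquely the target
species; (b) the target count is at least `f1`, so step (c) has
resolution; and (c) every individual non-target species' count is at most
`target / f2`, bounding the admissible non-target signal at `100 / f2` =
6.7%. Whether the original three-step rule compares each non-target count
or their sum is ambiguous in prose; both readings are implemented
(`nontarget_sum`), the per-species reading is the default, and the worked
1,094-target/38-non-target example passes under both. Samples whose total
over retained clusters falls below `f3` are removed afterwards.

**Abundance** (`within_species_abundance()`, `calibration_key()`,
`across_species_abundance()`): the within-species abundance of species *s*
in a sample is its summed cluster counts over the sample total. The
calibration key is the per-species mean of the calibration samples'
relative counts, renormalized to sum to 1; a calibration sample is
discarded first if any species' relative value deviates more than 2.5
sample standard deviations from that species' mean. The outlier pass is
single-shot and the SD includes the candidate — an iterative or
leave-one-out variant would be more aggressive, less auditable, and is not
what a one-pass 2.5-SD screen describes. The across-species abundance
divides the within signal by the key and renormalizes; with a uniform key
it reduces to the within signal exactly.

**Evaluation** (`evaluate_fps()`, `evaluate_fns()`, `rfps()`,
`regression_eval()`, `calibration_cv()`): the false positive signal of a
species is its mean estimated abundance over samples where it is truly
absent; false negatives are present-but-undetected entries, with a 1%
across-abundance threshold in calibrated mode and a species-specific
threshold of 1/50 of that species' 50%-biomass-sample mean signal in
non-calibrated mode. For congener groups, the relative FPS is the mean
signal of absent group members over the mean signal of present members
(percent), over samples where the group is partially present and the
present members are detected; the default aggregates as a ratio of means
(a mean-of-ratios option exists — with rounded published inputs the two
differ in the second decimal). Regressions of estimates on true
proportions are unweighted per-species OLS with squared Pearson
correlation.

## The synthetic-data generator

Every stage is testable without external data because
`simulate_msgbs_dataset()` generates the whole study: genomes, a
monoculture per species, equal-proportion calibration samples, and a
rotating mock-mixture grid in which each species anchors five mixtures at
50% biomass while the remaining proportions (20, 10, 10, 5, 5, 0, 0%) are
permuted — so every species also has truly-absent samples for FPS
evaluation. Its defaults are the package's study conditions:

* **Genomes**: 8 species, 1 Mb each, uniform base composition, with PacI
  and NsiI sites seeded at ~1.5 kb spacing so digestion yields a few
  thousand heterologous-ended fragments per genome; cut positions at motif
  midpoints (exact overhang geometry does not affect counts). Pairwise
  homology copies segments of 2 kb *verbatim* between genome pairs, which
  makes shared loci exact and the filter's task well defined.
* **Digestion and size selection**: only fragments with one PacI and one
  NsiI end amplify (two-adapter chemistry); size selection is a hard
  150 bp minimum.
* **Coverage bias**: each (species, fragment) receives a lognormal weight
  (sdlog 1.5) multiplied by an exponential short-fragment preference
  (scale 800 bp), drawn once per library so all samples share the same
  bias, as aliquots of one pooled library do. These two knobs were set
  against the marginal statistics a real msGBS run displays — roughly 40%
  of read pairs merging, strongly uneven per-locus coverage, and
  monoculture references that miss a tail of weakly covered loci.
* **Monoculture impurity**: 2% of a monoculture sample's molecules come
  from the other species, emulating field-grown monoculture root material.
  This is the mechanism that creates mislabelled reference clusters and
  non-target monoculture counts — precisely the signal the cluster filter
  consumes. Mixtures and calibration samples are simulated at their
  declared compositions.
* **Library**: 20% PCR duplicate pairs (re-emissions of an earlier
  molecule with the same fragment and UMI pair), 0.1% per-base
  substitution error over the whole read including UMI and index, constant
  Q30 qualities, 3-nt UMIs per mate, 5-nt dual indices assigned
  combinatorially from a small tag set, 150 nt insert per mate. Yield
  factors default to a geometric ladder from 0.3 to 6 (20-fold), the
  magnitude of between-species yield variation that makes calibration
  necessary.
* **Depths**: 20,000 fragments per monoculture and calibration sample;
  mixtures at 20,000 by default, raised to 100,000 in the deep parameter-
  recovery runs. These sizes keep a full study within minutes on one CPU
  while leaving per-species counts far above every filter threshold.

A single seed drives one RNG stream per simulation; identical seeds give
byte-identical reads and truth tables.

**What the generator does not emulate**: indels and quality-profile decay
(substitution-only errors at constant Q), chimeric fragments, UMI errors,
index hopping, real genome structure (repeats, GC skew, organellar DNA),
and taxonomically structured contamination (the annotation filter is
exercised with synthetic verdicts). Passing tests therefore demonstrate
the pipeline's correctness and its statistical behaviour under controlled
homology, impurity, yield and duplication — not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

* Dereplication orders by abundance descending, ties lexicographically;
  clustering and mapping tie-breaks are by founding/reference order —
  every stage is deterministic given its input.
* Identity thresholds are fractions in [0, 1]; the banded Levenshtein
  kernel uses band `(1 - threshold) * length + 1`, which cannot exclude a
  qualifying pair.
* A genome without cut sites digests to an empty fragment table (not an
  error); an empty meta-reference is a configuration error at mapping; a
  species with clusters but no monoculture sample is a configuration error
  at filtering; a monoculture with zero retained reads yields a flagged
  `NaN` crosstab row; all calibration samples flagged as outliers is an
  error (degenerate calibration set).
* Zero-SD calibration species flag no outliers (deviation 0 is never
  greater than 0); species absent from the key with zero signal are
  carried as zeros, with signal they are an error.

## Known limitations

* The mapper's ungapped scoring under-scores reads whose best alignment
  requires indels; such reads fall toward unmapped rather than being
  miscounted, but genuinely indel-rich data would lose depth.
* Cross-species tie discarding trades read efficiency for specificity;
  with heavily shared references the counted fraction of reads can drop
  well below the mapped fraction.
* The congener rFPS statistic is defined on non-calibrated signals only;
  calibrated rFPS is deliberately not offered because the calibration key
  is itself distorted for congeners that share clusters.
* `f1`, `f2`, `f3` are empirical settings, not derived quantities; the
  package exposes them but does not optimize them.
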