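---
title: "Marker gene-based OTU profiling: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker gene-based OTU profiling: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgotu)
```

## The problem and the model

Shotgun taxonomic profilers that depend on taxonomically annotated
reference genomes systematically miss the large fraction of prokaryotic
diversity that has never been cultured, and the missing organisms bias the
abundance estimates of the organisms that *are* detected.  `mgotu`
implements the marker gene-based alternative: ten universal, single-copy,
protein-coding phylogenetic marker genes (MGs) are present in essentially
all prokaryotes and can be recovered equally well from reference genomes,
metagenome-assembled genomes (MAGs), and single-cell genomes.  Sets of MGs
representing individual genomes are clustered by sequence identity into
species-level, marker gene-based operational taxonomic units (mOTUs), and
metagenomic inserts are quantified against the resulting database.

Two modelling commitments matter most:

1. **The species boundary is a sequence-identity cutoff.**  The default is
   96.5% MG identity, the published species-level calibration for these
   marker genes, applied uniformly to all ten families
   (`default_cutoffs()`); a per-family table can be supplied wherever
   cutoffs are accepted.  Sequence identity is pinned as *matches /
   alignment columns (including internal gaps) of a global alignment* —
   without a pinned definition, a cutoff of 96.5% is not reproducible.
2. **Unknown organisms are quantified, not ignored.**  Marker genes that
   fail every family cutoff are pooled into a single *unassigned* entry;
   at profiling time, inserts whose best hit falls between the report
   floor and the family cutoff are likewise counted as unassigned.
   Carrying this fraction through relative-abundance normalization debiases
   the abundances of the named taxa.

## Database construction and extension

A genome enters the database only if it carries at least **6 of the 10**
families — the published admission rule; genomes with fewer MGs are too
fragmentary to place reliably.  Admitted genomes are mapped against the
database (identity prefilter **0.80**, both strands, mirroring the
published `vsearch --usearch_global --strand both --id 0.8` step) and
assigned to the mOTU with the highest mean per-family best-hit identity,
provided at least `min_assign_families = 3` families individually meet
their cutoff.  The quorum of 3 is our choice: the source method's quorum is
not stated, and 3 balances sparse MG complements against false merging.
Assigned genomes are recorded as members but their sequences are *not*
added, since their species is already represented.

Genomes that fail assignment are clustered de novo into ext-mOTUs by
**greedy centroid clustering**: genomes sorted by family count
(descending) then id, each joining the first centroid whose mean MG
identity reaches the cutoff.  The published pipeline does not state its de
novo linkage rule; greedy centroid (the `vsearch --cluster_fast` family of
algorithms) was chosen for determinism and scalability, and the
deterministic input ordering makes `extend_database()` idempotent —
re-extending with the same genomes changes nothing, which the tests assert.
Ties in assignment are broken toward the lexicographically smaller mOTU id.

Consensus taxonomy per entry follows the majority rule: at each rank the
name carried by more than half of the annotated inputs wins, with per-rank
consistency recorded as *agreeing* (unanimous), *majority*, *not agreeing*
(no majority; the name and all lower ranks become `NA`), or
*not annotated*.

## The profiler

Inserts (an insert is the sequenced fragment; two paired mates share one
insert id and contribute one count) are matched by a k-mer seed index
(k = 14, seeds every 10 bp, both strands) followed by ungapped extension
along the best-voted diagonal.  An insert resolves to its best hit by
identity (ties: longer alignment, then smaller mOTU id):

* identity at or above the family cutoff → that mOTU;
* identity at or above the report floor (**0.93**) but below the cutoff,
  or any hit to an unassigned-entry sequence → *unassigned*;
* no hit of at least 45 bp → *discarded*.

The floor of 0.93 and the minimum alignment length of 45 bp are our
re-implementation choices (the published profiler defers these internals
to its predecessor); both are exposed as parameters.

Per-mOTU abundance is the **mean over the entry's families of
length-normalized counts** (inserts assigned to the family divided by the
family's total sequence length in kb), normalized over all entries
including the unassigned one.  The mean (rather than a trimmed mean or
median) is stable on desk-scale fixtures with few reads per family; where
the unassigned entry holds no sequence for a family, the database-wide
mean family length stands in as the effective length.

Sample handling mirrors the published workflow: samples with fewer than
**5000** mapped inserts are dropped (strictly "less than", so exactly 5000
is kept), counts are rarefied **without replacement to depth 5000**
(`vegan::rrarefy` semantics; a depth above the available total is an
error, not a pass-through), detected taxa are those with prevalence
strictly above **0.1%**, and Shannon diversity is `-sum(p log p)` in nats.

## Synthetic data: what it emulates and what it does not

All generators are deterministic given (parameters, seed) and use a
**substitution-only** mutation model: `mutate_to_identity()` applies
`round((1 - target) * length)` substitutions at positions sampled without
replacement, each to a different base, so the realized global-alignment
identity equals the target to within rounding.  This exact identity
targeting is what makes boundary probing of the 96.5% cutoff possible.
Indels, chimeras, and quality-score-dependent error profiles are *not*
modelled; a passing recovery test therefore demonstrates correctness of
the clustering and quantification logic under controlled identity
structure, not robustness to real sequencing artefacts.

* `make_species_clusters()` allocates mutation positions from disjoint
  pools, so founder-founder identity equals `between_id` exactly and every
  within-species identity exceeds every between-species identity by
  construction — the fixture provably straddles the cutoff.
* `make_16s_like_genomes()` emulates clades (such as the Pelagibacterales)
  whose conserved ribosomal locus saturates in identity while whole-genome
  similarity keeps falling: the embedded locus mutates at 1/5 the
  genome-wide rate and mutation counts are drawn binomially, so the locus
  signal is compressed fivefold relative to its sampling noise while the
  ten concatenated marker genes track the genome rate with ten times the
  sites.  That is the mechanism behind the expected ordering
  r²(mean-MG distance, genome distance) > r²(locus distance, genome
  distance).
* `simulate_inserts()` draws reads proportional to abundance × gene
  length with uniform starts, per-base substitution errors, and random
  strand; the length-normalized estimator is consistent for exactly this
  generative model.
* `make_two_group_cohort()` uses log-normal baselines and noise,
  multiplies group-B means by the planted fold changes, and renormalizes
  each sample — so planted effects are slightly compressed by
  compositionality, as in real data.  Planted taxa default to a baseline
  share of 1e-3: differentially abundant taxa in host-associated
  communities are typically low-abundance, and a low baseline keeps the
  compositional squeeze on the realized fold change small (about 0.004
  log10 units at that share).

## Evaluation statistics

The profile metrics follow the community benchmarking conventions:
presence/absence F1, L1 norm error (range [0, 2]) after renormalizing over
named taxa, completeness and purity with an optional prediction filter,
and weighted UniFrac error over the taxonomy tree with **unit branch
lengths** between consecutive ranks (taxonomies define no branch lengths).
The unassigned fraction is excluded before metric computation, since gold
standards enumerate named taxa only.  The sum-of-ranks composite ranks
tools per (sample, rank, metric) cell with 0 the best rank and ties
sharing the mean of their positions — the tie convention is not stated in
the source material and is pinned here.  Congruence with a reference
profiler is Spearman's rho on concatenated, union-aligned, zero-filled
abundance vectors.

Clustering congruence uses the V-measure (beta = 1, configurable): the
harmonic mean of homogeneity `1 - H(truth|pred)/H(truth)` and completeness
`1 - H(pred|truth)/H(pred)`, with the conventional value 1 when the
corresponding unconditional entropy is zero.  Whole-genome distances come
from a bottom-s MinHash over canonical k-mers (k = 21, sketch 1000 by
default, Mash-like) with `d = -(1/k) log(2j/(1+j))` and ANI estimated as
`1 - d`; distance-distance correlations are computed on distances
(1 - identity), matching the field's "distance" language, and the
correlation fixtures default to k = 12, where the Jaccard signal stays
informative across the 2-25% divergence range they span.

## Differential abundance

The two-group workflow filters taxa to those exceeding **0.1%** relative
abundance in at least one sample (strict), applies a two-sided Wilcoxon
rank-sum per taxon (exact when both groups have at most 25 samples and no
ties, normal approximation with continuity and tie correction otherwise),
corrects with Benjamini-Hochberg, and reports the **generalized fold
change** (gFC): the mean difference of log10 group quantiles over the
0.1-0.9 grid (step 0.1) with a 1e-5 pseudo-count — the cited tool's
defaults, exposed as parameters; quantiles use linear (type 7)
interpolation, pinned for exactness.  A taxon is called at q < 0.05 and
|gFC| > 1 (a tenfold shift).  Note that on compositional data an *exactly*
tenfold planted shift realizes a gFC marginally below 1 in expectation
(renormalization contributes about `-log10(1 + 9 * share)` and the
pseudo-count about `-0.39 * pseudo / Q_A`); with low-abundance planted
taxa both terms stay well inside the quantile-estimation noise.

## Numerical choices

* Alignment scoring: match +2, mismatch -3, gap opening 20, gap
  extension 8.  The stiff gap penalties make the optimal global alignment
  of substitution-only diverged pairs exactly the ungapped one over the
  whole 50-100% identity range (asserted against the full dynamic program
  in the tests), which both pins the cutoff semantics and enables a fast
  Hamming path for equal-length pairs.
* Greedy clustering order: length (or family count) descending, then id —
  every clustering in the package is deterministic and therefore
  reproducible and idempotent.
* Degenerate inputs: identical genomes yield zero distances and an `NA`
  r²; an empty prediction yields purity 0 with a warning; constant
  vectors yield `NA` Spearman rho; rarefaction beyond the available depth
  and aggregation of non-mOTU-level profiles are errors.
* Tie-breaks everywhere are lexicographic on ids, so outputs are
  byte-stable for a fixed seed.

## Problem sizes

The test and acceptance workloads are sized for a laptop-class single
core: communities of 5 species at 10,000 inserts with 0.5% error for
profiler recovery (L1 < 0.05), 50 genomes of 20 kb for the
distance-correlation pattern, cohorts of 20 + 20 samples over 100 taxa
with 50 null replicates for the false-discovery check, and boundary grids
of 51 identity steps for the cutoff probe.  These sizes reproduce every
qualitative phenomenon the package is built around; the headline numbers
of corpus-scale studies (tens of thousands of mOTUs from hundreds of
thousands of genomes) require the external genome collections themselves
and are out of scope by design.

## Known limitations

* Substitution-only fixtures cannot exercise indel handling in the seeded
  profiler; truly indel-rich reads would need the full alignment path.
* The greedy centroid rule is order-dependent by design; a different
  (e.g. abundance-weighted) ordering would yield different but equally
  deterministic clusters.
* The ANI clustering is single-stage (sketch distance only), a
  simplification of two-stage sketch-then-alignment pipelines; its
  congruence conclusions are validated on fixtures only.
* Taxa are free-form name paths, not taxonomy-database identifiers; CAMI
  output uses names as taxids.
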