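---
title: "Inferring putative operons from phylogenetic profiles, proximity, and co-expression"
author: "ppoperon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring putative operons from phylogenetic profiles, proximity, and co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial genes that are co-transcribed as an operon tend to leave three
independent footprints in comparative and functional genomic data:

1. **Shared evolutionary history.** Genes of one operon are inherited and
   lost together, so their *phylogenetic profiles* — binary vectors
   recording the presence (1) or absence (0) of each gene's orthogroup
   across a panel of related genomes — are near-identical.
2. **Genomic organisation.** Operon members sit close together on the
   same strand of the same replicon.
3. **Co-regulation.** Under a perturbation (here: a treated vs. control
   contrast from bulk RNA-seq of a focal strain), all members shift
   expression in the same direction.

`ppoperon` operationalises the intersection of these three signals as a
candidate caller: groups of two or more genes that simultaneously show
near-identical profiles, strand-aware proximity, and concordant
differential expression are reported as *putative operons*. The package
covers the full path from standard inputs (an OrthoFinder-style
orthogroup table, a GFF3 annotation, a count matrix or a precomputed DE
table, and optionally COG assignments and qPCR Ct values) to a written
candidate table, and ships a synthetic-study generator with planted
ground truth so every stage can be validated end to end.

## The procedure and its assumptions

### Phylogenetic profiles and the Jaccard distance

For each focal-genome gene, the profile bit for genome $g$ is 1 iff the
gene's orthogroup has at least one member in $g$; presence is binary
regardless of paralog count. Profiles are compared with the Jaccard
distance on presence sets,

$$d(A, B) = 1 - \frac{|A \cap B|}{|A \cup B|},$$

which is a metric on binary vectors. Distances are computed from integer
intersection/union counts, so they are exact ratios of small integers
and comparisons against the cutoff are reproducible.

Two numerical conventions are fixed here. First, a focal gene found in
no orthogroup keeps a *singleton* profile (present only in the focal
genome) instead of being dropped; this keeps the gene universe aligned
with the annotation and the DE table, and singletons essentially never
pair under the default cutoff. Second, the distance between two all-zero
profiles is defined as 0 with a warning (a 0/0 guard; it cannot occur
for focal genes, whose focal bit is always 1).

The focal genome's own column is constant 1 across focal genes, so it
shifts all similarities uniformly without reordering them; it is
**included** by default, with `exclude_focal = TRUE` available in
`profile_distance_matrix()` for the alternative convention.

### The grouping criteria

`infer_operons()` connects two genes whenever all four of these hold:

* profile distance **strictly below** `distance_cutoff` (default
  0.001 — over panels of up to a few hundred genomes this effectively
  demands identical profiles, since the smallest attainable nonzero
  Jaccard distance is $1/n_\text{genomes}$; the strict reading follows
  the "less than" convention and is documented rather than hidden);
* same contig and same strand;
* closest-edge gap (end of the upstream gene to the start of the
  downstream gene, minus one) at most `window_bp` (default 10,000 bp).
  Proximity is a *neighbour* condition: an operon's total span may
  exceed the window. A flag (`all_pairs_proximity`) switches to the
  stricter all-pairs reading;
* the same differential-expression call (UP or DOWN). Genes with call
  NS never join a candidate by default — concordant *differential*
  expression is read as requiring significance, not merely a shared
  sign; `require_significance = FALSE` switches to sign concordance.

Candidates are the connected components of size ≥ 2 of this graph
(single-linkage chaining). Chaining alone could violate the pairwise
distance bound, so each component is verified against an **all-pairs**
distance check; a failing component is split greedily by removing the
gene with the highest mean internal distance and re-chaining the rest
until every group passes. Under the default cutoff the distance relation
is "identical profile", which is transitive, so the verification step is
a no-op there and matters only for relaxed cutoffs.

### Differential expression

The DE stage is an edgeR-style negative-binomial analysis written for
this package (the contribution of `ppoperon` is the operon caller, but
the spec of the DE stage — TMM normalisation, a common-dispersion exact
test, BH adjustment — is simple enough to implement transparently, and
the `read_de_table()` path accepts external edgeR output unchanged):

* **TMM factors** are computed against the sample whose 75th
  count-fraction percentile is closest to the panel mean, trimming
  log-ratios 30% per tail and average log-abundances 5% per tail, with
  genes zero in either sample excluded and factors rescaled to
  geometric mean 1. The trimmed mean is unweighted; on simulated NB
  data the factors agree with edgeR's weighted version to about 1%,
  which the test suite checks.
* **Common dispersion** is estimated by maximising the *conditional*
  likelihood of $\phi$ given the per-condition totals of counts
  rescaled to a common library size. With three replicates per
  condition, the naive profile likelihood that plugs in per-condition
  mean MLEs underestimates $\phi$ by roughly the factor $(n-1)/n$
  (about 0.065 recovered for a true 0.1), while conditioning removes
  the nuisance means exactly; the conditional estimate recovers
  planted dispersions unbiasedly and agrees closely with edgeR's qCML
  estimator in the cross-check tests. The search scans a 25-point
  log-grid on $[10^{-4}, 4]$ and refines the best bracket with
  `optimize()`.
* **The exact test** rescales counts to the common library size, sums
  them per condition, and computes the two-sided conditional
  probability of a split at least as extreme as observed given the
  gene's total (the smaller tail doubled, capped at 1), under
  $S_i \sim \mathrm{NB}(n_i/\phi,\; n_i \cdot t/(n_1+n_2))$; with
  $\phi = 0$ this reduces to a binomial split test. Tail sums are
  computed from log-densities with a log-sum-exp normalisation.
* **Calls** use strict inequalities: a gene is UP/DOWN only if its
  |fold change| strictly *exceeds* `min_abs_fc` (default 2.0, with
  1.5 as the conventional sensitive variant) **and** its BH-adjusted
  FDR is strictly *below* `max_fdr` (default 0.05). Boundary values
  (FDR exactly 0.05, |FC| exactly 2) are NS; the boundary tests pin
  this down. Fold changes are reported both as `log2fc` and as the
  signed linear `fc_signed` = $\mathrm{sign}(\text{lfc}) \cdot
  2^{|\text{lfc}|}$ (so −1.61 means 1.61-fold down). A prior count of
  0.125 per sample stabilises fold changes of low-count genes.

### COG summaries and qPCR confirmation

`summarize_by_category()` tabulates UP/DOWN calls per COG one-letter
category. A gene with $k$ categories contributes one count to each
(multi-counting, not fractional — the convention is documented and the
conservation property $\sum_\text{cats} \text{counts} = \sum_\text{DEGs}
|\text{cats}|$ is tested); unassigned genes appear under `"-"`, and a
second DE set adds shared-direction intersection counts.

`ddct_ratio()` implements relative quantification with multiple
reference genes: per condition, $\Delta Ct$ subtracts the arithmetic
mean of the control genes' mean Ct (equivalent to a geometric mean on
the expression scale) from the target's mean Ct, and the fold change is
$E^{-\Delta\Delta Ct}$ with the target's amplification efficiency $E$
(default 2, the classic $2^{-\Delta\Delta Ct}$). A change is flagged
significant when it is two-fold or greater in either direction
(`fold_change` ≥ 2 or ≤ 0.5, boundary inclusive).

## The synthetic-study generator

`simulate_study()` plants a complete, fully known study:

* a genome panel (default 40 genomes; 163 is supported but slower to
  little validation benefit — the default is desk-scale while keeping
  the smallest nonzero Jaccard distance, 1/40 = 0.025, far above the
  0.001 cutoff) with one orthogroup per focal gene; planted operon
  members share one random presence pattern, background genes draw
  independent patterns with presence probability 0.5 (collisions with a
  planted pattern are allowed — they exercise the proximity and strand
  filters, not a bug);
* a single-contig annotation (900 bp genes, 200 bp gaps) in which each
  planted operon is contiguous on one random strand and separated from
  the next operon by at least one background gene, so proximity and
  strand criteria hold by construction;
* NB counts with log-normal baseline means (median 200, log-sd 1 — a
  realistic spread of bacterial RNA-seq expression levels), dispersion
  0.1, three replicates per condition, and a shared ±2 log2 fold change
  planted on every operon gene;
* a Ct table under the exponential amplification model with Gaussian
  cycle noise (sd 0.15; a standard qPCR error model) and per-gene
  baseline offsets.

Orthology-call noise can be emulated with `profile_noise_flips` (random
bit flips per planted profile); there is no canonical error model for
profiles, so flips are deliberately simple. All four generators derive
independent streams from one seed, and equal seeds give byte-identical
files.

**What passing tests do and do not show.** The generator plants clean,
block-contiguous operons with identical profiles and equal effect sizes;
real data add orthology-call errors, operon-internal promoters, partial
polarity, condition-specific sub-operon structure, and library-specific
biases that the simulation does not model. Recovery of planted truth
therefore validates the *implementation* of the criteria, not the
biological error rate of the method on real genomes.

## Validation and the quantities recomputed

The test-suite properties (and `scripts/acceptance.R`, which recomputes
the headline numbers from scratch at a user-supplied seed) include:

* exact agreement of the Jaccard machinery and of BH adjustment with
  independent brute-force oracles;
* exhaustive-search equivalence of `infer_operons()` on instances small
  enough to enumerate every candidate subset;
* recovery of the planted partition on the default study over 20
  independent seeds. *Precision* counts a candidate as correct when all
  its members belong to one planted operon (no mixing, no background
  genes); *recall* counts a planted operon as recovered only when a
  candidate matches its member set exactly. Pooled over seeds,
  precision is 1.0 and recall is about 0.95: occasionally a planted
  gene's estimated |FC| lands below the strict two-fold cutoff (the
  planted effect is 2 log2 units, the cutoff 1, the estimator sd about
  0.3–0.4 at low means), truncating or dropping that operon — expected
  stochastic behaviour, not an inference error;
* null calibration of the DE stage (raw p below 0.05 for ~5% of null
  genes; essentially zero false DEGs after BH and the fold-change
  filter) and dispersion recovery within [0.07, 0.13] for a true 0.1;
* monotonicity: relaxing the cutoff or the window never shrinks the
  set of genes covered by candidates;
* exact inversion of the Ct model by `ddct_ratio()` at zero noise, and
  a Monte-Carlo check that noisy recovery stays within 1.3× of truth in
  ≥ 95% of simulations.

Problem sizes in the default test run (500 genes × 40 genomes × 20
seeds for recovery; 2,000 genes for null calibration) were chosen as the
smallest instances at which the Monte-Carlo margins above are stable.

## Known limitations

* The DE stage implements the common-dispersion exact test only — no
  tagwise/trended dispersion, GLM or quasi-likelihood modes, and no
  multi-factor designs; users needing them should run edgeR and feed
  `read_de_table()`.
* Strict profile matching (cutoff 0.001 ⇒ identical profiles) is
  brittle to orthology-call errors; a single mis-assigned genome breaks
  a pair. The cutoff is configurable, and the greedy split keeps the
  output valid at relaxed cutoffs, but no error-tolerant profile model
  is provided.
* Proximity is intra-contig by definition; operons split across contig
  boundaries of a draft assembly are invisible.
* qPCR efficiencies are taken from the input table, not estimated from
  dilution series; amplification-curve QC is out of scope.
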