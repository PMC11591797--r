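# ppoperon

Putative operon inference for bacterial genomes from three independent
lines of evidence: **phylogenetic profiles**, **strand-aware genomic
proximity**, and **concordant differential expression**.

## The problem

Genes transcribed together as an operon are inherited together, sit
next to each other on one strand, and respond together to a
perturbation. `ppoperon` turns that triple footprint into a candidate
caller for a focal bacterial strain studied against a panel of related
genomes:

1. Each focal gene gets a binary **phylogenetic profile** — presence
   (1) or absence (0) of its orthogroup across the genome panel — built
   from an OrthoFinder-style `Orthogroups.tsv` table. Profiles are
   compared with the Jaccard distance
   `d(A, B) = 1 − |A ∩ B| / |A ∪ B|`.
2. Gene coordinates and strands come from a GFF3 annotation.
3. A treated-vs-control contrast is called from a gene × sample count
   matrix with TMM normalisation, a common-dispersion negative-binomial
   exact test, and Benjamini–Hochberg FDR (defaults: |FC| > 2,
   FDR < 0.05) — or ingested as a precomputed edgeR-style table.

Groups of ≥ 2 genes with pairwise profile distance < 0.001,
closest-edge gaps ≤ 10,000 bp on the same contig and strand, and the
same DE direction are reported as **putative operons**. Supporting
stages summarise DEGs by COG functional category and confirm selected
genes by ΔΔCt relative quantification of qPCR Ct tables with multiple
reference genes (significant when 2-fold or greater).

A synthetic-study generator (`simulate_study()`) plants ground-truth
operons — identical profiles, contiguous same-strand layout, shared
fold changes — so the whole pipeline is testable without any external
data.

## Worked example

```r
library(ppoperon)

cfg <- sim_config(n_genomes = 30, n_focal_genes = 300,
                  n_planted_operons = 8, rng_seed = 42)
study <- simulate_study(cfg, "study")   # writes orthogroups.tsv, genes.gff3, ...

prof <- build_profiles(read_orthogroups(study$paths$orthogroups),
                       focal_genome = "G001",
                       genes = read_gff3(study$paths$gff)$gene_id)
dm  <- profile_distance_matrix(prof)
fit <- de_exact_test(read_counts(study$paths$counts, study$paths$conditions))
fit
#> NB exact-test differential expression fit (300 genes)
#>   common dispersion: 0.09926
#>   thresholds: |FC| > 2, FDR < 0.05
#>   calls: 21 UP, 6 DOWN, 273 NS

operons <- infer_operons(dm, read_gff3(study$paths$gff), as.data.frame(fit))
summary(operons)
#> Putative operons: 8 candidate(s) covering 26 gene(s)
#>   criteria: Jaccard distance < 0.001, gap <= 10000 bp, same strand, concordant DE
#>   PO001 [-, DOWN]: gene0035, gene0036
#>   PO002 [-, UP]: gene0072, gene0073, gene0074, gene0075, gene0076, gene0077
#>   PO003 [-, UP]: gene0101, gene0102
#>   ...
```

The simulated counts were drawn with dispersion 0.1 — the fit recovers
0.099 — and all 8 planted operons are recovered with their exact member
sets (26 genes; the DE stage additionally calls one borderline
background gene, which joins no candidate). `write_operons(operons,
"operons.tsv")` emits the flat table plus a JSON mirror, and
`run_pipeline("config.yaml")` drives the same stages from a YAML
configuration, writing a manifest with parameter and checksum records.

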