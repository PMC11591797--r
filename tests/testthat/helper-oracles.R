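# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths: set arithmetic instead of matrix algebra,
# explicit step-up instead of p.adjust, exhaustive subset enumeration
# instead of graph chaining.

# Jaccard distance by explicit set operations on presence indices
oracle_jaccard <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  u <- union(A, B)
  if (length(u) == 0) return(0)
  1 - length(intersect(A, B)) / length(u)
}

oracle_distance_matrix <- function(profiles) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- oracle_jaccard(profiles[i, ], profiles[j, ])
  d
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank downwards
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# closest-edge gap between two 1-based inclusive intervals
oracle_gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2) - 1)

# Exhaustive enumeration of maximal putative-operon groups: all gene
# subsets of size >= 2 within one (contig, strand, direction) class
# whose pairwise profile distances are below the cutoff and whose
# consecutive members (in genomic order) are within the window.
oracle_enumerate_operons <- function(dm, genes, de, params) {
  keep <- de$gene_id[de$call != "NS"]
  keep <- intersect(keep, intersect(rownames(dm), genes$gene_id))
  gf <- genes[match(keep, genes$gene_id), , drop = FALSE]
  dir <- de$call[match(keep, de$gene_id)]
  classes <- split(gf$gene_id, paste(gf$contig, gf$strand, dir))

  valid <- function(members) {
    sub <- genes[match(members, genes$gene_id), , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    dsub <- dm[sub$gene_id, sub$gene_id]
    if (any(dsub[upper.tri(dsub)] >= params$distance_cutoff)) return(FALSE)
    if (nrow(sub) > 1) {
      gaps <- mapply(oracle_gap, sub$start[-nrow(sub)], sub$end[-nrow(sub)],
                     sub$start[-1], sub$end[-1])
      if (any(gaps > params$window_bp)) return(FALSE)
    }
    TRUE
  }

  groups <- list()
  for (cls in classes) {
    k <- length(cls)
    if (k < 2) next
    stopifnot(k <= 16)  # enumeration guard
    for (size in 2:k) {
      combos <- utils::combn(cls, size, simplify = FALSE)
      for (s in combos) if (valid(s)) groups[[length(groups) + 1]] <- sort(s)
    }
  }
  # keep only maximal groups (not a subset of another valid group)
  maximal <- logical(length(groups))
  for (i in seq_along(groups)) {
    maximal[i] <- !any(vapply(seq_along(groups), function(j)
      j != i && all(groups[[i]] %in% groups[[j]]), TRUE))
  }
  unique(groups[maximal])
}

# canonical form of an operon_set for oracle comparison
candidate_sets <- function(os) {
  s <- lapply(os$candidates, function(c) sort(c$member_genes))
  s[order(vapply(s, paste, "", collapse = ","))]
}

# a small complete synthetic study, shared by several test files
make_small_study <- function(seed = 1, ...) {
  cfg <- sim_config(n_genomes = 20, n_focal_genes = 120,
                    n_planted_operons = 4, operon_size_range = c(2, 4),
                    rng_seed = seed, ...)
  pg <- generate_pangenome(cfg)
  ann <- generate_annotation(cfg, pg$truth)
  cm <- generate_counts(cfg, pg$truth)
  prof <- build_profiles(pg$orthogroups, focal_genome = pg$focal_genome,
                         genes = ann$gene_id)
  list(cfg = cfg, pg = pg, truth = pg$truth, ann = ann, cm = cm,
       prof = prof, dm = profile_distance_matrix(prof))
}
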