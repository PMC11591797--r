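#' Parameters of the operon-inference procedure
#'
#' @param distance_cutoff strict upper bound on the pairwise Jaccard
#'   distance of phylogenetic profiles within a candidate (default
#'   0.001; over panels of up to a few hundred genomes this effectively
#'   requires identical profiles, since the smallest nonzero Jaccard
#'   distance is 1/n_genomes).
#' @param window_bp maximum closest-edge gap, in bp, between
#'   neighbouring genes of a candidate (default 10,000).
#' @param de_thresholds a [de_thresholds()] object used for the
#'   co-regulation criterion (default |FC| > 2, FDR < 0.05).
#' @param require_significance if `TRUE` (default) only genes called
#'   UP/DOWN can join a candidate; if `FALSE`, direction is taken from
#'   the sign of the log2 fold change regardless of significance.
#' @param all_pairs_proximity if `TRUE`, the gap condition is applied to
#'   every gene pair of a candidate rather than to neighbours only
#'   (neighbour-wise is the default: an operon's total span may exceed
#'   the window).
#' @return An object of class `operon_params`.
#' @export
operon_params <- function(distance_cutoff = 0.001, window_bp = 10000,
                          de_thresholds = ppoperon::de_thresholds(),
                          require_significance = TRUE,
                          all_pairs_proximity = FALSE) {
  if (!is.numeric(distance_cutoff) || distance_cutoff <= 0 || distance_cutoff >= 1)
    stopf("operon_params: 'distance_cutoff' must lie in (0, 1)")
  if (!is.numeric(window_bp) || window_bp <= 0)
    stopf("operon_params: 'window_bp' must be positive")
  stopifnot(inherits(de_thresholds, "de_thresholds"))
  structure(list(distance_cutoff = distance_cutoff,
                 window_bp = window_bp,
                 de_thresholds = de_thresholds,
                 require_significance = isTRUE(require_significance),
                 all_pairs_proximity = isTRUE(all_pairs_proximity)),
            class = "operon_params")
}

## closest-edge gap between two features (0 if they overlap)
edge_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1, start2) - pmin(end1, end2) - 1L)
}

#' Infer putative operons from profiles, proximity, and co-expression
#'
#' Groups focal-genome genes into putative operons using the three
#' criteria: (a) near-identical phylogenetic profiles (pairwise Jaccard
#' distance strictly below the cutoff), (b) genomic proximity on the
#' same contig and strand (closest-edge gap between neighbouring
#' members within the window), and (c) concordant differential
#' expression (all members called in the same direction).
#'
#' Discovery proceeds by single-linkage chaining: genes with a
#' significant DE call are connected whenever a pair satisfies all
#' criteria, and connected components of size >= 2 become candidates.
#' Because chaining alone could violate the pairwise distance bound,
#' every component is then verified against an all-pairs distance
#' check; a failing component is split greedily by removing the gene
#' with the highest mean internal distance and re-chaining, until all
#' resulting groups pass.
#'
#' @param dm symmetric Jaccard distance matrix with gene IDs as
#'   dimnames ([profile_distance_matrix()]).
#' @param genes gene feature data frame ([read_gff3()]).
#' @param de DE record data frame ([call_degs()] or
#'   `as.data.frame()` of a `de_fit`).
#' @param params an [operon_params()] object.
#' @return An object of class `operon_set`: a list with `candidates`
#'   (each with `operon_id`, ordered `member_genes`, `contig`, `strand`,
#'   `direction`, `max_internal_distance`, `max_gap_bp`), the `params`
#'   used, and bookkeeping counts.  Gene universes are reconciled by
#'   intersection; mismatches are reported via `message()`.
#' @examples
#' cfg <- sim_config(n_genomes = 20, n_focal_genes = 120,
#'                   n_planted_operons = 4, rng_seed = 3)
#' pg <- generate_pangenome(cfg)
#' ann <- generate_annotation(cfg, pg$truth)
#' prof <- build_profiles(pg$orthogroups, focal_genome = pg$focal_genome,
#'                        genes = ann$gene_id)
#' dm <- profile_distance_matrix(prof)
#' fit <- de_exact_test(generate_counts(cfg, pg$truth))
#' infer_operons(dm, ann, as.data.frame(fit))
#' @export
infer_operons <- function(dm, genes, de, params = operon_params()) {
  stopifnot(inherits(params, "operon_params"))
  if (is.null(rownames(dm)))
    stopf("infer_operons: distance matrix needs gene ids as dimnames")

  universe <- Reduce(intersect, list(rownames(dm), genes$gene_id, de$gene_id))
  dropped <- length(unique(c(rownames(dm), genes$gene_id, de$gene_id))) -
    length(universe)
  if (dropped > 0L)
    message(sprintf(paste0("infer_operons: %d gene id(s) absent from at least ",
                           "one of distance matrix / annotation / DE table; ",
                           "using the %d-gene intersection"),
                    dropped, length(universe)))

  de <- de[match(universe, de$gene_id), , drop = FALSE]
  if (params$require_significance) {
    direction <- de$call
  } else {
    direction <- ifelse(de$log2fc > 0, "UP", ifelse(de$log2fc < 0, "DOWN", "NS"))
  }
  names(direction) <- de$gene_id
  cand_genes <- universe[direction[universe] %in% c("UP", "DOWN")]

  feats <- genes[match(cand_genes, genes$gene_id), , drop = FALSE]
  empty <- structure(list(candidates = list(), params = params,
                          n_genes_considered = length(cand_genes),
                          n_genes_in_universe = length(universe)),
                     class = "operon_set")
  if (length(cand_genes) < 2L) return(empty)

  ## edges within (contig, strand, direction) classes
  key <- paste(feats$contig, feats$strand, direction[cand_genes], sep = "\r")
  groups <- split(seq_len(nrow(feats)), key)
  edge_from <- character(0); edge_to <- character(0)
  for (gidx in groups) {
    if (length(gidx) < 2L) next
    sub <- feats[gidx, , drop = FALSE]
    pairs <- utils::combn(nrow(sub), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      gi <- sub$gene_id[i]; gj <- sub$gene_id[j]
      if (dm[gi, gj] >= params$distance_cutoff) next
      gap <- edge_gap(sub$start[i], sub$end[i], sub$start[j], sub$end[j])
      if (gap > params$window_bp) next
      edge_from <- c(edge_from, gi); edge_to <- c(edge_to, gj)
    }
  }
  if (length(edge_from) == 0L) return(empty)

  comps <- connected_components(cand_genes, edge_from, edge_to)
  comps <- comps[lengths(comps) >= 2L]

  ## all-pairs distance verification with greedy splitting
  verified <- list()
  for (members in comps) {
    verified <- c(verified,
                  verify_component(members, dm, feats, params))
  }
  if (length(verified) == 0L) return(empty)

  ## assemble candidates in genomic order
  first_pos <- vapply(verified, function(m)
    min(feats$start[match(m, feats$gene_id)]), numeric(1))
  first_contig <- vapply(verified, function(m)
    feats$contig[match(m[1], feats$gene_id)], character(1))
  verified <- verified[order(first_contig, first_pos)]

  candidates <- lapply(seq_along(verified), function(i) {
    m <- verified[[i]]
    sub <- feats[match(m, feats$gene_id), , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gaps <- if (nrow(sub) > 1L)
      edge_gap(sub$start[-nrow(sub)], sub$end[-nrow(sub)],
               sub$start[-1], sub$end[-1]) else 0L
    dsub <- dm[sub$gene_id, sub$gene_id, drop = FALSE]
    list(operon_id = sprintf("PO%03d", i),
         member_genes = sub$gene_id,
         contig = sub$contig[1],
         strand = sub$strand[1],
         direction = unname(direction[sub$gene_id[1]]),
         max_internal_distance = max(dsub),
         max_gap_bp = as.integer(max(gaps)))
  })
  structure(list(candidates = candidates, params = params,
                 n_genes_considered = length(cand_genes),
                 n_genes_in_universe = length(universe)),
            class = "operon_set")
}

## union-find-free component search on a small explicit edge list
connected_components <- function(nodes, from, to) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

## enforce the all-pairs distance bound inside one chained component;
## returns a list of verified member vectors (size >= 2)
verify_component <- function(members, dm, feats, params) {
  if (length(members) < 2L) return(list())
  dsub <- dm[members, members, drop = FALSE]
  if (all(dsub[upper.tri(dsub)] < params$distance_cutoff)) {
    if (params$all_pairs_proximity && !all_pairs_within(members, feats, params))
      return(list())
    return(list(members))
  }
  ## drop the gene with the highest mean distance to the others,
  ## re-chain the remainder, and verify each resulting component
  mean_d <- rowMeans(dsub) * length(members) / (length(members) - 1L)
  worst <- members[which.max(mean_d)]
  remaining <- setdiff(members, worst)
  if (length(remaining) < 2L) return(list())
  sub <- feats[match(remaining, feats$gene_id), , drop = FALSE]
  edge_from <- character(0); edge_to <- character(0)
  if (nrow(sub) >= 2L) {
    pairs <- utils::combn(nrow(sub), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      gi <- sub$gene_id[i]; gj <- sub$gene_id[j]
      if (dm[gi, gj] >= params$distance_cutoff) next
      if (edge_gap(sub$start[i], sub$end[i], sub$start[j], sub$end[j]) >
          params$window_bp) next
      edge_from <- c(edge_from, gi); edge_to <- c(edge_to, gj)
    }
  }
  if (length(edge_from) == 0L) return(list())
  comps <- connected_components(remaining, edge_from, edge_to)
  comps <- comps[lengths(comps) >= 2L]
  out <- list()
  for (m in comps) out <- c(out, verify_component(m, dm, feats, params))
  out
}

all_pairs_within <- function(members, feats, params) {
  sub <- feats[match(members, feats$gene_id), , drop = FALSE]
  pairs <- utils::combn(nrow(sub), 2L)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (edge_gap(sub$start[i], sub$end[i], sub$start[j], sub$end[j]) >
        params$window_bp) return(FALSE)
  }
  TRUE
}

#' @export
print.operon_set <- function(x, ...) {
  cat(sprintf("Putative operons: %d candidate(s) covering %d gene(s)\n",
              length(x$candidates),
              sum(vapply(x$candidates, function(c) length(c$member_genes), 1L))))
  cat(sprintf("  criteria: Jaccard distance < %g, gap <= %d bp, same strand, concordant DE\n",
              x$params$distance_cutoff, as.integer(x$params$window_bp)))
  invisible(x)
}

#' @export
summary.operon_set <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  if (nrow(df) > 0L) {
    sizes <- table(df$operon_id)
    for (id in names(sizes)) {
      rows <- df[df$operon_id == id, ]
      cat(sprintf("  %s [%s, %s]: %s\n", id, rows$strand[1],
                  rows$direction[1], paste(rows$gene_id, collapse = ", ")))
    }
  }
  invisible(object)
}

#' Flatten an operon set to one row per member gene
#' @param x an `operon_set`.
#' @param ... unused.
#' @return Data frame with columns `operon_id`, `gene_id`, `rank`,
#'   `contig`, `strand`, `direction`, `max_internal_distance`,
#'   `max_gap_bp`.
#' @export
as.data.frame.operon_set <- function(x, ...) {
  if (length(x$candidates) == 0L)
    return(data.frame(operon_id = character(0), gene_id = character(0),
                      rank = integer(0), contig = character(0),
                      strand = character(0), direction = character(0),
                      max_internal_distance = numeric(0),
                      max_gap_bp = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$candidates, function(cand) {
    data.frame(operon_id = cand$operon_id,
               gene_id = cand$member_genes,
               rank = seq_along(cand$member_genes),
               contig = cand$contig, strand = cand$strand,
               direction = cand$direction,
               max_internal_distance = cand$max_internal_distance,
               max_gap_bp = cand$max_gap_bp,
               stringsAsFactors = FALSE)
  }))
}

#' Write putative operons as TSV plus a JSON mirror
#'
#' @param os an `operon_set` ([infer_operons()]).
#' @param path TSV output path; a JSON mirror is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_operons <- function(os, path) {
  stopifnot(inherits(os, "operon_set"))
  df <- as.data.frame(os)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    lapply(os$candidates, function(cand) cand),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a putative-operon TSV written by [write_operons()]
#' @param path TSV path.
#' @return Data frame in the [as.data.frame.operon_set()] layout.
#' @export
read_operons <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(operon_id = "character",
                                  gene_id = "character"))
  need <- c("operon_id", "gene_id", "rank", "contig", "strand",
            "direction", "max_internal_distance", "max_gap_bp")
  if (!all(need %in% names(df)))
    stopf("read_operons: missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df
}
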