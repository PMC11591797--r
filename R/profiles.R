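#' Build binary phylogenetic profiles for focal-genome genes
#'
#' A gene's phylogenetic profile is the 0/1 vector recording, for each
#' genome of the panel, whether the gene's orthogroup has at least one
#' member there.  Presence is binary regardless of paralog count.  All
#' genes of one orthogroup share a single profile, and the focal
#' genome's own bit is 1 for every focal gene by construction.
#'
#' @param orthogroups an `orthogroups` object ([read_orthogroups()]).
#' @param panel ordered character vector of genome identifiers; defaults
#'   to the table's own column order.
#' @param focal_genome name of the focal genome (must be in `panel`).
#' @param genes optional character vector of focal gene IDs (e.g. from
#'   the annotation).  Genes absent from every orthogroup are kept and
#'   assigned a singleton profile (present only in the focal genome),
#'   with a message; this keeps the gene universe aligned with the
#'   annotation and the expression table.
#' @return An integer 0/1 matrix, genes x genomes, with the focal genome
#'   recorded in `attr(, "focal_genome")`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("Orthogroup\tA\tB\tC",
#'              "OG1\tgA1, gA2\t\tgC1",
#'              "OG2\tgA3\tgB1\t"), tf)
#' og <- read_orthogroups(tf)
#' build_profiles(og, focal_genome = "A")
#' @export
build_profiles <- function(orthogroups, panel = attr(orthogroups, "panel"),
                           focal_genome, genes = NULL) {
  stopifnot(inherits(orthogroups, "orthogroups"))
  if (is.null(panel) || length(panel) == 0L)
    stopf("build_profiles: empty genome panel")
  if (anyDuplicated(panel))
    stopf("build_profiles: duplicated genome ids in panel")
  if (!focal_genome %in% panel)
    stopf("build_profiles: focal genome '%s' is not in the panel", focal_genome)

  ## orthogroup-level presence bits
  pres <- t(vapply(orthogroups, function(members)
    as.integer(lengths(members[panel]) > 0L), integer(length(panel))))
  colnames(pres) <- panel

  ## one profile per focal gene, inherited from its orthogroup
  focal_members <- lapply(orthogroups, `[[`, focal_genome)
  n_per_og <- lengths(focal_members)
  gene_ids <- unlist(focal_members, use.names = FALSE)
  prof <- pres[rep(seq_along(orthogroups), n_per_og), , drop = FALSE]
  rownames(prof) <- gene_ids

  if (!is.null(genes)) {
    missing <- setdiff(genes, gene_ids)
    if (length(missing) > 0L) {
      message(sprintf(paste0("build_profiles: %d gene(s) not found in any ",
                             "orthogroup; assigned singleton profiles ",
                             "(present only in '%s')"),
                      length(missing), focal_genome))
      singleton <- matrix(0L, length(missing), length(panel),
                          dimnames = list(missing, panel))
      singleton[, focal_genome] <- 1L
      prof <- rbind(prof, singleton)
    }
    prof <- prof[genes, , drop = FALSE]
  }
  if (anyDuplicated(rownames(prof)))
    stopf("build_profiles: duplicated focal gene id(s): %s",
          paste(unique(rownames(prof)[duplicated(rownames(prof))]), collapse = ", "))
  structure(prof, focal_genome = focal_genome)
}

#' Jaccard distance between two binary profiles
#'
#' `1 - |A intersect B| / |A union B|` on the presence sets of the two
#' profiles.  Two all-zero profiles (empty presence sets) are defined to
#' be at distance 0, with a warning; this cannot occur for focal-genome
#' genes, whose focal bit is always 1.
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 2/3
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b))
    stopf("jaccard_distance: profile lengths differ (%d vs %d)",
          length(a), length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stopf("jaccard_distance: profiles must be binary 0/1 vectors")
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) {
    warnf("jaccard_distance: both profiles are all-zero; returning 0")
    return(0)
  }
  1 - inter / union
}

#' Pairwise Jaccard distance matrix of phylogenetic profiles
#'
#' Computes the full symmetric matrix of Jaccard distances between the
#' rows of a binary profile matrix, via integer intersection/union
#' counts (so entries are exact ratios of small integers).
#'
#' @param profiles integer 0/1 matrix, genes x genomes, with unique row
#'   names ([build_profiles()]).
#' @param exclude_focal if `TRUE`, drop the focal genome's column (which
#'   is constant 1 across focal genes and shifts all similarities
#'   uniformly) before computing distances.  Default keeps it.
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, row/column names = gene IDs.
#' @export
profile_distance_matrix <- function(profiles, exclude_focal = FALSE) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L)
    stopf("profile_distance_matrix: need a matrix of at least 2 profiles")
  if (is.null(rownames(profiles)) || anyDuplicated(rownames(profiles)))
    stopf("profile_distance_matrix: profiles must carry unique gene ids as row names")
  if (!all(profiles %in% c(0L, 1L)))
    stopf("profile_distance_matrix: profiles must be binary 0/1")
  if (exclude_focal) {
    focal <- attr(profiles, "focal_genome")
    if (is.null(focal))
      stopf("profile_distance_matrix: 'exclude_focal' requires a 'focal_genome' attribute")
    profiles <- profiles[, setdiff(colnames(profiles), focal), drop = FALSE]
  }
  m <- profiles
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  union <- outer(ones, ones, "+") - inter
  d <- ifelse(union == 0, 0, 1 - inter / union)
  diag(d) <- 0
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

#' Write a profile or distance matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.  First column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
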