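#' Read gene features from a GFF3 file
#'
#' Minimal, strict reader for the gene-level slice of a GFF3 annotation:
#' keeps rows of the requested feature type, requires an `ID` attribute
#' and a definite strand (`+` or `-`; the method is strand-aware, so
#' `.` is rejected), and preserves 1-based inclusive coordinates.
#' Windows (CRLF) line endings are accepted.
#'
#' @param path path to the GFF3 file.
#' @param feature_type feature type (column 3) to keep; default `"gene"`.
#' @return A data frame (`gene_id`, `contig`, `start`, `end`, `strand`)
#'   sorted by contig then start.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  lines <- sub("\r$", "", readLines(path))
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  out <- vector("list", length(idx))
  k <- 0L
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stopf("read_gff3: line %d: expected 9 tab-separated columns, got %d",
            i, length(f))
    if (f[3] != feature_type) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stopf("read_gff3: line %d: non-numeric coordinates", i)
    if (start < 1L || start > end)
      stopf("read_gff3: line %d: invalid coordinates (start %d, end %d)",
            i, start, end)
    if (!f[7] %in% c("+", "-"))
      stopf(paste0("read_gff3: line %d: strand '%s' not allowed; the method ",
                   "requires a definite '+' or '-' strand"), i, f[7])
    m <- regmatches(f[9], regexec("(?:^|;)\\s*ID=([^;]+)", f[9]))[[1]]
    if (length(m) < 2L || !nzchar(m[2]))
      stopf("read_gff3: line %d: feature lacks an ID attribute", i)
    k <- k + 1L
    out[[k]] <- data.frame(gene_id = m[2], contig = f[1], start = start,
                           end = end, strand = f[7],
                           stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, out[seq_len(k)])
  if (is.null(feats))
    feats <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  if (anyDuplicated(feats$gene_id))
    stopf("read_gff3: duplicated gene id(s): %s",
          paste(unique(feats$gene_id[duplicated(feats$gene_id)]), collapse = ", "))
  feats[order(feats$contig, feats$start), , drop = FALSE]
}

#' Write gene features as GFF3
#'
#' @param features data frame with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand` (e.g. from [generate_annotation()]).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "ppoperon") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$contig, source, features$start, features$end,
                     features$strand, features$gene_id))
  writeLines(lines, path)
  invisible(path)
}
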