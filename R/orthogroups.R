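#' Read an OrthoFinder-style orthogroup membership table
#'
#' Parses the `Orthogroups.tsv` dialect: a tab-separated table whose
#' first column is the orthogroup identifier and whose remaining columns
#' are genomes; a cell holds the comma(+space)-separated gene IDs of
#' that orthogroup in that genome, and an empty cell means absence.
#'
#' @param path path to the table.
#' @return An object of class `orthogroups`: a named list mapping each
#'   orthogroup to a named list (genome -> character vector of member
#'   gene IDs, possibly empty).  The ordered genome panel is available
#'   as `attr(x, "panel")`.
#' @seealso [write_orthogroups()], [build_profiles()]
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L)
    stopf("read_orthogroups: '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L || header[1] != "Orthogroup")
    stopf(paste0("read_orthogroups: line 1: expected a header starting with ",
                 "'Orthogroup' followed by genome names"))
  panel <- header[-1]
  if (anyDuplicated(panel))
    stopf("read_orthogroups: duplicated genome name(s) in header: %s",
          paste(unique(panel[duplicated(panel)]), collapse = ", "))
  nf <- length(header)

  body <- fields[-1]
  keep <- lengths(body) > 0L | nzchar(lines[-1])
  body <- body[keep]
  og <- vector("list", length(body))
  og_ids <- character(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    ## trailing empty cells may be dropped by strsplit; pad them back
    if (length(row) < nf) row <- c(row, rep("", nf - length(row)))
    if (length(row) != nf)
      stopf("read_orthogroups: line %d: expected %d tab-separated fields, got %d",
            i + 1L, nf, length(row))
    og_ids[i] <- row[1]
    members <- lapply(row[-1], split_gene_cell)
    names(members) <- panel
    og[[i]] <- members
  }
  if (anyDuplicated(og_ids))
    stopf("read_orthogroups: duplicated orthogroup id(s): %s",
          paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "))
  names(og) <- og_ids

  ## a gene ID may occur only once within a genome column
  for (g in panel) {
    genes <- unlist(lapply(og, `[[`, g), use.names = FALSE)
    if (anyDuplicated(genes))
      stopf("read_orthogroups: gene id(s) %s appear in more than one orthogroup of genome '%s'",
            paste(unique(genes[duplicated(genes)]), collapse = ", "), g)
  }
  structure(og, panel = panel, class = "orthogroups")
}

split_gene_cell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(character(0))
  trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' @param og an `orthogroups` object ([read_orthogroups()] or
#'   [generate_pangenome()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  stopifnot(inherits(og, "orthogroups"))
  panel <- attr(og, "panel")
  header <- paste(c("Orthogroup", panel), collapse = "\t")
  rows <- vapply(names(og), function(id) {
    cells <- vapply(panel, function(g)
      paste(og[[id]][[g]], collapse = ", "), character(1))
    paste(c(id, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @export
print.orthogroups <- function(x, ...) {
  panel <- attr(x, "panel")
  cat(sprintf("Orthogroup table: %d orthogroups x %d genomes\n",
              length(x), length(panel)))
  cat("  genomes:", paste(utils::head(panel, 5), collapse = ", "),
      if (length(panel) > 5) sprintf("... (%d more)", length(panel) - 5) else "",
      "\n")
  invisible(x)
}
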