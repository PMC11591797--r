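#' Read a gene-to-COG-category mapping
#'
#' Expects a two-column TSV (`gene_id`, COG letters); a multi-letter
#' cell such as `"KG"` assigns the gene to each of those categories.
#' Lowercase letters are normalised to uppercase with a warning;
#' letters outside the standard COG one-letter alphabet are rejected
#' with the offending line number.
#'
#' @param path path to the table.
#' @param header whether the file carries a header row (default `TRUE`).
#' @return An object of class `cog_map`: a named list mapping gene IDs
#'   to character vectors of single category letters.
#' @export
read_cog_map <- function(path, header = TRUE) {
  lines <- sub("\r$", "", readLines(path))
  if (header) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stopf("read_cog_map: line %d: expected two tab-separated columns",
            i + as.integer(header))
    letters_i <- strsplit(f[2], "")[[1]]
    low <- letters_i %in% letters
    if (any(low)) {
      warnf("read_cog_map: line %d: lowercase COG letter(s) '%s' normalised to uppercase",
            i + as.integer(header), paste(letters_i[low], collapse = ""))
      letters_i <- toupper(letters_i)
    }
    bad <- setdiff(letters_i, COG_LETTERS)
    if (length(bad) > 0L)
      stopf("read_cog_map: line %d: '%s' is not a COG category letter",
            i + as.integer(header), bad[1])
    out[[f[1]]] <- unique(letters_i)
  }
  structure(out, class = "cog_map")
}

#' Summarise differentially expressed genes by COG category
#'
#' Tabulates UP and DOWN calls per COG functional category.  A gene
#' assigned to k categories contributes one count to each of them
#' (multi-counting, not fractional); genes with no assignment are
#' reported under `"-"`.  When a second DE set is given (e.g. the other
#' treatment of a two-treatment study), per-category counts of genes
#' differentially expressed in the same direction in both sets are
#' added.
#'
#' @param de DE record data frame ([call_degs()]).
#' @param cog a `cog_map` ([read_cog_map()]) or a named list gene ->
#'   letters.
#' @param de2 optional second DE record data frame.
#' @return Data frame with columns `category`, `n_up`, `n_down`, and,
#'   if `de2` is given, `n_up_shared`, `n_down_shared`.
#' @export
summarize_by_category <- function(de, cog, de2 = NULL) {
  cats_of <- function(g) {
    v <- cog[[g]]
    if (is.null(v) || length(v) == 0L) "-" else v
  }
  tally <- function(de_tab) {
    up <- integer(0); down <- integer(0)
    env <- new.env(parent = emptyenv())
    add <- function(tab, cat) { tab[cat] <- (if (cat %in% names(tab)) tab[cat] else 0L) + 1L; tab }
    for (r in seq_len(nrow(de_tab))) {
      if (de_tab$call[r] == "NS") next
      for (cat in cats_of(de_tab$gene_id[r])) {
        if (de_tab$call[r] == "UP") up <- add(up, cat) else down <- add(down, cat)
      }
    }
    list(up = up, down = down)
  }
  t1 <- tally(de)
  cats <- sort(unique(c(names(t1$up), names(t1$down))))
  res <- data.frame(
    category = cats,
    n_up = vapply(cats, function(c) if (c %in% names(t1$up)) t1$up[[c]] else 0L, 1L),
    n_down = vapply(cats, function(c) if (c %in% names(t1$down)) t1$down[[c]] else 0L, 1L),
    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(de2)) {
    shared_dir <- function(dir) {
      g1 <- de$gene_id[de$call == dir]
      g2 <- de2$gene_id[de2$call == dir]
      intersect(g1, g2)
    }
    count_cats <- function(genes) {
      tab <- table(unlist(lapply(genes, cats_of)))
      vapply(res$category, function(c)
        if (c %in% names(tab)) as.integer(tab[[c]]) else 0L, 1L)
    }
    res$n_up_shared <- count_cats(shared_dir("UP"))
    res$n_down_shared <- count_cats(shared_dir("DOWN"))
  }
  res
}
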