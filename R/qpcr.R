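#' Construct a validated qPCR Ct table
#'
#' @param data data frame with columns `gene_id`, `sample_id`,
#'   `condition` (`"control"`/`"treated"`), `ct` (threshold cycles, > 0)
#'   and, optionally, `efficiency` (per-cycle amplification factor in
#'   `(1, 2.2]`, default 2 = perfect doubling).
#' @param control_genes character vector of reference gene IDs (>= 1);
#'   their expression is assumed stable across conditions.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(data, control_genes) {
  need <- c("gene_id", "sample_id", "condition", "ct")
  if (!all(need %in% names(data)))
    stopf("ct_table: missing column(s): %s",
          paste(setdiff(need, names(data)), collapse = ", "))
  if (!"efficiency" %in% names(data)) data$efficiency <- 2
  if (any(is.na(data$ct)) || any(data$ct <= 0))
    stopf("ct_table: Ct values must be positive")
  if (any(data$efficiency <= 1 | data$efficiency > 2.2))
    stopf("ct_table: efficiencies must lie in (1, 2.2]")
  if (!all(data$condition %in% c("control", "treated")))
    stopf("ct_table: conditions must be 'control' or 'treated'")
  if (length(control_genes) < 1L)
    stopf("ct_table: at least one control gene is required")
  missing_ctrl <- setdiff(control_genes, data$gene_id)
  if (length(missing_ctrl) > 0L)
    stopf("ct_table: control gene(s) not measured: %s",
          paste(missing_ctrl, collapse = ", "))
  structure(list(data = data, control_genes = control_genes),
            class = "ct_table")
}

#' Read a qPCR Ct table from TSV
#' @param path TSV with columns `gene_id`, `sample_id`, `condition`,
#'   `ct` and optionally `efficiency`.
#' @param control_genes reference gene IDs.
#' @return A [ct_table()] object.
#' @export
read_ct_table <- function(path, control_genes) {
  ct_table(read.delim(path, stringsAsFactors = FALSE), control_genes)
}

#' Write a qPCR Ct table as TSV
#' @param tbl a [ct_table()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "ct_table"))
  write.table(tbl$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## mean Ct of a gene in one condition; NA if unmeasured
mean_ct <- function(tbl, gene, condition) {
  v <- tbl$data$ct[tbl$data$gene_id == gene & tbl$data$condition == condition]
  if (length(v) == 0L) NA_real_ else mean(v)
}

#' Relative quantification of one target gene by the delta-delta-Ct
#' method
#'
#' Per condition, `dCt = mean Ct(target) - mean over control genes of
#' mean Ct(control)` (the arithmetic mean of control Ct values,
#' equivalent to a geometric mean of control expression levels); then
#' `ddCt = dCt(treated) - dCt(control)` and `fold_change =
#' E^(-ddCt)` with `E` the target's amplification efficiency (E = 2
#' reproduces the classic `2^-ddCt`).  A change is flagged significant
#' when the fold change is 2-fold or greater in either direction
#' (`fold_change >= 2` or `<= 0.5`).
#'
#' @param tbl a [ct_table()] object.
#' @param target target gene ID (must not be a control gene).
#' @return A list with `fold_change`, `log2fc`, `significant`, `ddct`.
#' @export
ddct_ratio <- function(tbl, target) {
  stopifnot(inherits(tbl, "ct_table"))
  if (target %in% tbl$control_genes)
    stopf("ddct_ratio: '%s' is a control gene", target)
  if (!target %in% tbl$data$gene_id)
    stopf("ddct_ratio: target '%s' not measured", target)

  gaps <- character(0)
  for (cond in c("control", "treated")) {
    if (is.na(mean_ct(tbl, target, cond)))
      gaps <- c(gaps, sprintf("%s in %s condition", target, cond))
    for (cg in tbl$control_genes)
      if (is.na(mean_ct(tbl, cg, cond)))
        gaps <- c(gaps, sprintf("control %s in %s condition", cg, cond))
  }
  if (length(gaps) > 0L)
    stopf("ddct_ratio: missing measurements: %s", paste(gaps, collapse = "; "))

  dct <- vapply(c("control", "treated"), function(cond) {
    ctrl_mean <- mean(vapply(tbl$control_genes, mean_ct, numeric(1),
                             tbl = tbl, condition = cond))
    mean_ct(tbl, target, cond) - ctrl_mean
  }, numeric(1))
  ddct <- dct[["treated"]] - dct[["control"]]
  E <- tbl$data$efficiency[tbl$data$gene_id == target][1]
  fc <- E^(-ddct)
  list(fold_change = fc, log2fc = log2(fc),
       significant = fc >= 2 || fc <= 0.5, ddct = unname(ddct))
}

#' Delta-delta-Ct quantification of every non-control gene
#' @param tbl a [ct_table()] object.
#' @return Data frame with columns `gene_id`, `fold_change`, `log2fc`,
#'   `significant`.
#' @export
ddct_all <- function(tbl) {
  stopifnot(inherits(tbl, "ct_table"))
  targets <- setdiff(unique(tbl$data$gene_id), tbl$control_genes)
  rows <- lapply(targets, function(g) {
    r <- ddct_ratio(tbl, g)
    data.frame(gene_id = g, fold_change = r$fold_change,
               log2fc = r$log2fc, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare qPCR fold changes to RNA-seq calls
#'
#' Joins delta-delta-Ct results with RNA-seq DE records and flags sign
#' concordance (both directions agree).  No statistical test is
#' performed; the comparison is confirmatory.
#'
#' @param qpcr_results data frame from [ddct_all()].
#' @param de DE record data frame ([call_degs()]).
#' @return Data frame with columns `gene_id`, `fc_qpcr`, `fc_rnaseq`
#'   (the signed linear fold change), `sign_agrees` (`NA` when the gene
#'   is absent from the DE table).
#' @export
compare_to_rnaseq <- function(qpcr_results, de) {
  idx <- match(qpcr_results$gene_id, de$gene_id)
  fc_rnaseq <- de$fc_signed[idx]
  sign_q <- sign(log2(qpcr_results$fold_change))
  sign_r <- sign(de$log2fc[idx])
  data.frame(gene_id = qpcr_results$gene_id,
             fc_qpcr = qpcr_results$fold_change,
             fc_rnaseq = fc_rnaseq,
             sign_agrees = ifelse(is.na(fc_rnaseq), NA, sign_q == sign_r),
             stringsAsFactors = FALSE)
}
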